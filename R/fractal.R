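# The core statistic: box-counting fractal dimension (D_box) of the
# skeletonized capillary network inside the analysis mask. N(eps) counts the
# eps x eps grid boxes (single grid, anchored at the top-left corner) that
# contain at least one skeleton pixel inside the mask; D_box is the OLS
# slope of log N(eps) against log(1/eps).

#' Skeletonize a binary vessel map
#'
#' Topology-preserving thinning (Zhang-Suen with a staircase cleanup pass) to
#' 1-px-wide centerlines. The number of 8-connected components is preserved
#' and the skeleton is a subset of the input foreground.
#'
#' @param vessels a [vessel_map()] or logical matrix.
#' @return A list of class `skeleton_map` with elements `pixels` and `source`.
#' @export
skeletonize <- function(vessels) {
  px <- as_pixel_matrix(vessels)
  stopifnot(is.logical(px))
  sk <- .thin_cpp(px)
  # The thinning's local simple-point test occasionally leaves a 2x2 block
  # at a junction whose pixels are all locally non-simple yet globally
  # redundant. Resolve the (rare) survivors with an exact global check:
  # delete a block pixel only if the component count is unchanged.
  repeat {
    blk <- which(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
                 sk[-nrow(sk), -1] & sk[-1, -1], arr.ind = TRUE)
    if (nrow(blk) == 0) break
    ncomp <- n_components(sk)
    progressed <- FALSE
    for (b in seq_len(nrow(blk))) {
      r <- blk[b, 1]; c <- blk[b, 2]
      for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        if (!sk[r + off[1], c + off[2]]) next
        trial <- sk
        trial[r + off[1], c + off[2]] <- FALSE
        if (n_components(trial) == ncomp) {
          sk <- trial
          progressed <- TRUE
          break
        }
      }
      if (progressed) break
    }
    if (!progressed) break  # topologically required block: keep it
  }
  structure(list(pixels = sk, source = vessels), class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %dx%d px, %d skeleton px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

default_box_sizes <- function(side) {
  s <- 2
  out <- integer(0)
  while (s <= side / 4) {
    out <- c(out, s)
    s <- s * 2
  }
  if (!length(out)) out <- 2L
  rev(as.integer(out))  # decreasing
}

#' Count occupied boxes at a series of box sizes
#'
#' Tiles the grid from the top-left origin into `eps x eps` boxes and counts,
#' for each box size, the boxes containing at least one pixel that is both
#' foreground and inside the mask.
#'
#' @param map a `skeleton_map`, [vessel_map()] or logical matrix.
#' @param mask optional [make_annulus_mask()] or logical matrix restricting
#'   the counted pixels (default: whole image).
#' @param box_sizes_px positive integer box sizes; default powers of two
#'   from 2 px up to a quarter of the image side.
#' @return A list of class `box_count_curve`: `box_sizes_px` (decreasing),
#'   `counts`, `mask_area_px`.
#' @export
box_count <- function(map, mask = NULL, box_sizes_px = NULL) {
  px <- as_pixel_matrix(map)
  stopifnot(is.logical(px))
  mk <- if (is.null(mask)) matrix(TRUE, nrow(px), ncol(px))
        else if (inherits(mask, "annulus_mask")) mask$pixels
        else mask
  stopifnot(identical(dim(mk), dim(px)))
  if (is.null(box_sizes_px)) box_sizes_px <- default_box_sizes(min(dim(px)))
  box_sizes_px <- as.integer(box_sizes_px)
  if (any(box_sizes_px < 1)) stop("box sizes must be >= 1")
  box_sizes_px <- sort(unique(box_sizes_px), decreasing = TRUE)

  fg <- which(px & mk, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("no foreground inside the mask: D_box is undefined")
  counts <- vapply(box_sizes_px, function(eps) {
    br <- (fg[, 1] - 1L) %/% eps
    bc <- (fg[, 2] - 1L) %/% eps
    length(unique(br * (((ncol(px) - 1L) %/% eps) + 1L) + bc))
  }, integer(1))
  structure(list(box_sizes_px = box_sizes_px, counts = counts,
                 mask_area_px = sum(mk)),
            class = "box_count_curve")
}

#' Fit the box-counting dimension
#'
#' Ordinary least squares of `log N(eps)` on `log(1/eps)` over the requested
#' fit range; the slope is D_box.
#'
#' @param curve a [box_count()] result.
#' @param fit_range optional `c(min_eps, max_eps)` bounds on the box sizes
#'   used in the fit.
#' @return A list of class `dbox_result`: `dbox`, `intercept`, `r_squared`,
#'   `fit_range` (box sizes used), `curve`, and `flag` (character vector of
#'   quality flags, e.g. when the slope leaves \[0, 2\]).
#' @export
fit_dbox <- function(curve, fit_range = NULL) {
  stopifnot(inherits(curve, "box_count_curve"))
  eps <- curve$box_sizes_px
  n_eps <- curve$counts
  keep <- rep(TRUE, length(eps))
  if (!is.null(fit_range))
    keep <- eps >= min(fit_range) & eps <= max(fit_range)
  eps <- eps[keep]; n_eps <- n_eps[keep]
  dup <- duplicated(eps)
  if (any(dup)) {
    warning("dropping duplicated box sizes from the fit")
    eps <- eps[!dup]; n_eps <- n_eps[!dup]
  }
  if (length(eps) < 3) stop("need at least 3 box sizes in the fit range")
  x <- log(1 / eps)
  y <- log(n_eps)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  r2 <- if (stats::var(y) == 0) 1
        else 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  flag <- character(0)
  if (slope < 0 || slope > 2) flag <- c(flag, "dbox_outside_[0,2]")
  if (r2 < 0.95) flag <- c(flag, "low_fit_r_squared")
  structure(list(dbox = slope, intercept = unname(fit$coefficients[1]),
                 r_squared = r2, fit_range = eps, curve = curve, flag = flag),
            class = "dbox_result")
}

#' @export
print.dbox_result <- function(x, ...) {
  cat(sprintf("<dbox_result> D_box = %.4f (R^2 = %.4f, %d scales%s)\n",
              x$dbox, x$r_squared, length(x$fit_range),
              if (length(x$flag)) paste0("; flags: ",
                                         paste(x$flag, collapse = ", ")) else ""))
  invisible(x)
}

#' End-to-end D_box from an angiogram or vessel map
#'
#' Runs the full measurement chain: segmentation (skipped for binary input),
#' FAZ detection, FAZ-excluded annulus construction, skeletonization, box
#' counting and log-log fit. All intermediates are attached for audit.
#'
#' @param x an [enface_angiogram()] (grayscale) or [vessel_map()] (binary).
#' @param extent_mm physical field size; taken from the angiogram when
#'   available.
#' @param seg_params [segmentation_params()] used for grayscale input.
#' @param inner_diameter_mm,outer_diameter_mm annulus diameters.
#' @param exclude_faz detect and remove the FAZ from the mask (default TRUE).
#' @param use_skeleton compute D_box on the skeleton (default, matching the
#'   standard protocol) or on the binary map (`FALSE`; sensitivity analysis).
#' @param box_sizes_px forwarded to [box_count()].
#' @param fit_range forwarded to [fit_dbox()].
#' @return A `dbox_result` whose `"intermediates"` attribute holds the
#'   vessel map, skeleton, FAZ region and annulus mask.
#' @export
compute_dbox <- function(x, extent_mm = 3, seg_params = segmentation_params(),
                         inner_diameter_mm = 0.6, outer_diameter_mm = 2.5,
                         exclude_faz = TRUE, use_skeleton = TRUE,
                         box_sizes_px = NULL, fit_range = NULL) {
  if (inherits(x, "enface_angiogram")) {
    extent_mm <- x$extent_mm
    vessels <- segment_vessels(x, seg_params)
  } else if (inherits(x, "vessel_map")) {
    vessels <- x
  } else if (is.matrix(x) && is.logical(x)) {
    vessels <- vessel_map(x, "ground_truth")
  } else stop("x must be an angiogram, a vessel map, or a logical matrix")

  mpp <- mm_per_pixel(extent_mm, ncol(vessels$pixels))
  faz <- if (exclude_faz && any(vessels$pixels))
    detect_faz(vessels, mpp, close_radius_px = seg_params$faz_close_radius_px)
  else NULL
  mask <- make_annulus_mask(dim(vessels$pixels), mpp, inner_diameter_mm,
                            outer_diameter_mm, faz = faz)
  skel <- skeletonize(vessels)
  target <- if (use_skeleton) skel else vessels
  curve <- box_count(target, mask, box_sizes_px)
  res <- fit_dbox(curve, fit_range)
  attr(res, "intermediates") <- list(vessels = vessels, skeleton = skel,
                                     faz = faz, mask = mask)
  res
}
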