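# Parafoveal region of interest: the annular zone of 0.6-2.5 mm diameter
# around the foveal center, with the detected FAZ removed. Geometry is
# pixel-center sampled with a half-open radial interval [inner, outer) so
# that pixel counts are bit-reproducible and exactly symmetric under 90-degree
# rotation about the image center.

#' Physical pixel pitch
#'
#' @param extent_mm physical side length of the field of view.
#' @param width_px image side length in pixels.
#' @return `extent_mm / width_px`, the size of one pixel in mm.
#' @examples
#' mm_per_pixel(3, 300)  # 0.01
#' @export
mm_per_pixel <- function(extent_mm, width_px) {
  if (extent_mm <= 0 || width_px <= 0) stop("extent and width must be positive")
  extent_mm / width_px
}

#' Build the FAZ-excluded parafoveal annulus mask
#'
#' A pixel belongs to the annulus iff the distance from its center to
#' `center_px` satisfies `inner_radius <= d < outer_radius` (radii in px =
#' diameter / 2 / mm_per_px). When a found [detect_faz()] region is supplied,
#' its pixels are removed from the mask.
#'
#' @param shape image dimensions, either one integer (square) or c(rows, cols).
#' @param mm_per_px pixel pitch from [mm_per_pixel()].
#' @param inner_diameter_mm,outer_diameter_mm annulus diameters (defaults
#'   0.6 and 2.5 mm, the usual parafoveal ring).
#' @param faz optional [detect_faz()] result (or logical matrix) to exclude.
#' @param center_px optional (row, col) center; default the geometric image
#'   center.
#' @return A list of class `annulus_mask`: `pixels` (logical matrix),
#'   `inner_diameter_mm`, `outer_diameter_mm`, `center_px`, `faz_excluded`.
#' @export
make_annulus_mask <- function(shape, mm_per_px, inner_diameter_mm = 0.6,
                              outer_diameter_mm = 2.5, faz = NULL,
                              center_px = NULL) {
  if (length(shape) == 1) shape <- c(shape, shape)
  stopifnot(mm_per_px > 0)
  if (inner_diameter_mm >= outer_diameter_mm)
    stop("inner diameter must be smaller than outer diameter")
  n_r <- shape[1]; n_c <- shape[2]
  if (is.null(center_px)) center_px <- c((n_r + 1) / 2, (n_c + 1) / 2)
  r_in <- inner_diameter_mm / 2 / mm_per_px
  r_out <- outer_diameter_mm / 2 / mm_per_px
  rr <- matrix(seq_len(n_r), n_r, n_c)
  cl <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  d <- sqrt((rr - center_px[1])^2 + (cl - center_px[2])^2)
  mask <- d >= r_in & d < r_out
  faz_excluded <- FALSE
  if (!is.null(faz)) {
    fmask <- if (inherits(faz, "faz_region")) {
      if (faz$found) faz$mask else NULL
    } else faz
    if (!is.null(fmask)) {
      stopifnot(identical(dim(fmask), dim(mask)))
      mask <- mask & !fmask
      faz_excluded <- TRUE
    }
  }
  structure(list(pixels = mask, inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm, center_px = center_px,
                 faz_excluded = faz_excluded),
            class = "annulus_mask")
}

#' @export
print.annulus_mask <- function(x, ...) {
  cat(sprintf("<annulus_mask> %.1f-%.1f mm, %d px%s\n", x$inner_diameter_mm,
              x$outer_diameter_mm, sum(x$pixels),
              if (x$faz_excluded) ", FAZ excluded" else ""))
  invisible(x)
}
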