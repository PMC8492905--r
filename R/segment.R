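# Classical vessel segmentation and FAZ detection. The study this pipeline
# emulates used a fine-tuned U-net whose weights are not public; here the
# segmenter is a multiscale Frangi vesselness filter followed by
# quantile-based hysteresis thresholding and small-object removal. The
# function signature acts as a segmenter interface: a learned model could be
# slotted in by providing another function with the same contract.

#' Segmentation parameters
#'
#' @param scales_px Gaussian scales of the vesselness filter, in pixels;
#'   should bracket the expected capillary radius.
#' @param beta Frangi blobness weight.
#' @param q_low low hysteresis threshold, as a quantile of the intensities of
#'   foreground-candidate pixels (those at or above the Otsu threshold);
#'   pixels above it are growable.
#' @param q_high high hysteresis threshold, as a quantile of the multiscale
#'   vesselness response; growable pixels above it are seeds.
#' @param min_object_px connected components smaller than this are dropped.
#' @param faz_close_radius_px disk radius of the morphological closing used
#'   before FAZ background extraction.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(scales_px = c(1, 1.5, 2, 3), beta = 0.5,
                                q_low = 0.05, q_high = 0.90,
                                min_object_px = 30L, faz_close_radius_px = 5) {
  stopifnot(all(scales_px > 0), q_low < q_high, q_low > 0, q_high < 1,
            min_object_px >= 0, faz_close_radius_px >= 0)
  structure(list(scales_px = scales_px, beta = beta, q_low = q_low,
                 q_high = q_high, min_object_px = as.integer(min_object_px),
                 faz_close_radius_px = faz_close_radius_px),
            class = "segmentation_params")
}

#' Segment vessels in an en face angiogram
#'
#' Hysteresis segmentation driven by two complementary channels: the
#' multiscale Frangi vesselness response supplies the seeds (its high
#' quantile marks pixels that are certainly on a curvilinear structure),
#' while the image intensity — gated at the Otsu threshold — supplies the
#' growable support that recovers the full vessel width. Seeds are grown
#' through 8-connected support pixels; specks below the minimum object size
#' are removed. Deterministic.
#'
#' @param image an [enface_angiogram()] or numeric matrix in \[0, 1\].
#' @param params a [segmentation_params()].
#' @return A [vessel_map()] with provenance `"segmented"`. A
#'   constant-intensity image yields an empty map with a warning.
#' @export
segment_vessels <- function(image, params = segmentation_params()) {
  px <- as_pixel_matrix(image)
  meta <- if (inherits(image, "enface_angiogram"))
    image[c("extent_mm", "layer", "subject_id", "eye", "sq")] else list()
  rng <- range(px)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant-intensity image: returning an empty vessel map")
    return(vessel_map(matrix(FALSE, nrow(px), ncol(px)), "segmented", meta))
  }
  t_otsu <- otsu_threshold(px)
  cand <- px >= t_otsu
  t_low <- stats::quantile(px[cand], params$q_low, names = FALSE)
  weak <- px >= max(t_low, t_otsu)
  v <- frangi_vesselness(px, scales = params$scales_px, beta = params$beta)
  strong <- weak & (v >= stats::quantile(v, params$q_high, names = FALSE))
  seg <- .hysteresis_cpp(strong, weak)
  seg <- remove_small_objects(seg, params$min_object_px)
  vessel_map(seg, "segmented", meta)
}

#' Foveal avascular zone detection
#'
#' Morphologically closes the vessel map (bridging capillary gaps), then
#' takes the background connected component containing — or nearest to —
#' the image center, clipped to a search disk. `found` is `FALSE` when no
#' avascular component of at least `min_area_mm2` lies within reach.
#'
#' @param vessels a [vessel_map()] or logical matrix.
#' @param mm_per_px physical pixel pitch, from [mm_per_pixel()].
#' @param search_radius_mm how far from the image center to look (default
#'   0.75 mm, generous for a macular scan centred on the fovea).
#' @param close_radius_px closing disk radius in px.
#' @param min_area_mm2 minimum plausible FAZ area.
#' @return A list of class `faz_region`: `mask` (logical matrix),
#'   `centroid_px` (row, col), `area_mm2`, `found`.
#' @export
detect_faz <- function(vessels, mm_per_px, search_radius_mm = 0.75,
                       close_radius_px = 5, min_area_mm2 = 0.02) {
  px <- as_pixel_matrix(vessels)
  stopifnot(is.logical(px), mm_per_px > 0)
  n_r <- nrow(px); n_c <- ncol(px)
  cr <- (n_r + 1) / 2; cc <- (n_c + 1) / 2
  rr <- matrix(seq_len(n_r), n_r, n_c)
  cl <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  d2 <- (rr - cr)^2 + (cl - cc)^2
  disk <- d2 <= (search_radius_mm / mm_per_px)^2

  bg <- !close_disk(px, close_radius_px)
  cand <- bg & disk
  empty <- function() structure(list(mask = matrix(FALSE, n_r, n_c),
                                     centroid_px = c(NA_real_, NA_real_),
                                     area_mm2 = 0, found = FALSE),
                                class = "faz_region")
  if (!any(cand)) return(empty())
  lab <- label_components(cand, connectivity = 4L)
  ctr_lab <- lab[round(cr), round(cc)]
  if (ctr_lab == 0) {
    # nearest labelled pixel to the center
    idx <- which(lab > 0)
    ctr_lab <- lab[idx[which.min(d2[idx])]]
  }
  mask <- lab == ctr_lab
  area <- sum(mask) * mm_per_px^2
  if (area < min_area_mm2) return(empty())
  centroid <- c(mean(rr[mask]), mean(cl[mask]))
  structure(list(mask = mask, centroid_px = centroid, area_mm2 = area,
                 found = TRUE),
            class = "faz_region")
}

#' @export
print.faz_region <- function(x, ...) {
  if (x$found)
    cat(sprintf("<faz_region> found, area %.3f mm^2, centroid (%.1f, %.1f)\n",
                x$area_mm2, x$centroid_px[1], x$centroid_px[2]))
  else cat("<faz_region> not found\n")
  invisible(x)
}
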