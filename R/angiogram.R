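# Core containers for the imaging side of the pipeline. These are light
# S3 records over plain matrices so that every intermediate stays printable
# and testable.

#' En face OCTA angiogram
#'
#' A grayscale en face angiogram of the macular microvasculature: a square
#' pixel grid with physical extent in millimetres plus acquisition metadata.
#' The standard acquisition emulated here is a 3 x 3 mm macular scan of one
#' capillary layer (superficial, deep or whole plexus).
#'
#' @param pixels numeric matrix with intensities in \[0, 1\].
#' @param extent_mm physical side length of the field of view (default 3).
#' @param layer capillary layer tag: `"SCP"`, `"DCP"` or `"WCP"`.
#' @param subject_id,eye optional identifiers (`eye` is `"OD"` or `"OS"`).
#' @param sq device-reported signal-quality index (integer scale; studies
#'   typically accept scans with `sq >= 6`).
#' @return An object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(pixels, extent_mm = 3, layer = c("SCP", "DCP", "WCP"),
                             subject_id = NA_character_, eye = NA_character_,
                             sq = NA_integer_) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels), extent_mm > 0)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("angiogram intensities must lie in [0, 1]")
  structure(list(pixels = pixels, extent_mm = extent_mm, layer = layer,
                 subject_id = subject_id, eye = eye, sq = sq),
            class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %dx%d px, %.1f mm, layer %s, SQ %s\n",
              nrow(x$pixels), ncol(x$pixels), x$extent_mm, x$layer,
              ifelse(is.na(x$sq), "?", x$sq)))
  invisible(x)
}

#' Binary vessel map
#'
#' A boolean pixel grid marking segmented (or ground-truth) vessels, carrying
#' the provenance and source metadata of the angiogram it came from.
#'
#' @param pixels logical matrix.
#' @param provenance `"segmented"` or `"ground_truth"`.
#' @param meta list of metadata copied from the source angiogram.
#' @return An object of class `vessel_map`.
#' @export
vessel_map <- function(pixels, provenance = c("segmented", "ground_truth"),
                       meta = list()) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, provenance = provenance, meta = meta),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> %dx%d px, %d foreground px (%s)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$provenance))
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "enface_angiogram") || inherits(x, "vessel_map") ||
      inherits(x, "skeleton_map")) return(x$pixels)
  if (is.matrix(x)) return(x)
  stop("expected an image-like object or a matrix")
}

# ---- PNG input/output -------------------------------------------------------

#' Read a grayscale PNG as an angiogram
#'
#' 8- or 16-bit PNGs are accepted; RGB(A) images are converted to luminance.
#'
#' @param path PNG file.
#' @inheritParams enface_angiogram
#' @return An [enface_angiogram()].
#' @export
read_angiogram_png <- function(path, extent_mm = 3, layer = "SCP",
                               subject_id = NA_character_, eye = NA_character_,
                               sq = NA_integer_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    a <- if (nch >= 3) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
         else a[, , 1]
  }
  enface_angiogram(a, extent_mm = extent_mm, layer = layer,
                   subject_id = subject_id, eye = eye, sq = sq)
}

#' Write a grayscale image or binary mask as 8-bit PNG
#'
#' @param x matrix (numeric in \[0,1\] or logical) or image-like object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  m <- as_pixel_matrix(x)
  if (is.logical(m)) m <- m * 1
  m <- pmin(pmax(m, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' Pixels above `threshold` become foreground.
#'
#' @param path PNG file.
#' @param threshold intensity cutoff (default 0.5).
#' @return Logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > threshold
}
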