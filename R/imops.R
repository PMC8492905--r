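# Low-level pixel-grid operations: separable Gaussian filtering, Hessian
# ridge (vesselness) response, and binary morphology wrappers around the
# compiled kernels. All images are plain numeric/logical matrices.

gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# shift a matrix by `by` rows (positive = down) or columns, replicating edges
shift_rows <- function(m, by) {
  n <- nrow(m)
  idx <- pmin(pmax(seq_len(n) - by, 1L), n)
  m[idx, , drop = FALSE]
}

shift_cols <- function(m, by) {
  n <- ncol(m)
  idx <- pmin(pmax(seq_len(n) - by, 1L), n)
  m[, idx, drop = FALSE]
}

# separable convolution with a symmetric 1-D kernel, replicate padding
conv_sep <- function(img, kernel) {
  h <- (length(kernel) - 1L) / 2L
  offs <- seq(-h, h)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(offs)) out <- out + kernel[i] * shift_rows(img, offs[i])
  res <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(offs)) res <- res + kernel[i] * shift_cols(out, offs[i])
  res
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel(sigma))
}

# Multiscale Frangi (1998) ridge filter for bright curvilinear structures.
# The Hessian is taken by central differences of the Gaussian-smoothed image
# and scale-normalized by sigma^2; the response at each pixel is the maximum
# over scales.
frangi_vesselness <- function(img, scales = c(1, 1.5, 2, 3), beta = 0.5,
                              c_frac = 0.5) {
  stopifnot(is.matrix(img))
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    g <- gaussian_blur(img, s)
    fxx <- shift_cols(g, 1) - 2 * g + shift_cols(g, -1)
    fyy <- shift_rows(g, 1) - 2 * g + shift_rows(g, -1)
    fxy <- (shift_rows(shift_cols(g, 1), 1) - shift_rows(shift_cols(g, -1), 1) -
            shift_rows(shift_cols(g, 1), -1) + shift_rows(shift_cols(g, -1), -1)) / 4
    s2 <- s^2
    fxx <- fxx * s2; fyy <- fyy * s2; fxy <- fxy * s2
    tmp <- sqrt((fxx - fyy)^2 + 4 * fxy^2)
    l1 <- (fxx + fyy + tmp) / 2
    l2 <- (fxx + fyy - tmp) / 2
    # order by magnitude: |la| <= |lb|
    swap <- abs(l1) > abs(l2)
    la <- ifelse(swap, l2, l1)
    lb <- ifelse(swap, l1, l2)
    rb2 <- (la / pmax(abs(lb), .Machine$double.eps))^2
    s2n <- la^2 + lb^2
    cpar <- c_frac * sqrt(max(s2n))
    if (cpar <= 0) next
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2n / (2 * cpar^2)))
    v[lb > 0] <- 0  # bright ridges have a strongly negative large eigenvalue
    best <- pmax(best, v)
  }
  best
}

# Otsu's threshold (maximal between-class variance), 256-bin histogram
otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(img, brk, all.inside = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius^2
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]))
}

dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  o <- disk_offsets(radius)
  .dilate_cpp(mask, o$dr, o$dc)
}

erode_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !dilate_disk(!mask, radius)
}

close_disk <- function(mask, radius) erode_disk(dilate_disk(mask, radius), radius)

label_components <- function(mask, connectivity = 8L) {
  .cc_label_cpp(mask, as.integer(connectivity))
}

n_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}

remove_small_objects <- function(mask, min_size, connectivity = 8L) {
  if (min_size <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard segmentation agreement score.
#' Returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return A number in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
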