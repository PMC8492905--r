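# Rasterized fractals with known Hausdorff dimension. These are the oracles
# for the box-counting estimator: a correct implementation must recover the
# closed-form dimension of each set to within a small scale-range error.

#' Generate a binary image of a known fractal
#'
#' Produces deterministic rasterizations of sets with closed-form fractal
#' dimension, used to validate the box-counting estimator: a line (dimension
#' 1), a filled square (2), the Koch curve (log 4 / log 3), the Sierpinski
#' carpet (log 8 / log 3) and the Sierpinski triangle (log 3 / log 2).
#'
#' @param kind one of `"line"`, `"filled_square"`, `"koch_curve"`,
#'   `"sierpinski_carpet"`, `"sierpinski_triangle"`.
#' @param size_px side length of the square raster.
#' @param iterations construction depth for the self-similar sets (ignored
#'   for line and filled square).
#' @return A [vessel_map()] whose `meta$dimension` holds the theoretical
#'   fractal dimension.
#' @examples
#' k <- generate_known_fractal("sierpinski_carpet", 243, 5)
#' k$meta$dimension  # log(8)/log(3)
#' @export
generate_known_fractal <- function(kind = c("line", "filled_square", "koch_curve",
                                            "sierpinski_carpet",
                                            "sierpinski_triangle"),
                                   size_px, iterations = 5L) {
  kind <- match.arg(kind)
  stopifnot(size_px >= 2)
  iterations <- as.integer(iterations)
  if (kind %in% c("koch_curve", "sierpinski_carpet", "sierpinski_triangle")) {
    if (iterations < 1) stop("iterations must be >= 1")
    base <- if (kind == "sierpinski_carpet") 3 else 2
    if (base^iterations > size_px)
      stop(sprintf("iterations too deep for size_px: need size_px >= %d",
                   base^iterations))
  }
  px <- matrix(FALSE, size_px, size_px)
  dim_theory <- switch(kind,
    line = 1.0,
    filled_square = 2.0,
    koch_curve = log(4) / log(3),
    sierpinski_carpet = log(8) / log(3),
    sierpinski_triangle = log(3) / log(2))

  if (kind == "line") {
    px[ceiling(size_px / 2), ] <- TRUE
  } else if (kind == "filled_square") {
    px[] <- TRUE
  } else if (kind == "koch_curve") {
    px <- rasterize_koch(size_px, iterations)
  } else if (kind == "sierpinski_carpet") {
    m <- 3L^iterations
    u <- floor((seq_len(size_px) - 1) * m / size_px)
    keep_digit <- function(v, k) (v %/% 3L^(k - 1L)) %% 3L
    ok <- matrix(TRUE, size_px, size_px)
    for (k in seq_len(iterations)) {
      di <- keep_digit(u, k)
      ok <- ok & !(outer(di == 1L, di == 1L, "&"))
    }
    px <- ok
  } else {  # sierpinski_triangle
    m <- 2L^iterations
    u <- floor((seq_len(size_px) - 1) * m / size_px)
    px <- outer(u, u, function(a, b) bitwAnd(a, b) == 0L)
  }
  vessel_map(px, provenance = "ground_truth",
             meta = list(kind = kind, dimension = dim_theory,
                         iterations = iterations))
}

# Koch curve: refine the segment list, peak pointing toward lower row indices.
# The baseline row is deliberately off the dyadic grid (0.7 * size + 0.5):
# at 0.75 * size the flat base segments would lie exactly on power-of-two box
# boundaries, a degenerate alignment that makes single-grid box counts
# unstable under 1-px shifts.
rasterize_koch <- function(size_px, iterations) {
  y0 <- 0.7 * size_px + 0.5
  segs <- list(list(a = c(1, y0), b = c(size_px, y0)))  # (x, y) in px
  rot <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  for (it in seq_len(iterations)) {
    nxt <- vector("list", 4 * length(segs))
    j <- 0
    for (s in segs) {
      v <- (s$b - s$a) / 3
      p1 <- s$a + v
      p2 <- s$a + 2 * v
      peak <- p1 + rot(v, -60)  # negative y rotation = upward on screen
      nxt[[j + 1]] <- list(a = s$a, b = p1)
      nxt[[j + 2]] <- list(a = p1, b = peak)
      nxt[[j + 3]] <- list(a = peak, b = p2)
      nxt[[j + 4]] <- list(a = p2, b = s$b)
      j <- j + 4
    }
    segs <- nxt
  }
  px <- matrix(FALSE, size_px, size_px)
  for (s in segs) px <- draw_segment(px, s$a, s$b)
  px
}

# stamp a polyline segment onto a logical raster (x = column, y = row)
draw_segment <- function(px, a, b, step = 0.4) {
  len <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(len / step))
  t <- seq(0, 1, length.out = n)
  xs <- round(a[1] + t * (b[1] - a[1]))
  ys <- round(a[2] + t * (b[2] - a[2]))
  keep <- xs >= 1 & xs <= ncol(px) & ys >= 1 & ys <= nrow(px)
  px[cbind(ys[keep], xs[keep])] <- TRUE
  px
}
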