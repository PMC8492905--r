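# Synthetic retinal-like angiograms with ground truth. The generator grows a
# stochastic branching tree from arteriole entry points on the image border
# toward the fovea, stops at the boundary of an elliptical foveal avascular
# zone, rasterizes the tree at a given vessel width, and degrades the binary
# render into a grayscale angiogram (Gaussian blur + additive noise).

#' Parameters of the synthetic vasculature generator
#'
#' Defaults emulate a 3 x 3 mm macular scan rendered at 512 x 512 px
#' (about 5.9 um/px): a dozen feeding vessels, capillary-scale width of
#' 2.5 px (~15 um), a foveal avascular zone of 0.25 x 0.20 mm semi-axes
#' (area ~0.16 mm^2, typical for a healthy macula), mild optical blur and
#' low additive noise.
#'
#' @param image_size_px raster side length (>= 64).
#' @param extent_mm physical side length of the field.
#' @param n_seed_vessels number of entry points on the image border.
#' @param branch_density nonnegative dial controlling the per-step branching
#'   probability; 0 grows unbranched trunks only.
#' @param faz_semi_axes_mm semi-axes (a, b) of the central avascular ellipse.
#' @param vessel_width_px stroke width of the rasterized vessels.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param blur_sigma_px Gaussian blur applied before noise.
#' @return A list of class `synth_vasc_params`.
#' @export
synth_vasc_params <- function(image_size_px = 512L, extent_mm = 3.0,
                              n_seed_vessels = 12L, branch_density = 1.0,
                              faz_semi_axes_mm = c(0.25, 0.20),
                              vessel_width_px = 2.5, noise_sd = 0.02,
                              blur_sigma_px = 0.7) {
  stopifnot(image_size_px >= 64, extent_mm > 0, n_seed_vessels >= 1,
            branch_density >= 0, vessel_width_px > 0, noise_sd >= 0,
            blur_sigma_px >= 0, length(faz_semi_axes_mm) == 2)
  if (any(faz_semi_axes_mm >= extent_mm / 2))
    stop("FAZ semi-axes must be smaller than half the field extent")
  structure(list(image_size_px = as.integer(image_size_px),
                 extent_mm = extent_mm,
                 n_seed_vessels = as.integer(n_seed_vessels),
                 branch_density = branch_density,
                 faz_semi_axes_mm = faz_semi_axes_mm,
                 vessel_width_px = vessel_width_px,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px),
            class = "synth_vasc_params")
}

# evaluate expr with a private RNG stream; the caller's stream is untouched
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic angiogram with ground truth
#'
#' Grows a branching vascular tree (angle-jittered random walk with Bernoulli
#' branching per step) from border seed points toward the image center,
#' terminating at the FAZ ellipse, then renders a grayscale angiogram.
#' Identical `params` and `seed` give bit-identical output.
#'
#' @param params a [synth_vasc_params()].
#' @param seed integer RNG seed.
#' @param layer capillary layer tag for the metadata.
#' @return A list of class `synthetic_angiogram` with elements `image`
#'   ([enface_angiogram()]), `truth_vessels` ([vessel_map()]), `truth_faz`
#'   (logical matrix), `params` and `seed`.
#' @examples
#' sa <- generate_vasculature(synth_vasc_params(image_size_px = 128), seed = 1)
#' sum(sa$truth_vessels$pixels & sa$truth_faz)  # 0: the FAZ is avascular
#' @export
generate_vasculature <- function(params = synth_vasc_params(), seed = 1L,
                                 layer = "SCP") {
  stopifnot(inherits(params, "synth_vasc_params"))
  n <- params$image_size_px
  mm_px <- params$extent_mm / n
  cx <- n / 2 + 0.5
  cy <- n / 2 + 0.5
  ax <- params$faz_semi_axes_mm[1] / mm_px  # ellipse semi-axes in px
  ay <- params$faz_semi_axes_mm[2] / mm_px
  if (ax >= n / 2 || ay >= n / 2) stop("degenerate geometry: FAZ covers the field")

  pts <- with_local_seed(seed, grow_tree(n, cx, cy, ax, ay,
                                         params$n_seed_vessels,
                                         params$branch_density))

  vessels <- matrix(FALSE, n, n)
  if (nrow(pts) > 0) {
    o <- disk_offsets(params$vessel_width_px / 2)
    rr <- rep(round(pts[, 2]), each = length(o$dr)) + o$dr
    cc <- rep(round(pts[, 1]), each = length(o$dr)) + o$dc
    keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    vessels[cbind(rr[keep], cc[keep])] <- TRUE
  }

  xs <- matrix(seq_len(n), n, n, byrow = TRUE)  # column index = x
  ys <- matrix(seq_len(n), n, n)                # row index = y
  faz <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
  vessels[faz] <- FALSE

  img <- vessels * 1.0
  img <- gaussian_blur(img, params$blur_sigma_px)
  if (params$noise_sd > 0)
    img <- img + with_local_seed(seed + 1L,
                                 matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n))
  img <- pmin(pmax(img, 0), 1)

  structure(list(
    image = enface_angiogram(img, extent_mm = params$extent_mm, layer = layer),
    truth_vessels = vessel_map(vessels, provenance = "ground_truth",
                               meta = list(layer = layer)),
    truth_faz = faz,
    params = params, seed = as.integer(seed)),
    class = "synthetic_angiogram")
}

# random-walk growth; returns a matrix of stamp points (x, y)
grow_tree <- function(n, cx, cy, ax, ay, n_seeds, branch_density,
                      step_len = 2, ang_sd = 0.22, center_pull = 0.10,
                      branch_rate = 0.035, max_gen = 6L, max_branches = 4000L,
                      max_steps = 600L) {
  inside_faz <- function(x, y) ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
  # seed entry points: angles around the border, projected onto the square
  th <- 2 * pi * (seq_len(n_seeds) - 1) / n_seeds + stats::runif(n_seeds, 0, 2 * pi / n_seeds)
  sc <- pmax(abs(cos(th)), abs(sin(th)))
  sx <- cx + cos(th) / sc * (n / 2 - 1)
  sy <- cy + sin(th) / sc * (n / 2 - 1)
  queue <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    d0 <- atan2(cy - sy[k], cx - sx[k]) + stats::rnorm(1, 0, 0.15)
    queue[[k]] <- list(x = sx[k], y = sy[k], dir = d0, gen = 1L)
  }
  chunks <- list()
  n_br <- n_seeds
  qi <- 1L
  while (qi <= length(queue)) {
    br <- queue[[qi]]; qi <- qi + 1L
    x <- br$x; y <- br$y; dir <- br$dir
    bx <- numeric(2 * max_steps); by <- numeric(2 * max_steps); np <- 0L
    for (s in seq_len(max_steps)) {
      # jitter heading, pull gently toward the fovea
      toc <- atan2(cy - y, cx - x)
      dd <- ((toc - dir + pi) %% (2 * pi)) - pi
      dir <- dir + stats::rnorm(1, 0, ang_sd) + center_pull * dd
      nx <- x + step_len * cos(dir)
      ny <- y + step_len * sin(dir)
      if (nx < 1 || nx > n || ny < 1 || ny > n) break
      if (inside_faz(nx, ny)) break
      # stamp substeps for a continuous stroke
      bx[np + 1L] <- (x + nx) / 2; by[np + 1L] <- (y + ny) / 2
      bx[np + 2L] <- nx; by[np + 2L] <- ny
      np <- np + 2L
      x <- nx; y <- ny
      if (branch_density > 0 && br$gen < max_gen && n_br < max_branches &&
          stats::runif(1) < branch_density * branch_rate) {
        side <- sample(c(-1, 1), 1)
        queue[[length(queue) + 1L]] <-
          list(x = x, y = y, dir = dir + side * stats::runif(1, 0.35, 1.2),
               gen = br$gen + 1L)
        n_br <- n_br + 1L
      }
    }
    if (np > 0) chunks[[length(chunks) + 1L]] <- cbind(bx[seq_len(np)], by[seq_len(np)])
  }
  if (!length(chunks)) return(cbind(x = numeric(0), y = numeric(0)))
  pts <- do.call(rbind, chunks)
  colnames(pts) <- c("x", "y")
  pts
}
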