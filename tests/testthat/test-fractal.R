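# Skeletonization, box counting and the D_box fit.

test_that("skeletonization thins a bar to its centerline", {
  bar <- matrix(FALSE, 20, 110)
  bar[8:12, 6:105] <- TRUE  # 5 px wide, 100 px long
  sk <- skeletonize(bar)$pixels
  expect_true(abs(sum(sk) - 100) <= 4)
  expect_true(all(bar[sk]))  # skeleton subset of foreground
})

test_that("empty input gives an empty skeleton", {
  sk <- skeletonize(matrix(FALSE, 10, 10))
  expect_equal(sum(sk$pixels), 0)
})

test_that("thinning preserves 8-connected component count and 1-px width", {
  for (s in 1:5) {
    v <- generate_vasculature(synth_vasc_params(image_size_px = 192,
                                                noise_sd = 0),
                              seed = s)$truth_vessels$pixels
    sk <- skeletonize(v)$pixels
    expect_equal(octafd:::n_components(sk), octafd:::n_components(v))
    expect_true(all(v[sk]))
    blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
              sk[-nrow(sk), -1] & sk[-1, -1]
    expect_equal(sum(blocks), 0)  # no 2x2 block: max local width 1 px
  }
})

test_that("box counts match closed forms on simple patterns", {
  filled <- matrix(TRUE, 64, 64)
  expect_equal(box_count(filled, box_sizes_px = 8)$counts, 64L)
  single <- matrix(FALSE, 64, 64); single[17, 42] <- TRUE
  expect_equal(box_count(single, box_sizes_px = c(1, 2, 4, 8, 16))$counts,
               rep(1L, 5))
  row1 <- matrix(FALSE, 64, 64); row1[10, ] <- TRUE
  expect_equal(box_count(row1, box_sizes_px = 4)$counts, 16L)
})

test_that("box_count equals the brute-force double loop on random instances", {
  n_cases <- 0
  for (seed in 1:25) {
    px <- random_blob_map(64, n_blobs = sample(3:15, 1), seed = seed)
    set.seed(seed + 1000)
    inner <- runif(1, 0, 0.2); outer <- runif(1, 0.35, 0.7)
    mask <- make_annulus_mask(64, 0.01, inner, outer)
    for (eps in c(3, 5, 8, 16)) {
      expect_equal(box_count(px, mask, eps)$counts,
                   brute_box_count(px, mask$pixels, eps))
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 100)
})

test_that("box-count curve invariants hold", {
  px <- random_blob_map(64, seed = 3)
  cv <- box_count(px, box_sizes_px = c(2, 4, 8, 16))
  # box sizes are stored in decreasing order, so counts are nondecreasing
  # along the vector as eps shrinks
  expect_true(all(diff(cv$counts) >= 0))
  expect_true(all(cv$counts >= 1))
  expect_true(all(cv$counts <= ceiling(64 / cv$box_sizes_px)^2))
  # skeleton counts are dominated by the parent map's counts
  sk <- skeletonize(px)$pixels
  cs <- box_count(sk, box_sizes_px = c(2, 4, 8, 16))
  expect_true(all(cs$counts <= cv$counts))
  expect_error(box_count(matrix(FALSE, 8, 8)), "no foreground")
})

test_that("fit_dbox recovers an exact power law and validates input", {
  eps <- c(1, 2, 4, 8, 16)
  curve <- structure(list(box_sizes_px = rev(eps), counts = rev((64 / eps)^2),
                          mask_area_px = 64^2), class = "box_count_curve")
  res <- fit_dbox(curve)
  expect_equal(res$dbox, 2.0, tolerance = 1e-12)
  expect_equal(res$r_squared, 1.0, tolerance = 1e-12)
  expect_error(fit_dbox(structure(list(box_sizes_px = c(4, 2), counts = c(1, 2),
                                       mask_area_px = 1),
                                  class = "box_count_curve")),
               "at least 3")
  res2 <- fit_dbox(curve, fit_range = c(2, 16))
  expect_equal(length(res2$fit_range), 4)
})

test_that("translation by 1 px perturbs counts and dimension only slightly", {
  koch <- generate_known_fractal("koch_curve", 512, 5)$pixels
  sizes <- c(2, 4, 8, 16, 32, 64)
  c1 <- box_count(koch, box_sizes_px = sizes)
  for (shifted in list(rbind(matrix(FALSE, 1, 512), koch[-512, ]),
                       cbind(matrix(FALSE, 512, 1), koch[, -512]))) {
    c2 <- box_count(shifted, box_sizes_px = sizes)
    for (i in seq_along(sizes)) {
      # change bounded by the number of occupied boxes at that scale
      expect_lte(abs(c1$counts[i] - c2$counts[i]), c1$counts[i])
    }
    expect_lt(abs(fit_dbox(c1)$dbox - fit_dbox(c2)$dbox), 0.02)
  }
})

test_that("compute_dbox composes the stages consistently", {
  sa <- generate_vasculature(synth_vasc_params(image_size_px = 256,
                                               noise_sd = 0), seed = 5)
  # ground-truth binary input bypasses segmentation and equals the
  # skeleton-path result assembled by hand
  res <- compute_dbox(sa$truth_vessels, extent_mm = 3)
  mpp <- mm_per_pixel(3, 256)
  faz <- detect_faz(sa$truth_vessels, mpp)
  mask <- make_annulus_mask(256, mpp, faz = faz)
  manual <- fit_dbox(box_count(skeletonize(sa$truth_vessels), mask))
  expect_equal(res$dbox, manual$dbox)
  # determinism
  expect_equal(compute_dbox(sa$image)$dbox, compute_dbox(sa$image)$dbox)
  # intermediates are retrievable
  ints <- attr(res, "intermediates")
  expect_named(ints, c("vessels", "skeleton", "faz", "mask"))
})

test_that("the complexity dial moves D_box monotonically", {
  d <- sapply(c(0.3, 2.0), function(bd) mean(sapply(1:6, function(s)
    compute_dbox(generate_vasculature(
      synth_vasc_params(image_size_px = 256, branch_density = bd),
      seed = s)$image)$dbox)))
  expect_gt(d[2], d[1])
})
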