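# Synthetic-data module: known fractals, vascular growth, cohort simulator.

test_that("known fractals have the stated raster and metadata", {
  line <- generate_known_fractal("line", 256)
  expect_equal(sum(line$pixels), 256)
  expect_equal(sum(rowSums(line$pixels) > 0), 1)  # one row
  expect_equal(line$meta$dimension, 1.0)

  sq <- generate_known_fractal("filled_square", 256)
  expect_true(all(sq$pixels))
  expect_equal(sq$meta$dimension, 2.0)

  koch <- generate_known_fractal("koch_curve", 1024, 6)
  expect_equal(koch$meta$dimension, log(4) / log(3))
  expect_gt(sum(koch$pixels), 1024)  # longer than the base line

  expect_equal(generate_known_fractal("sierpinski_carpet", 729, 6)$meta$dimension,
               log(8) / log(3))
  expect_equal(generate_known_fractal("sierpinski_triangle", 256, 6)$meta$dimension,
               log(3) / log(2))
  # carpet at exact power-of-3 raster: self-similar count 8^k at eps = 3^(6-k)
  carp <- generate_known_fractal("sierpinski_carpet", 729, 6)
  expect_equal(sum(carp$pixels), 8^6)
})

test_that("known-fractal generation is deterministic and validates input", {
  a <- generate_known_fractal("koch_curve", 512, 5)
  b <- generate_known_fractal("koch_curve", 512, 5)
  expect_identical(a$pixels, b$pixels)
  expect_error(generate_known_fractal("koch_curve", 16, 6), "too deep")
  expect_error(generate_known_fractal("nonsense", 64), "arg")
})

test_that("vasculature growth honours the branching dial and determinism", {
  p0 <- synth_vasc_params(image_size_px = 128, branch_density = 0, noise_sd = 0)
  sa <- generate_vasculature(p0, seed = 4)
  # no branching: component count at most the number of seed trunks
  expect_lte(octafd:::n_components(sa$truth_vessels$pixels), p0$n_seed_vessels)

  s1 <- generate_vasculature(synth_vasc_params(image_size_px = 128), seed = 9)
  s2 <- generate_vasculature(synth_vasc_params(image_size_px = 128), seed = 9)
  expect_identical(s1$truth_vessels$pixels, s2$truth_vessels$pixels)
  expect_identical(s1$image$pixels, s2$image$pixels)
  s3 <- generate_vasculature(synth_vasc_params(image_size_px = 128), seed = 10)
  expect_false(identical(s1$truth_vessels$pixels, s3$truth_vessels$pixels))

  # mean foreground count strictly larger at branch_density 2.0 than 0.5
  fg <- function(bd) mean(sapply(1:10, function(s)
    sum(generate_vasculature(synth_vasc_params(image_size_px = 256,
                                               branch_density = bd),
                             seed = s)$truth_vessels$pixels)))
  expect_gt(fg(2.0), fg(0.5))
})

test_that("synthetic angiogram invariants hold across seeds", {
  for (s in 1:5) {
    sa <- generate_vasculature(synth_vasc_params(image_size_px = 128), seed = s)
    expect_identical(dim(sa$image$pixels), dim(sa$truth_vessels$pixels))
    expect_identical(dim(sa$image$pixels), dim(sa$truth_faz))
    # the FAZ is avascular in the ground truth
    expect_equal(sum(sa$truth_vessels$pixels & sa$truth_faz), 0)
    expect_true(all(sa$image$pixels >= 0 & sa$image$pixels <= 1))
  }
  expect_error(synth_vasc_params(faz_semi_axes_mm = c(2, 2)), "semi-axes")
  expect_error(synth_vasc_params(image_size_px = 32), "image_size_px")
})

test_that("cohort simulator produces the stated design", {
  cfg <- cohort_sim_config(n_hc = 44, n_nmosd_non = 13, n_nmosd_on = 21, seed = 2)
  tab <- generate_cohort(cfg)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 2 * (44 + 13 + 21) * 3)  # eyes x subjects x layers
  expect_setequal(unique(tab$layer), c("SCP", "DCP", "WCP"))
  expect_true(all(is.na(tab$edss[tab$group == "HC"])))
  expect_true(all(!is.na(tab$edss[tab$group == "NMOSD"])))
  expect_true(all(tab$on_history[tab$group == "HC"] == 0))
  expect_true(any(tab$sq < 6))  # quality filter must be exercisable
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))  # determinism
  expect_error(generate_cohort(cohort_sim_config(0, 0, 0)), "empty cohort")
  expect_error(generate_cohort(cohort_sim_config(inter_eye_corr = 0.01,
                                                 edss_dbox_corr = -0.9)),
               "positive definite")
})

test_that("null EDSS link yields null correlations over 200 simulations", {
  z <- sapply(1:200, function(s) {
    cfg <- cohort_sim_config(n_hc = 0, n_nmosd_non = 10, n_nmosd_on = 10,
                             edss_dbox_corr = 0, seed = s)
    r <- correlate(generate_cohort(cfg), "edss", "dbox_true",
                   unit = "subject", layer = "SCP")$r
    atanh(r)
  })
  # pooled Fisher-z mean should sit within its own 95% CI of zero
  expect_lt(abs(mean(z)) / (sd(z) / sqrt(length(z))), 1.96)
})

test_that("inter-eye correlation is realized empirically", {
  cfg <- cohort_sim_config(n_hc = 500, n_nmosd_non = 0, n_nmosd_on = 0,
                           inter_eye_corr = 0.8, seed = 11)
  tab <- generate_cohort(cfg)
  scp <- tab[tab$layer == "SCP", ]
  od <- scp$dbox_true[scp$eye == "OD"][order(scp$subject_id[scp$eye == "OD"])]
  os <- scp$dbox_true[scp$eye == "OS"][order(scp$subject_id[scp$eye == "OS"])]
  expect_lt(abs(cor(od, os) - 0.8), 0.05)
})

test_that("cohort marginals match the configuration at large n", {
  cfg <- cohort_sim_config(n_hc = 400, n_nmosd_non = 0, n_nmosd_on = 0, seed = 3)
  tab <- generate_cohort(cfg)
  for (l in c("SCP", "DCP", "WCP")) {
    x <- tab$dbox_true[tab$layer == l]
    se <- cfg$sd_dbox[[l]] / sqrt(length(x))  # conservative (ignores clustering)
    expect_lt(abs(mean(x) - cfg$mean_dbox["HC", l]), 3 * se * sqrt(2))
    expect_lt(abs(sd(x) - cfg$sd_dbox[[l]]) / cfg$sd_dbox[[l]], 0.15)
  }
})

test_that("cohort CSV round-trips", {
  tab <- generate_cohort(cohort_sim_config(n_hc = 4, n_nmosd_non = 2,
                                           n_nmosd_on = 2, seed = 6))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, f)
  back <- read_cohort_csv(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$dbox_true, tab$dbox_true)
  expect_error(read_cohort_csv({
    f2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing columns")
})
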