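# Quality filter, LogMAR conversion, correlation inference, GEE.

test_that("quality filter removes low-SQ rows and logs exclusions", {
  # roster of 46 subjects, 12 of whom fail SQ < 6 on every image
  set.seed(1)
  good <- sprintf("P%02d", 1:34)
  bad <- sprintf("P%02d", 35:46)
  tab <- data.frame(subject_id = rep(c(good, bad), each = 2),
                    eye = rep(c("OD", "OS"), 46),
                    group = "NMOSD", on_history = 0, layer = "SCP",
                    sq = c(rep(7L, 68), rep(4L, 24)))
  out <- quality_filter(tab)
  expect_equal(length(unique(out$subject_id)), 34)
  expect_equal(sort(attr(out, "removed")$subjects), sort(bad))
  expect_identical(nrow(quality_filter(tab, threshold = 0)), nrow(tab))
  expect_warning(empty <- quality_filter(tab, threshold = 99), "every row")
  expect_equal(nrow(empty), 0)
  # idempotence (up to the removal log attribute)
  expect_equal(as.data.frame(quality_filter(out)), as.data.frame(out),
               ignore_attr = TRUE)
})

test_that("LogMAR conversion handles Snellen, finger counting, passthrough", {
  expect_equal(to_logmar("20/20"), 0)
  expect_equal(to_logmar("20/200"), 1)
  expect_equal(to_logmar(list(type = "snellen", num = 20, den = 40)),
               log10(2))
  expect_equal(to_logmar("CF"), 1.85)
  expect_equal(to_logmar("CF", counting_fingers_logmar = 2.0), 2.0)
  expect_equal(to_logmar(0.3), 0.3)
  expect_error(to_logmar(list(type = "snellen", num = 0, den = 20)), "positive")
  expect_error(to_logmar("garbled"), "unrecognized")
})

test_that("p_from_r matches textbook worked examples", {
  expect_equal(p_from_r(0, 30)$p_value, 1.0)
  # frozen values computed from the closed form t = r sqrt(n-2)/sqrt(1-r^2)
  expect_equal(round(p_from_r(-0.475, 34)$p_value, 3), 0.005)
  expect_equal(round(p_from_r(0.378, 44)$p_value, 3), 0.011)
  expect_true(p_from_r(1, 10)$degenerate)
  expect_equal(p_from_r(1, 10)$p_value, 0)
  expect_error(p_from_r(0.5, 2), "n >= 3")
})

test_that("p_from_r is sign-symmetric and monotone in |r| and n", {
  rs <- seq(0.05, 0.9, by = 0.05)
  for (r in rs) expect_equal(p_from_r(r, 25)$p_value, p_from_r(-r, 25)$p_value)
  p_r <- sapply(rs, function(r) p_from_r(r, 25)$p_value)
  expect_true(all(diff(p_r) < 0))
  ns <- c(5, 10, 20, 40, 80)
  p_n <- sapply(ns, function(n) p_from_r(0.4, n)$p_value)
  expect_true(all(diff(p_n) < 0))
})

test_that("correlate recovers configured associations and flags degeneracy", {
  # homogeneous subgroup: the configured link is conditional on subgroup
  # (pooling subgroups with different means attenuates the marginal r)
  cfg <- cohort_sim_config(n_hc = 0, n_nmosd_non = 0, n_nmosd_on = 200,
                           edss_dbox_corr = -0.5, seed = 7)
  tab <- generate_cohort(cfg)
  res <- correlate(tab, "edss", "dbox_true", unit = "subject", layer = "SCP")
  ci <- tanh(atanh(res$r) + c(-1, 1) * 1.96 / sqrt(res$n - 3))
  expect_true(ci[1] <= -0.5 && -0.5 <= ci[2])
  expect_equal(res$n, 200)
  same <- correlate(tab, "edss", "edss", unit = "subject", layer = "SCP")
  expect_true(same$degenerate)
  expect_error(correlate(tab[1:2, ], "edss", "dbox_true"), "fewer than 3")
  # eye unit uses each eye separately
  eye <- correlate(tab, "edss", "dbox_true", unit = "eye", layer = "SCP")
  expect_equal(eye$n, 400)
})

test_that("GEE with singleton clusters equals robust OLS to 6 sig figs", {
  set.seed(21)
  n <- 60
  d <- data.frame(id = sprintf("s%02d", 1:n), x = rnorm(n),
                  g = sample(c("a", "b"), n, TRUE))
  d$y <- 0.5 + 0.3 * d$x + 0.2 * (d$g == "b") + rnorm(n, 0, 0.4)
  fit <- gee_fit(y ~ x + g, d, "id")
  X <- model.matrix(~ x + g, d)
  oracle <- ols_hc0(X, d$y)
  expect_equal(fit$coefficients, oracle$coefficients, tolerance = 1e-7)
  expect_equal(sqrt(diag(fit$vcov)), sqrt(diag(oracle$vcov)),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("gee_compare estimates are invariant to eye relabeling", {
  cfg <- cohort_sim_config(n_hc = 20, n_nmosd_non = 10, n_nmosd_on = 10, seed = 3)
  tab <- generate_cohort(cfg)
  a <- gee_compare(tab, outcome = "dbox_true", layer = "SCP")
  swapped <- tab
  swapped$eye <- ifelse(swapped$eye == "OD", "OS", "OD")
  b <- gee_compare(swapped, outcome = "dbox_true", layer = "SCP")
  expect_equal(a$difference, b$difference, tolerance = 1e-12)
  expect_equal(a$robust_se, b$robust_se, tolerance = 1e-12)
})

test_that("gee_compare validates groups and design", {
  tab <- generate_cohort(cohort_sim_config(n_hc = 10, n_nmosd_non = 0,
                                           n_nmosd_on = 0, seed = 4))
  expect_error(gee_compare(tab, outcome = "dbox_true", layer = "SCP"),
               "at least 2 groups")
  d <- data.frame(id = rep(1:10, each = 2), y = rnorm(20),
                  x1 = rep(1:10, each = 2))
  d$x2 <- 2 * d$x1  # collinear
  expect_error(gee_fit(y ~ x1 + x2, d, "id"), "singular")
})

test_that("exchangeable alpha is estimated near the simulated correlation", {
  cfg <- cohort_sim_config(n_hc = 300, n_nmosd_non = 0, n_nmosd_on = 0,
                           inter_eye_corr = 0.6, seed = 12)
  tab <- generate_cohort(cfg)
  scp <- tab[tab$layer == "SCP", ]
  fit <- gee_fit(dbox_true ~ 1, scp, "subject_id")
  expect_lt(abs(fit$alpha - 0.6), 0.08)
})
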