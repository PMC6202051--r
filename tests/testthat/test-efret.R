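test_that("bleed-through calibration recovers exact proportionality constants", {
  donor_only <- data.frame(f_cer = c(100, 200, 400, 150, 300),
                           f_fret = c(88, 176, 352, 132, 264))
  acceptor_only <- data.frame(f_yfp = c(100, 200, 400, 150, 300),
                              f_fret = 0.075 * c(100, 200, 400, 150, 300))
  cal <- calibrate_bleedthrough(donor_only, acceptor_only)
  expect_equal(cal$d, 0.88)
  expect_equal(cal$a, 0.075)
  expect_equal(cal$g_factor, 4.74)

  # zero-crosstalk controls
  zero <- calibrate_bleedthrough(
    data.frame(f_cer = c(100, 200, 300, 400, 500), f_fret = rep(0, 5)),
    data.frame(f_yfp = c(100, 200, 300, 400, 500), f_fret = rep(0, 5)))
  expect_equal(zero$a, 0)
  expect_equal(zero$d, 0)

  expect_error(
    calibrate_bleedthrough(donor_only[1:3, ], acceptor_only), "at least 5")
})

test_that("per-cell efficiency: arithmetic oracle, null, monotonicity, scale invariance", {
  cal <- fret_calibration(a = 0.075, d = 0.88, g_factor = 4.74)

  # frozen single-step arithmetic: fc = 200 - 15 - 88 = 97; e = 97/571
  e1 <- compute_efficiency(
    data.frame(cell_id = "c1", f_cer = 100, f_yfp = 200, f_fret = 200), cal)
  expect_equal(e1$fc, 97)
  expect_equal(e1$e, 97 / 571)

  # pure bleed-through: fc = 0, e = 0
  e0 <- compute_efficiency(
    data.frame(cell_id = "c0", f_cer = 100, f_yfp = 200,
               f_fret = 0.075 * 200 + 0.88 * 100), cal)
  expect_equal(e0$fc, 0)
  expect_equal(e0$e, 0)

  # e strictly increasing in f_fret, other channels fixed
  ff <- seq(100, 400, by = 25)
  es <- compute_efficiency(
    data.frame(cell_id = as.character(ff), f_cer = 100, f_yfp = 200,
               f_fret = ff), cal)$e
  expect_true(all(diff(es) > 0))

  # scale invariance: multiplying all three channels leaves e unchanged
  base <- data.frame(cell_id = "c", f_cer = 120, f_yfp = 340, f_fret = 310)
  for (k in c(0.1, 3, 1000)) {
    scaled <- base
    scaled[, 2:4] <- scaled[, 2:4] * k
    expect_equal(compute_efficiency(scaled, cal)$e,
                 compute_efficiency(base, cal)$e)
  }

  # non-positive donor cells are excluded with a message
  expect_message(
    out <- compute_efficiency(
      data.frame(cell_id = c("a", "b"), f_cer = c(-5, 100),
                 f_yfp = 200, f_fret = 200), cal),
    "excluded 1")
  expect_identical(nrow(out), 1L)
})

test_that("binding-curve fit: exact on noiseless hyperbola, matches grid-search oracle with noise", {
  # noiseless points straight off the model
  x <- exp(seq(log(2), log(2000), length.out = 60))
  e <- 0.25 * x / (80 + x)
  fit <- fit_binding_curve(data.frame(e = e, x = x), bootstrap_n = 0)
  expect_equal(fit$fret_max, 0.25, tolerance = 1e-8)
  expect_equal(fit$kd, 80, tolerance = 1e-8)
  # x = kd gives e = fret_max/2 on the fitted curve by construction
  expect_equal(fit$fret_max * fit$kd / (fit$kd + fit$kd), fit$fret_max / 2)

  # noisy population: NLS optimum within one grid cell of a dense grid search
  pop <- gen_fret_population(n_cells = 600, fret_max = 0.3, kd = 50,
                             noise_cv = 0.1, seed = 21)
  effs <- compute_efficiency(pop)
  fit <- fit_binding_curve(effs, bootstrap_n = 0)
  keep <- effs$e >= -0.5 & effs$e <= 1
  or <- oracle_grid_hyperbola(effs$x[keep], effs$e[keep])
  expect_lt(abs(fit$fret_max - or$fret_max), or$f_step)
  expect_lt(abs(log(fit$kd / or$kd)), log(or$k_ratio))
  expect_lte(fit$rss, or$rss + 1e-9)

  expect_error(fit_binding_curve(data.frame(e = e[1:5], x = x[1:5])),
               "at least 10")
})

test_that("bootstrap interval covers the generating FRET_max of a reference-scale population", {
  # population generated at the PLN-SERCA2a plateau efficiency (29.9%)
  pop <- gen_fret_population(n_cells = 1000, fret_max = 0.299, kd = 60,
                             noise_cv = 0.1, seed = 33)
  fit <- fit_binding_curve(compute_efficiency(pop), bootstrap_n = 200,
                           seed = 4)
  expect_true(abs(fit$fret_max - 0.299) <= 1.96 * fit$fret_max_se)
  expect_gt(fit$fret_max_se, 0)
})

test_that("affinity comparison reproduces the textbook t-test and handles nulls", {
  cmp <- compare_affinity(c(10, 12, 11, 13), c(20, 22, 21, 23),
                          labels = c("fast", "slow"))
  expect_equal(cmp$t, oracle_pooled_t(c(10, 12, 11, 13), c(20, 22, 21, 23)),
               tolerance = 1e-12)
  expect_equal(abs(cmp$t), 10.954451, tolerance = 1e-6)
  expect_identical(cmp$df, 6)
  expect_lt(cmp$p, 0.001)
  expect_identical(cmp$higher_affinity, "fast")
  expect_identical(cmp$n, c(4L, 4L))  # 4 experiments per construct

  # same values up to permutation: no difference
  null <- compare_affinity(c(10, 12, 11, 13), c(13, 10, 12, 11))
  expect_equal(null$mean[1], null$mean[2])
  expect_identical(null$tier, "")
  expect_true(is.na(null$higher_affinity))
})
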