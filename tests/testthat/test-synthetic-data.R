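test_that("FRET population generator inverts exactly and is seed-deterministic", {
  pop <- gen_fret_population(n_cells = 1000, fret_max = 0.3, kd = 50,
                             noise_cv = 0, background = 0, seed = 11)
  expect_identical(nrow(pop), 1000L)  # the per-experiment sampling scale
  truth <- attr(pop, "truth")
  effs <- compute_efficiency(pop, fret_calibration())
  expect_lt(max(abs(effs$e - truth$e_true)), 1e-10)

  # identical seed, identical table
  pop2 <- gen_fret_population(n_cells = 1000, fret_max = 0.3, kd = 50,
                              noise_cv = 0, background = 0, seed = 11)
  expect_identical(pop, pop2)

  expect_error(gen_fret_population(fret_max = 1), "fret_max")
  expect_error(gen_fret_population(kd = 0), "kd")
})

test_that("bleaching generator: null interaction, 1:1 linearity, enumeration oracle", {
  # no FRET: donor constant across steps
  bs <- gen_bleach_series(e_pair = 0, noise_cv = 0, seed = 1)
  expect_true(all(bs$f_donor == bs$f_donor[1]))

  # 1:1 expected trajectory is exactly collinear
  exp1 <- gen_bleach_series(acceptors_per_donor = 1, e_pair = 0.3,
                            expected = TRUE)
  fit <- lm(f_donor ~ f_acceptor, data = exp1)
  expect_lt(sum(residuals(fit)^2), 1e-18 * sum(exp1$f_donor^2))

  # oligomer expectation matches exhaustive binomial enumeration
  exp5 <- gen_bleach_series(n_steps = 10, bleach_rate = 0.25, e_pair = 0.3,
                            acceptors_per_donor = 5, n_complexes = 300,
                            expected = TRUE)
  or <- oracle_bleach_expectation(10, 0.25, 0.3, k = 5, n_complexes = 300)
  expect_equal(exp5$f_donor, or$f_donor, tolerance = 1e-12)
  expect_equal(exp5$f_acceptor, or$f_acceptor, tolerance = 1e-12)

  # determinism and validation
  expect_identical(gen_bleach_series(seed = 7), gen_bleach_series(seed = 7))
  expect_error(gen_bleach_series(n_steps = 2), "n_steps")
})

test_that("transient generator honours its closed form and the pacing rate", {
  tr <- gen_transient_trace(baseline = 1, amplitude = 0.5, tau = 0.25,
                            pacing_hz = 0.5, noise_sd = 0, seed = 2)
  expect_equal(max(tr$ratio) - 1, 0.5)

  # log of the decay phase is linear with slope -1/tau
  one_decay <- tr[tr$t > 0.15 & tr$t < 1.9, ]
  sl <- coef(lm(log(ratio - 1) ~ t, data = one_decay))[2]
  expect_equal(unname(sl), -1 / 0.25, tolerance = 1e-9)

  # 0.5 Hz pacing: peaks 2 s apart
  pk_t <- tr$t[abs(tr$ratio - max(tr$ratio)) < 1e-9]
  expect_equal(unique(round(diff(pk_t), 6)), 2)

  expect_error(gen_transient_trace(duration = 1, pacing_hz = 0.5), "duration")
})

test_that("uptake generator half-max identity and grid validation", {
  grid <- sort(c(uptake_ca_grid(), 0.25))
  cu <- gen_uptake_curve(vmax = 60, k_ca = 0.25, hill = 2, ca_grid = grid,
                         noise_cv = 0)
  expect_equal(cu$rate[cu$ca_free == 0.25], 30)
  expect_equal(range(uptake_ca_grid()), c(0.02, 5))
  expect_error(gen_uptake_curve(k_ca = 10), "k_ca")       # outside grid span
  expect_error(gen_uptake_curve(ca_grid = numeric(0)), "ca_grid")
})

test_that("echo cohort generator reproduces configured means at zero SD", {
  params <- default_echo_params()[c("WT", "MLP KO")]
  for (g in names(params)) params[[g]]$sd[] <- 0
  coh <- gen_echo_cohort(params, n_per_group = 3, seed = 5)
  expect_identical(nrow(coh), 6L)
  wt <- coh[coh$genotype == "WT", ]
  expect_true(all(wt$e_mm_s == 569.7))
  expect_true(all(wt$hr_bpm == 465.7))
  mlp <- coh[coh$genotype == "MLP KO", ]
  expect_true(all(mlp$eprime_mm_s == 15.1))
  expect_error(gen_echo_cohort(list()), "named list")
  expect_error(gen_echo_cohort(n_per_group = 0), "at least one animal")
})
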