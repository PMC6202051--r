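test_that("transient analysis is exact on noiseless traces and matches the log-linear oracle with noise", {
  tr <- gen_transient_trace(baseline = 1, amplitude = 0.5, tau = 0.2,
                            noise_sd = 0, seed = 1)
  m <- analyze_transient(tr)
  expect_lt(abs(m$tau - 0.2), 1e-6)
  expect_equal(m$amplitude, 0.5, tolerance = 1e-9)
  expect_equal(m$baseline, 1, tolerance = 1e-9)
  expect_equal(m$period, 2, tolerance = 1e-9)

  # log-linear oracle on the noiseless decay gives the same constant the
  # noisy fit must approach (SNR 20)
  dec <- tr[tr$t > 0.16 & tr$t < 1.9, ]
  tau_or <- oracle_loglinear_tau(dec$t, dec$ratio, baseline = 1)
  trn <- gen_transient_trace(baseline = 1, amplitude = 0.5, tau = 0.2,
                             noise_sd = 0.025, seed = 8)
  mn <- analyze_transient(trn)
  expect_lt(abs(mn$tau - tau_or) / tau_or, 0.02)

  # both fitting modes agree at this noise level
  mb <- analyze_transient(trn, mode = "beat")
  expect_lt(abs(mb$tau - mn$tau) / mn$tau, 0.05)

  # constant trace: no transient
  flat <- data.frame(t = seq(0, 5, by = 0.005), ratio = 1)
  expect_error(analyze_transient(flat), "no transient")
})

test_that("beat segmentation is invariant to where the recording starts", {
  tr <- gen_transient_trace(amplitude = 0.5, tau = 0.25, duration = 12,
                            noise_sd = 0.01, seed = 5)
  tau_full <- analyze_transient(tr)$tau
  # drop a non-integer fraction of the pacing period (0.73 s of a 2 s cycle)
  shifted <- tr[tr$t >= 0.73, ]
  tau_shift <- analyze_transient(shifted)$tau
  expect_lt(abs(tau_shift - tau_full) / tau_full, 0.01)
})

test_that("shortening analysis: arithmetic, flat channel, scale invariance, tau recovery", {
  tr <- gen_transient_trace(sl_rest = 1.80, sl_fs = 0.10, tau = 0.25,
                            noise_sd = 0, seed = 2)
  s <- analyze_shortening(tr)
  # sl_rest 1.80, sl_min 1.62 -> 10%
  expect_equal(s$fs_pct, 10, tolerance = 1e-6)
  expect_equal(s$sl_min, 1.62, tolerance = 1e-6)
  expect_equal(s$relax_tau_sl, 0.25, tolerance = 1e-4)
  expect_gt(s$max_shortening_rate, 0)
  expect_gt(s$max_relengthening_rate, 0)

  # fs is invariant to rescaling the length channel
  tr_scaled <- tr
  tr_scaled$sl <- tr$sl * 2  # outside the 1-3 um physiological band
  expect_warning(s2 <- analyze_shortening(tr_scaled), "non-physiological")
  expect_equal(s2$fs_pct, s$fs_pct, tolerance = 1e-9)

  # flat channel: zero shortening, zero rates, no error
  flat <- tr
  flat$sl <- 1.8
  s0 <- analyze_shortening(flat)
  expect_equal(s0$fs_pct, 0)
  expect_equal(s0$max_shortening_rate, 0)

  expect_error(analyze_shortening(data.frame(t = 1:100 / 100, ratio = 1)),
               "missing")
})

test_that("cell summaries average animals first and reproduce the textbook t-test", {
  # 3 animals x 12 cells per group; within-animal replication collapses to n=3
  mk_group <- function(geno, animal_means) {
    do.call(rbind, lapply(seq_along(animal_means), function(a) {
      data.frame(cell_id = sprintf("%s_a%d_c%d", geno, a, 1:12),
                 amplitude = animal_means[a] + seq(-0.11, 0.11, length.out = 12),
                 animal_id = sprintf("%s_a%d", geno, a), genotype = geno)
    }))
  }
  g1 <- mk_group("WT", c(10, 12, 11))
  g2 <- mk_group("TG", c(20, 22, 21))
  metrics <- rbind(g1[c("cell_id", "amplitude")], g2[c("cell_id", "amplitude")])
  meta <- rbind(g1[c("cell_id", "animal_id", "genotype")],
                g2[c("cell_id", "animal_id", "genotype")])
  out <- summarize_cells(metrics, meta, reference = "WT")
  expect_identical(unique(out$group_summary$n_animals), 3L)
  # centered within-animal offsets leave the per-animal means exact
  expect_equal(out$tests$t, oracle_pooled_t(c(20, 22, 21), c(10, 12, 11)),
               tolerance = 1e-9)
  expect_match(out$tests$tier, "\\*{3,4}")

  # identical groups: nothing significant
  g3 <- mk_group("TG", c(10, 12, 11))
  metrics0 <- rbind(g1[c("cell_id", "amplitude")], g3[c("cell_id", "amplitude")])
  meta0 <- rbind(g1[c("cell_id", "animal_id", "genotype")],
                 g3[c("cell_id", "animal_id", "genotype")])
  out0 <- summarize_cells(metrics0, meta0, reference = "WT")
  expect_identical(out0$tests$tier, "")

  expect_error(summarize_cells(metrics, meta, reference = "nope"),
               "unknown reference")
})
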