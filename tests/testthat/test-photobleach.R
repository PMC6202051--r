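make_series <- function(donor, acceptor) {
  data.frame(sample_id = "s", step = seq_along(donor), f_donor = donor,
             f_acceptor = acceptor)
}

test_that("photobleach FRET arithmetic and sign convention", {
  # no dequenching
  s <- make_series(rep(100, 6), c(100, 100, 60, 30, 5, 0))
  expect_equal(compute_pb_fret(s)$fret_pb, 0)

  # f_da = 70, f_d = 100 -> 0.30
  s <- make_series(c(70, 70, 85, 95, 100, 100), c(100, 100, 60, 30, 5, 0))
  r <- compute_pb_fret(s)
  expect_equal(r$fret_pb, 0.30)
  expect_false(r$flagged)

  # noise pushes pre-bleach above post-bleach: negative, flagged, not clamped
  s <- make_series(c(101, 102, 100, 99, 100, 99), c(100, 100, 60, 30, 5, 0))
  r <- compute_pb_fret(s)
  expect_lt(r$fret_pb, 0)
  expect_true(r$flagged)

  # donor still rising sharply at the end: incomplete bleach
  s <- make_series(c(70, 70, 75, 80, 85, 95), c(100, 100, 80, 60, 40, 20))
  expect_error(compute_pb_fret(s), "incomplete bleach")
})

test_that("stoichiometry classifier separates linear, curved and flat trajectories", {
  # perfectly collinear with negative slope: 1:1, no curvature evidence
  acc <- seq(100, 10, length.out = 8)
  s <- make_series(200 - 0.5 * acc, acc)
  call <- classify_stoichiometry(s)
  expect_identical(call$call, "one_to_one")
  expect_equal(call$linear_r2, 1)
  expect_equal(call$curvature_p, 1)
  expect_identical(call$slope_sign, "-")

  # pentamer-like generator trajectory matches the enumeration-oracle curvature
  s5 <- gen_bleach_series(n_steps = 12, bleach_rate = 0.25, e_pair = 0.3,
                          acceptors_per_donor = 5, noise_cv = 0.02, seed = 14)
  expect_identical(classify_stoichiometry(s5)$call, "higher_order")
  or <- oracle_bleach_expectation(12, 0.25, 0.3, k = 5, n_complexes = 500)
  expect_identical(classify_stoichiometry(cbind(sample_id = "o", or))$call,
                   "higher_order")

  # flat donor (no interaction)
  s0 <- gen_bleach_series(n_steps = 12, e_pair = 0, noise_cv = 0.02, seed = 3)
  expect_identical(classify_stoichiometry(s0)$call, "no_fret")

  # shallow bleach rejected
  sb <- make_series(100 + seq(0, 7), seq(100, 90, length.out = 8))
  expect_error(classify_stoichiometry(sb), "insufficient bleach depth")
  expect_error(classify_stoichiometry(s[1:5, ]), "at least 6")
})

test_that("oligomer detection across replicate series", {
  # monomeric peptide probed against itself: no FRET anywhere
  null_sets <- lapply(1:4, function(i)
    gen_bleach_series(e_pair = 0, noise_cv = 0.02, seed = 40 + i))
  null_sum <- detect_oligomer_fret(null_sets)
  expect_identical(null_sum$present, "absent")

  # pentameric sets: FRET present with higher-order majority
  pent_sets <- lapply(1:4, function(i)
    gen_bleach_series(n_steps = 12, bleach_rate = 0.25, e_pair = 0.3,
                      acceptors_per_donor = 4, noise_cv = 0.02,
                      seed = 50 + i))
  pent_sum <- detect_oligomer_fret(pent_sets)
  expect_identical(pent_sum$present, "present")
  expect_identical(pent_sum$majority_call, "higher_order")
  expect_lt(pent_sum$p, 0.05)

  # degenerate zero-variance null: p reported as 1 with a note
  flat <- make_series(rep(100, 8), seq(100, 10, length.out = 8))
  zero_sum <- detect_oligomer_fret(list(flat, flat, flat))
  expect_identical(zero_sum$present, "absent")
  expect_equal(zero_sum$p, 1)
  expect_match(zero_sum$note, "p set to 1")

  expect_error(detect_oligomer_fret(null_sets[1:2]), "at least 3")
})
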