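test_that("systolic indices follow the M-mode formulas exactly", {
  rec <- data.frame(lvid_d_mm = 4.0, lvid_s_mm = 2.8, edv_ul = 70,
                    esv_ul = 25)
  out <- compute_systolic(rec)
  expect_equal(out$fs_pct, 30)
  expect_equal(out$ef_pct, (70 - 25) / 70 * 100)

  # no contraction
  same <- data.frame(lvid_d_mm = 4, lvid_s_mm = 4, edv_ul = 70, esv_ul = 25)
  expect_equal(compute_systolic(same)$fs_pct, 0)

  # invariance under unit rescaling (mm -> cm, uL -> mL)
  scaled <- rec
  scaled$lvid_d_mm <- rec$lvid_d_mm / 10
  scaled$lvid_s_mm <- rec$lvid_s_mm / 10
  scaled$edv_ul <- rec$edv_ul / 1000
  scaled$esv_ul <- rec$esv_ul / 1000
  expect_equal(compute_systolic(scaled)$fs_pct, out$fs_pct)
  expect_equal(compute_systolic(scaled)$ef_pct, out$ef_pct)

  bad <- data.frame(lvid_d_mm = 3, lvid_s_mm = 3.5, edv_ul = 70, esv_ul = 25)
  expect_error(compute_systolic(bad), "non-physiological")
})

test_that("diastolic ratios: per-animal and group-mean conventions", {
  wt <- data.frame(e_mm_s = 569.7, a_mm_s = 408.0, eprime_mm_s = 25.6)
  out <- compute_diastolic(wt)
  expect_equal(round(out$e_over_a, 1), 1.4)
  expect_equal(round(out$e_over_eprime, 1), 22.3)

  ident <- data.frame(e_mm_s = 500, a_mm_s = 500, eprime_mm_s = 25)
  expect_equal(compute_diastolic(ident)$e_over_a, 1)

  grp <- data.frame(genotype = rep("WT", 2), e_mm_s = c(560, 580),
                    a_mm_s = c(400, 416), eprime_mm_s = c(25, 26.2))
  gm <- compute_diastolic(grp, mode = "group_means")
  expect_equal(gm$e_over_a, round(570 / 408, 1))

  expect_error(compute_diastolic(
    data.frame(e_mm_s = 500, a_mm_s = 0, eprime_mm_s = 25)), "denominator")
})

test_that("significance tiers and the group summary table", {
  expect_identical(tier_symbol(0.03), "*")
  expect_identical(tier_symbol(0.004), "***")
  expect_identical(tier_symbol(0.0005), "****")
  expect_identical(tier_symbol(0.2), "")
  expect_identical(tier_symbol(0.0005, "#"), "####")

  set.seed(3)
  records <- data.frame(
    animal_id = sprintf("a%02d", 1:12),
    genotype = rep(c("WT", "KO", "KO/Tg"), each = 4),
    val = c(10, 12, 11, 13, 20, 22, 21, 23, 11, 13, 12, 10))
  sg <- summarize_groups(records, metrics = "val", reference = "WT")
  ko <- sg$tests[sg$tests$genotype == "KO", ]
  expect_equal(abs(ko$t), 10.954451, tolerance = 1e-6)
  expect_identical(ko$tier, "****")

  # dual-reference annotation: '*' vs first reference, '#' vs second
  sg2 <- summarize_groups(records, metrics = "val",
                          reference = c("WT", "KO"))
  kt <- sg2$table[sg2$table$genotype == "KO/Tg", ]
  expect_match(kt$annotation, "#")  # differs from KO
  expect_false(grepl("\\*", kt$annotation))  # similar to WT

  # identical groups carry no symbol
  null_rec <- data.frame(animal_id = sprintf("b%02d", 1:8),
                         genotype = rep(c("WT", "KO"), each = 4),
                         val = rep(c(10, 12, 11, 13), 2))
  sg0 <- summarize_groups(null_rec, metrics = "val", reference = "WT")
  expect_true(all(sg0$table$annotation == ""))

  expect_error(summarize_groups(records, metrics = "val", reference = "ZZ"),
               "unknown reference")
})
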