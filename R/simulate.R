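# Forward models for every measurement modality the analysis modules consume.
# Each generator is exactly invertible at zero noise and deterministic under
# its seed, so the matched estimator can be tested against known ground truth.

#' Simulate a FRET-vs-expression cell population
#'
#' Forward model for acceptor-sensitization (three-cube) E-FRET screening of a
#' transfected cell population, of the kind used to measure the apparent
#' affinity of SERCA for fluorescently tagged micropeptides. Per cell, a donor
#' amount `D` (normal, truncated at 0) and an acceptor expression level `X`
#' (log-normal, spanning the low-to-high expression sweep a binding-curve fit
#' requires) are drawn; the true efficiency follows the hyperbola
#' `E = fret_max * X / (kd + X)`. Channels are constructed by exact inversion
#' of the E-FRET equations:
#' `F_Cer = D * (1 - E)`, sensitized emission `Fc = g_factor * F_Cer * E /
#' (1 - E)`, `F_YFP = X`, and `F_FRET = Fc + a * F_YFP + d * F_Cer`.
#' Multiplicative Gaussian noise (CV = `noise_cv`) and additive background are
#' applied last, after the exact optical model.
#'
#' @param n_cells number of cells (the reference experiments imaged ~1000
#'   cells per sample).
#' @param fret_max intrinsic FRET of the bound complex, in `[0, 1)`.
#' @param kd apparent dissociation constant in acceptor-expression units (AU).
#' @param donor_mean,donor_cv donor expression mean (AU) and CV.
#' @param acceptor_log_mean,acceptor_log_sd log-normal parameters of acceptor
#'   expression (natural log of AU).
#' @param bleedthrough_a,bleedthrough_d acceptor and donor bleed-through
#'   fractions into the FRET channel.
#' @param g_factor ratio of sensitized emission to donor dequenching.
#' @param noise_cv multiplicative noise CV applied to each channel.
#' @param background additive background (AU) applied to each channel.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `cell_id`, `f_cer`, `f_yfp`, `f_fret`;
#'   the ground truth (`cell_id`, `e_true`, `x`, `donor`) is attached as the
#'   `"truth"` attribute (sidecar table).
#' @examples
#' pop <- gen_fret_population(n_cells = 100, noise_cv = 0, seed = 1)
#' head(attr(pop, "truth"))
#' @export
gen_fret_population <- function(n_cells = 1000, fret_max = 0.3, kd = 50,
                                donor_mean = 1000, donor_cv = 0.3,
                                acceptor_log_mean = log(50),
                                acceptor_log_sd = 1.2,
                                bleedthrough_a = 0.075, bleedthrough_d = 0.88,
                                g_factor = 4.74, noise_cv = 0.1,
                                background = 0, seed = 1) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(fret_max, "fret_max", lower = 0, upper = 1, allow_upper = FALSE)
  check_number(kd, "kd", lower = 0, allow_lower = FALSE)
  check_number(donor_mean, "donor_mean", lower = 0, allow_lower = FALSE)
  check_number(donor_cv, "donor_cv", lower = 0)
  check_number(acceptor_log_sd, "acceptor_log_sd", lower = 0)
  check_number(bleedthrough_a, "bleedthrough_a", lower = 0)
  check_number(bleedthrough_d, "bleedthrough_d", lower = 0)
  check_number(g_factor, "g_factor", lower = 0, allow_lower = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(background, "background", lower = 0)

  set.seed(seed)
  donor <- stats::rnorm(n_cells, donor_mean, donor_mean * donor_cv)
  for (i in seq_len(100)) {           # truncate at 0 by redraw
    neg <- donor <= 0
    if (!any(neg)) break
    donor[neg] <- stats::rnorm(sum(neg), donor_mean, donor_mean * donor_cv)
  }
  if (any(donor <= 0) || any(!is.finite(donor)))
    stop_bad_arg("non-positive or non-finite donor draws; check donor_mean/donor_cv")
  x <- stats::rlnorm(n_cells, acceptor_log_mean, acceptor_log_sd)
  if (any(!is.finite(x)))
    stop_bad_arg("non-finite acceptor draws; check acceptor_log_mean/acceptor_log_sd")

  e_true <- fret_max * x / (kd + x)
  f_cer  <- donor * (1 - e_true)
  fc     <- g_factor * f_cer * e_true / (1 - e_true)
  f_yfp  <- x
  f_fret <- fc + bleedthrough_a * f_yfp + bleedthrough_d * f_cer

  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    f_cer  = apply_noise_cv(f_cer, noise_cv) + background,
    f_yfp  = apply_noise_cv(f_yfp, noise_cv) + background,
    f_fret = apply_noise_cv(f_fret, noise_cv) + background,
    stringsAsFactors = FALSE)
  attr(cells, "truth") <- data.frame(
    cell_id = cells$cell_id, e_true = e_true, x = x, donor = donor,
    stringsAsFactors = FALSE)
  attr(cells, "params") <- list(
    n_cells = n_cells, fret_max = fret_max, kd = kd,
    donor_mean = donor_mean, donor_cv = donor_cv,
    acceptor_log_mean = acceptor_log_mean, acceptor_log_sd = acceptor_log_sd,
    bleedthrough_a = bleedthrough_a, bleedthrough_d = bleedthrough_d,
    g_factor = g_factor, noise_cv = noise_cv, background = background,
    seed = seed)
  cells
}

#' Simulate a progressive acceptor-photobleaching trajectory
#'
#' Forward model for progressive acceptor photobleaching of donor/acceptor
#' labelled complexes. After `n_baseline` pre-bleach frames, each surviving
#' acceptor independently bleaches with probability `bleach_rate` per step. A
#' donor with `j` unbleached partners transfers with efficiency
#' `1 - (1 - e_pair)^j`; the donor channel sums `1 - E` over complexes and the
#' acceptor channel is proportional to the unbleached acceptor count.
#' `acceptors_per_donor = 1` gives an exactly linear expected donor-vs-acceptor
#' relation; `>= 2` (an oligomer) gives a convex one, which is what the
#' stoichiometry classifier exploits.
#'
#' @param n_steps number of bleaching steps (>= 3).
#' @param bleach_rate per-step bleaching probability of a surviving acceptor.
#' @param e_pair per-acceptor FRET efficiency, in `[0, 1)`.
#' @param acceptors_per_donor acceptors bound to each donor (1 for a 1:1
#'   complex, 4 for a donor inside a pentamer, 0 for no interaction partner).
#' @param n_complexes number of donor-containing complexes in the cell.
#' @param noise_cv multiplicative measurement noise CV.
#' @param seed integer RNG seed.
#' @param n_baseline pre-bleach baseline frames (no photobleaching).
#' @param sample_id identifier carried into the output table.
#' @param expected if `TRUE`, return the noiseless expected trajectory
#'   (binomial survival in expectation) instead of a stochastic realisation.
#' @return A data.frame with columns `sample_id`, `step`, `f_donor`,
#'   `f_acceptor`, with the generating parameters in the `"params"` attribute.
#' @export
gen_bleach_series <- function(n_steps = 12, bleach_rate = 0.25, e_pair = 0.3,
                              acceptors_per_donor = 1, n_complexes = 500,
                              noise_cv = 0.02, seed = 1, n_baseline = 2,
                              sample_id = "sample1", expected = FALSE) {
  n_steps <- check_count(n_steps, "n_steps", min = 3L)
  check_number(bleach_rate, "bleach_rate", lower = 0, upper = 1)
  check_number(e_pair, "e_pair", lower = 0, upper = 1, allow_upper = FALSE)
  acceptors_per_donor <- check_count(acceptors_per_donor,
                                     "acceptors_per_donor", min = 0L)
  n_complexes <- check_count(n_complexes, "n_complexes")
  check_number(noise_cv, "noise_cv", lower = 0)
  n_baseline <- check_count(n_baseline, "n_baseline", min = 1L)

  k <- acceptors_per_donor
  total_steps <- n_baseline + n_steps
  f_donor <- f_acceptor <- numeric(total_steps)

  if (expected) {
    # per-acceptor survival probability q at each frame
    bleach_idx <- pmax(seq_len(total_steps) - n_baseline, 0)
    q <- (1 - bleach_rate)^bleach_idx
    f_donor <- n_complexes * (1 - q * e_pair)^k
    f_acceptor <- n_complexes * k * q
  } else {
    set.seed(seed)
    alive <- rep(k, n_complexes)
    for (s in seq_len(total_steps)) {
      if (s > n_baseline)
        alive <- stats::rbinom(n_complexes, alive, 1 - bleach_rate)
      f_donor[s] <- sum((1 - e_pair)^alive)
      f_acceptor[s] <- sum(alive)
    }
    f_donor <- apply_noise_cv(f_donor, noise_cv)
    f_acceptor <- apply_noise_cv(f_acceptor, noise_cv)
  }
  out <- data.frame(sample_id = sample_id, step = seq_len(total_steps),
                    f_donor = f_donor, f_acceptor = f_acceptor,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(
    n_steps = n_steps, bleach_rate = bleach_rate, e_pair = e_pair,
    acceptors_per_donor = k, n_complexes = n_complexes, noise_cv = noise_cv,
    seed = seed, n_baseline = n_baseline, expected = expected)
  out
}

#' Simulate a paced cardiomyocyte Ca2+ transient and shortening trace
#'
#' Forward model for field-paced, Fura-2 loaded cardiomyocyte recordings.
#' Each pacing cycle holds the baseline for `stim_delay` seconds, rises
#' linearly to `baseline + amplitude` over `rise_time`, then decays as
#' `baseline + amplitude * exp(-t/tau)`. The sarcomere-length channel mirrors
#' the transient: `sl = sl_rest * (1 - sl_fs * shape)`, so its relaxation time
#' constant equals `tau`. Gaussian noise of sd `noise_sd` is added to the
#' ratio channel and `sl_noise_sd` (um) to the length channel.
#'
#' @param baseline resting Fura-2 340/380 ratio.
#' @param amplitude peak-minus-baseline transient amplitude (ratio units).
#' @param tau decay time constant (s).
#' @param pacing_hz pacing frequency (Hz); myocyte experiments here pace at
#'   0.5 Hz.
#' @param rise_time upstroke duration (s).
#' @param duration total recording length (s); must exceed one pacing period.
#' @param dt sample interval (s).
#' @param sl_rest resting sarcomere length (um).
#' @param sl_fs peak fractional shortening of the sarcomere, in `[0, 1)`.
#' @param noise_sd Gaussian noise sd on the ratio channel.
#' @param sl_noise_sd Gaussian noise sd on the length channel (um).
#' @param seed integer RNG seed.
#' @param stim_delay pre-stimulus baseline within each cycle (s).
#' @param cell_id identifier carried into the output table.
#' @return A data.frame with columns `cell_id`, `t`, `ratio`, `sl`; generating
#'   parameters attached as the `"params"` attribute.
#' @export
gen_transient_trace <- function(baseline = 1.0, amplitude = 0.5, tau = 0.25,
                                pacing_hz = 0.5, rise_time = 0.05,
                                duration = 10, dt = 0.005,
                                sl_rest = 1.8, sl_fs = 0.10,
                                noise_sd = 0, sl_noise_sd = noise_sd * 0.1,
                                seed = 1, stim_delay = 0.1,
                                cell_id = "cell1") {
  check_number(baseline, "baseline")
  check_number(amplitude, "amplitude", lower = 0)
  check_number(tau, "tau", lower = 0, allow_lower = FALSE)
  check_number(pacing_hz, "pacing_hz", lower = 0, allow_lower = FALSE)
  check_number(rise_time, "rise_time", lower = 0, allow_lower = FALSE)
  check_number(dt, "dt", lower = 0, allow_lower = FALSE)
  check_number(duration, "duration", lower = 1 / pacing_hz,
               allow_lower = FALSE)
  check_number(sl_rest, "sl_rest", lower = 0, allow_lower = FALSE)
  check_number(sl_fs, "sl_fs", lower = 0, upper = 1, allow_upper = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sl_noise_sd, "sl_noise_sd", lower = 0)
  check_number(stim_delay, "stim_delay", lower = 0)

  t <- seq(0, duration, by = dt)
  period <- 1 / pacing_hz
  phase <- t %% period
  shape <- numeric(length(t))
  rising <- phase >= stim_delay & phase < stim_delay + rise_time
  decaying <- phase >= stim_delay + rise_time
  shape[rising] <- (phase[rising] - stim_delay) / rise_time
  shape[decaying] <- exp(-(phase[decaying] - stim_delay - rise_time) / tau)

  set.seed(seed)
  ratio <- baseline + amplitude * shape +
    if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  sl <- sl_rest * (1 - sl_fs * shape) +
    if (sl_noise_sd > 0) stats::rnorm(length(t), 0, sl_noise_sd) else 0

  out <- data.frame(cell_id = cell_id, t = t, ratio = ratio, sl = sl,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(
    baseline = baseline, amplitude = amplitude, tau = tau,
    pacing_hz = pacing_hz, rise_time = rise_time, duration = duration,
    dt = dt, sl_rest = sl_rest, sl_fs = sl_fs, noise_sd = noise_sd,
    sl_noise_sd = sl_noise_sd, seed = seed, stim_delay = stim_delay)
  out
}

#' Default free-Ca2+ grid for uptake assays
#'
#' Log-spaced grid spanning the 0.02-5 uM free Ca2+ range used in
#' oxalate-supported Ca2+-uptake assays.
#'
#' @param n number of concentrations.
#' @param from,to grid endpoints (uM).
#' @return Increasing numeric vector of length `n`.
#' @export
uptake_ca_grid <- function(n = 8, from = 0.02, to = 5) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate an oxalate-supported Ca2+-uptake curve
#'
#' Generates rate-vs-free-Ca2+ points from the cooperative activation model
#' `V(ca) = vmax / (1 + (k_ca / ca)^hill)` with multiplicative noise.
#'
#' @param vmax maximal uptake rate (nmol/mg/min scale; units are carried
#'   through, not interpreted).
#' @param k_ca free Ca2+ at half-maximal rate (uM); must lie inside the span
#'   of `ca_grid`.
#' @param hill Hill coefficient (> 0); cardiac SERCA activation is
#'   cooperative with `hill` near 2.
#' @param ca_grid strictly increasing vector of free Ca2+ concentrations (uM).
#' @param noise_cv multiplicative noise CV on rates.
#' @param seed integer RNG seed.
#' @param sample_id identifier carried into the output table.
#' @return A data.frame with columns `sample_id`, `ca_free`, `rate`;
#'   generating parameters in the `"params"` attribute.
#' @export
gen_uptake_curve <- function(vmax = 60, k_ca = 0.25, hill = 2,
                             ca_grid = uptake_ca_grid(), noise_cv = 0.05,
                             seed = 1, sample_id = "sample1") {
  check_number(vmax, "vmax", lower = 0, allow_lower = FALSE)
  check_number(hill, "hill", lower = 0, allow_lower = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (!length(ca_grid))
    stop_bad_arg("'ca_grid' must be non-empty")
  if (any(ca_grid <= 0) || any(diff(ca_grid) <= 0))
    stop_bad_arg("'ca_grid' must be strictly positive and increasing")
  check_number(k_ca, "k_ca", lower = min(ca_grid), upper = max(ca_grid))

  set.seed(seed)
  rate <- apply_noise_cv(hill_rate(ca_grid, vmax, k_ca, hill), noise_cv)
  out <- data.frame(sample_id = sample_id, ca_free = ca_grid, rate = rate,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(vmax = vmax, k_ca = k_ca, hill = hill,
                              ca_grid = ca_grid, noise_cv = noise_cv,
                              seed = seed)
  out
}

#' Default genotype parameters for synthetic echocardiography cohorts
#'
#' Group means and SDs used by [gen_echo_cohort()]. Doppler fields (E, A, E',
#' A', heart rate) follow reference murine group means for the six genotypes
#' of the dilated-cardiomyopathy rescue design (WT, DWORF KO, DWORF Tg,
#' MLP KO, MLP/DWORF dKO, MLP KO/DWORF Tg); M-mode dimensions and volumes are
#' realistic murine values chosen once: normal systolic function for WT-like
#' groups and a dilated, hypocontractile phenotype for the cardiomyopathic
#' (MLP-deficient) groups. All values parameterize a synthetic cohort; none
#' are measurements.
#'
#' @return Named list (one element per genotype) of lists with `mean` and
#'   `sd` numeric vectors over the echo record fields.
#' @export
default_echo_params <- function() {
  field_names <- c("lvid_d_mm", "lvid_s_mm", "edv_ul", "esv_ul",
                   "e_mm_s", "a_mm_s", "eprime_mm_s", "aprime_mm_s",
                   "hr_bpm")
  mk <- function(mean, sd) {
    names(mean) <- names(sd) <- field_names
    list(mean = mean, sd = sd)
  }
  list(
    "WT" = mk(
      c(3.6, 2.2, 60, 18, 569.7, 408.0, 25.6, 10.7, 465.7),
      c(0.2, 0.2, 6, 3, 39.0, 39.2, 2.4, 1.8, 22.0)),
    "DWORF KO" = mk(
      c(3.7, 2.3, 62, 20, 591.5, 432.1, 25.2, 19.3, 447.3),
      c(0.2, 0.2, 6, 3, 22.1, 61.8, 2.0, 1.4, 8.3)),
    "DWORF Tg" = mk(
      c(3.5, 2.0, 58, 14, 624.2, 443.6, 26.6, 11.8, 445.7),
      c(0.2, 0.2, 6, 3, 43.2, 81.8, 1.7, 1.3, 5.0)),
    "MLP KO" = mk(
      c(4.6, 3.8, 95, 55, 546.0, 236.9, 15.1, 14.7, 438.6),
      c(0.3, 0.3, 9, 7, 38.7, 78.1, 2.8, 2.3, 19.3)),
    "MLP/DWORF dKO" = mk(
      c(4.8, 4.1, 100, 62, 536.9, 251.2, 10.6, 13.6, 444.3),
      c(0.3, 0.3, 9, 7, 60.2, 24.6, 1.0, 1.0, 21.7)),
    "MLP KO/DWORF Tg" = mk(
      c(3.7, 2.3, 63, 20, 606.4, 492.0, 24.0, 18.7, 467.0),
      c(0.2, 0.2, 6, 3, 199.6, 182.7, 4.1, 3.1, 14.1)))
}

#' Simulate an echocardiography cohort
#'
#' Draws per-animal M-mode and Doppler measurements from genotype-specific
#' normal distributions (see [default_echo_params()]). Draws violating record
#' coherence (diastolic dimension/volume at least the systolic one, positive
#' velocities) are rejected and redrawn, so the marginals are mildly
#' truncated where a group's SD is large relative to its systolic reserve.
#'
#' @param genotype_params named list as returned by [default_echo_params()];
#'   may be any subset of genotypes.
#' @param n_per_group animals per genotype (scalar or named vector).
#' @param seed integer RNG seed.
#' @return A data.frame with columns `animal_id`, `genotype`, `lvid_d_mm`,
#'   `lvid_s_mm`, `edv_ul`, `esv_ul`, `e_mm_s`, `a_mm_s`, `eprime_mm_s`,
#'   `aprime_mm_s`, `hr_bpm`.
#' @export
gen_echo_cohort <- function(genotype_params = default_echo_params(),
                            n_per_group = 5, seed = 1) {
  if (!length(genotype_params) || is.null(names(genotype_params)))
    stop_bad_arg("'genotype_params' must be a non-empty named list")
  if (length(n_per_group) == 1L)
    n_per_group <- stats::setNames(rep(n_per_group, length(genotype_params)),
                                   names(genotype_params))
  if (any(n_per_group < 1))
    stop_bad_arg("each group needs at least one animal")
  set.seed(seed)
  rows <- lapply(names(genotype_params), function(g) {
    p <- genotype_params[[g]]
    n <- n_per_group[[g]]
    draw_rows <- function(m) {
      d <- vapply(seq_along(p$mean), function(j)
        stats::rnorm(m, p$mean[j], p$sd[j]), numeric(m))
      if (m == 1L) d <- matrix(d, nrow = 1L)
      colnames(d) <- names(p$mean)
      d
    }
    draws <- draw_rows(n)
    # records must be physiologically coherent: redraw animals violating
    # LVID;d >= LVID;s, EDV >= ESV or positive velocities
    for (i in seq_len(100)) {
      bad <- draws[, "lvid_d_mm"] < draws[, "lvid_s_mm"] |
        draws[, "edv_ul"] < draws[, "esv_ul"] |
        draws[, "lvid_s_mm"] <= 0 | draws[, "esv_ul"] <= 0 |
        draws[, "e_mm_s"] <= 0 | draws[, "a_mm_s"] <= 0 |
        draws[, "eprime_mm_s"] <= 0 | draws[, "aprime_mm_s"] <= 0
      if (!any(bad)) break
      draws[bad, ] <- draw_rows(sum(bad))
    }
    if (any(bad)) stop_bad_arg(
      "could not draw physiological records for group '", g,
      "'; check its means/SDs")
    data.frame(animal_id = sprintf("%s_%02d", gsub("[ /]", "_", g),
                                   seq_len(n)),
               genotype = g, draws, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hill-type cooperative activation curve (shared by generator and fitter).
hill_rate <- function(ca, vmax, k_ca, hill) vmax / (1 + (k_ca / ca)^hill)
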