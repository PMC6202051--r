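# Paced cardiomyocyte trace analysis: Fura-2 transient amplitude and decay
# tau, sarcomere fractional shortening, and contraction/relaxation kinetics.

# centered moving average (odd window), endpoints padded by replication
moving_average <- function(y, k = 5L) {
  if (k < 2L) return(y)
  half <- k %/% 2L
  yp <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  stats::filter(yp, rep(1 / k, k), sides = 2)[(half + 1L):(half + length(y))]
}

check_uniform_grid <- function(t) {
  if (length(t) < 10L) stop_bad_arg("trace too short")
  dts <- diff(t)
  if (any(dts <= 0)) stop_bad_arg("'t' must be strictly increasing")
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 0.01 * dt)
    stop_bad_arg("'t' must be a uniform grid (within 1%)")
  dt
}

# Segment a periodic paced signal into beats via threshold upstroke crossings.
# Returns crossing indices, the pacing period, and per-beat sample windows.
segment_beats <- function(t, y, dt, smooth_k = 5L) {
  ys <- moving_average(y, smooth_k)
  b0 <- stats::median(ys)
  pk <- max(ys)
  if (pk - b0 <= 0) return(NULL)
  thr <- b0 + 0.5 * (pk - b0)
  up <- which(ys[-1L] >= thr & ys[-length(ys)] < thr) + 1L
  if (length(up) < 2L) return(NULL)
  # pacing period from the autocorrelation peak of the mean-removed signal
  # (global max past the first zero crossing), then a half-period refractory
  # drops spurious threshold re-crossings during the slow decay
  r <- as.numeric(ys - mean(ys))
  a <- stats::acf(r, lag.max = length(r) - 2L, plot = FALSE)$acf[-1L]
  neg <- which(a < 0)[1L]
  if (is.na(neg) || neg >= length(a)) return(NULL)
  period0 <- (neg + which.max(a[(neg + 1L):length(a)])) * dt
  kept <- up[1L]
  for (ci in up[-1L])
    if (t[ci] - t[kept[length(kept)]] > 0.5 * period0) kept <- c(kept, ci)
  up <- kept
  if (length(up) < 2L) return(NULL)
  period <- stats::median(diff(t[up]))
  n_pre <- round(0.15 * period / dt)
  n_post <- round(0.85 * period / dt) - 1L
  windows <- lapply(up, function(ci) {
    idx <- (ci - n_pre):(ci + n_post)
    if (idx[1L] < 1L || idx[length(idx)] > length(y)) NULL else idx
  })
  windows <- Filter(Negate(is.null), windows)
  if (length(windows) < 2L) return(NULL)
  list(crossings = up, period = period, windows = windows,
       n_pre = n_pre, dt = dt)
}

# Single-exponential decay fit y = b + A * exp(-(t - t0)/tau), started from a
# log-linear regression; returns NULL on failure.
fit_exp_decay <- function(t, y, b_start, a_start, tau_start = NA) {
  if (is.na(tau_start) || !is.finite(tau_start) || tau_start <= 0) {
    resid0 <- y - b_start
    ok <- resid0 > 0.05 * max(a_start, 1e-12)
    if (sum(ok) >= 3) {
      ll <- stats::lm(log(resid0[ok]) ~ t[ok])
      sl <- unname(stats::coef(ll)[2L])
      tau_start <- if (sl < 0) -1 / sl else (max(t) - min(t)) / 3
    } else tau_start <- (max(t) - min(t)) / 3
  }
  t0 <- t[1L]
  df <- data.frame(tt = t - t0, y = y)
  fit <- tryCatch(
    stats::nls(y ~ b + A * exp(-tt / tau), data = df,
               start = list(b = b_start, A = a_start, tau = tau_start),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  if (!is.finite(co["tau"]) || co["tau"] <= 0) return(NULL)
  list(b = unname(co["b"]), A = unname(co["A"]), tau = unname(co["tau"]),
       rss = sum(stats::residuals(fit)^2))
}

# shared per-beat measurement used by both channels; y is "upward" (already
# inverted for sarcomere shortening)
measure_beats <- function(t, y, seg, baseline_window = 0.1, mode, dt) {
  pre_gap <- max(0.02 * seg$period, 2 * dt)
  n_base <- max(3L, round(baseline_window / dt))
  n_gap <- round(pre_gap / dt)

  beat_data <- lapply(seq_along(seg$windows), function(j) {
    idx <- seg$windows[[j]]
    ci <- idx[seg$n_pre + 1L]
    base_idx <- (ci - n_gap - n_base):(ci - n_gap)
    base_idx <- base_idx[base_idx >= 1L]
    if (length(base_idx) < 3L) return(NULL)
    list(idx = idx, baseline = stats::median(y[base_idx]),
         base_sd = stats::sd(y[base_idx]))
  })
  beat_data <- Filter(Negate(is.null), beat_data)
  if (length(beat_data) < 1L) return(NULL)

  if (mode == "ensemble") {
    m <- vapply(beat_data, function(b) y[b$idx], numeric(length(beat_data[[1L]]$idx)))
    y_avg <- rowMeans(m)
    rel_t <- (seq_along(y_avg) - 1L) * dt
    beats <- list(list(t = rel_t, y = y_avg,
                       baseline = mean(vapply(beat_data, `[[`, numeric(1), "baseline")),
                       base_sd = mean(vapply(beat_data, `[[`, numeric(1), "base_sd"))))
  } else {
    beats <- lapply(beat_data, function(b)
      list(t = t[b$idx] - t[b$idx[1L]], y = y[b$idx],
           baseline = b$baseline, base_sd = b$base_sd))
  }
  list(beats = beats, n_raw_beats = length(beat_data))
}

#' Analyze a paced Ca2+ transient trace
#'
#' Segments a paced Fura-2 ratio trace into beats (upstroke threshold
#' crossings at half-amplitude; the pacing period is the median inter-beat
#' interval), then measures the baseline (median of the 100 ms pre-stimulus
#' window), peak amplitude, and the decay time constant tau from a
#' least-squares single-exponential fit `baseline + A * exp(-t/tau)` of the
#' decay phase (peak to end of the beat window). In `"ensemble"` mode
#' (default) beats are averaged into one mean transient before fitting; in
#' `"beat"` mode each beat is fit and the metrics averaged.
#'
#' @param trace data.frame with columns `t` (s, uniform grid) and `ratio`.
#' @param mode `"ensemble"` or `"beat"` (see Details).
#' @param baseline_window pre-stimulus window width (s) for the baseline
#'   median.
#' @param noise_mult amplitude must exceed `noise_mult` x baseline SD, else a
#'   "no transient" error is raised.
#' @return A list of class `transient_metrics` with `baseline`, `amplitude`,
#'   `tau`, `fit_rss`, `period`, `n_beats`, `n_beats_dropped`, `mode`.
#' @export
analyze_transient <- function(trace, mode = c("ensemble", "beat"),
                              baseline_window = 0.1, noise_mult = 4) {
  mode <- match.arg(mode)
  check_columns(trace, c("t", "ratio"), "trace")
  dt <- check_uniform_grid(trace$t)
  seg <- segment_beats(trace$t, trace$ratio, dt)
  if (is.null(seg))
    stop_bad_arg("no transient: could not detect at least 2 paced beats")
  mb <- measure_beats(trace$t, trace$ratio, seg, baseline_window, mode, dt)
  if (is.null(mb)) stop_bad_arg("no transient: no measurable beat windows")

  fits <- list()
  dropped <- 0L
  for (b in mb$beats) {
    pk_i <- which.max(b$y)
    amp_raw <- b$y[pk_i] - b$baseline
    if (is.finite(b$base_sd) && b$base_sd > 0 &&
        amp_raw < noise_mult * b$base_sd) {
      dropped <- dropped + 1L
      next
    }
    dec <- (pk_i):length(b$y)
    f <- fit_exp_decay(b$t[dec], b$y[dec], b_start = b$baseline,
                       a_start = amp_raw)
    if (is.null(f)) {
      message("analyze_transient: dropped one beat (decay fit did not converge)")
      dropped <- dropped + 1L
      next
    }
    # peak value from the decay fit at peak time (avoids max-of-noise bias)
    fits[[length(fits) + 1L]] <- list(baseline = b$baseline,
                                      amplitude = f$b + f$A - b$baseline,
                                      tau = f$tau, rss = f$rss)
  }
  if (!length(fits))
    stop_bad_arg("no transient: all beats dropped (below noise floor or unfit)")

  agg <- function(field) mean(vapply(fits, `[[`, numeric(1), field))
  structure(list(
    baseline = agg("baseline"), amplitude = agg("amplitude"),
    tau = agg("tau"), fit_rss = agg("rss"), period = seg$period,
    n_beats = mb$n_raw_beats, n_beats_dropped = dropped, mode = mode),
    class = "transient_metrics")
}

#' Analyze sarcomere shortening from a paced trace
#'
#' Measures contractility from the sarcomere-length channel: fractional
#' shortening `fs_pct = (sl_rest - sl_min) / sl_rest * 100` with `sl_rest` the
#' pre-stimulus median, maximal shortening and relengthening rates from the
#' smoothed (centered 5-point moving average) first derivative, the time from
#' stimulus to peak shortening, and the relaxation time constant from a
#' single-exponential fit of the sarcomere-length recovery. A flat channel
#' returns zero shortening and rates rather than an error. Lengths outside
#' the physiological 1-3 um band are flagged.
#'
#' @param trace data.frame with columns `t` and `sl` (sarcomere length, um).
#' @param mode,baseline_window as in [analyze_transient()].
#' @return A list of class `shortening_metrics` with `sl_rest`, `sl_min`,
#'   `fs_pct`, `time_to_peak_sl`, `relax_tau_sl`, `max_shortening_rate`,
#'   `max_relengthening_rate`, `n_beats`, `flagged_nonphysiological`.
#' @export
analyze_shortening <- function(trace, mode = c("ensemble", "beat"),
                               baseline_window = 0.1) {
  mode <- match.arg(mode)
  if (!"sl" %in% names(trace) || all(is.na(trace$sl)))
    stop_bad_arg("sarcomere-length channel 'sl' is missing")
  check_columns(trace, c("t", "sl"), "trace")
  dt <- check_uniform_grid(trace$t)
  flagged <- any(trace$sl < 1 | trace$sl > 3, na.rm = TRUE)
  if (flagged)
    warning("non-physiological sarcomere lengths (<1 or >3 um) present; flagged")

  # shortening is a downward deflection: segment the inverted channel
  inv <- max(trace$sl) - trace$sl
  seg <- segment_beats(trace$t, inv, dt)
  if (is.null(seg)) {
    # flat channel: no contraction
    return(structure(list(
      sl_rest = stats::median(trace$sl), sl_min = stats::median(trace$sl),
      fs_pct = 0, time_to_peak_sl = NA_real_, relax_tau_sl = NA_real_,
      max_shortening_rate = 0, max_relengthening_rate = 0,
      n_beats = 0L, flagged_nonphysiological = flagged, mode = mode),
      class = "shortening_metrics"))
  }
  mb <- measure_beats(trace$t, inv, seg, baseline_window, mode, dt)
  if (is.null(mb)) stop_bad_arg("no measurable contraction windows")

  res <- list()
  for (b in mb$beats) {
    sl_beat <- max(trace$sl) - b$y          # back to length units
    sl_rest <- max(trace$sl) - b$baseline
    pk_i <- which.max(b$y)                  # peak shortening position
    dsl <- diff(moving_average(sl_beat, 5L)) / dt
    # time from upstroke crossing to peak shortening
    t_cross <- b$t[seg$n_pre + 1L]
    rec <- pk_i:length(sl_beat)
    f <- fit_exp_decay(b$t[rec], b$y[rec], b_start = b$baseline,
                       a_start = max(b$y) - b$baseline)
    # peak shortening from the recovery fit at peak time (see analyze_transient)
    short_amp <- if (is.null(f)) max(b$y) - b$baseline
      else f$b + f$A - b$baseline
    sl_min <- sl_rest - short_amp
    fs_pct <- short_amp / sl_rest * 100
    res[[length(res) + 1L]] <- list(
      sl_rest = sl_rest, sl_min = sl_min, fs_pct = fs_pct,
      time_to_peak_sl = b$t[pk_i] - t_cross,
      relax_tau_sl = if (is.null(f)) NA_real_ else f$tau,
      max_shortening_rate = max(-dsl),
      max_relengthening_rate = max(dsl))
  }
  agg <- function(field) {
    v <- vapply(res, `[[`, numeric(1), field)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(list(
    sl_rest = agg("sl_rest"), sl_min = agg("sl_min"), fs_pct = agg("fs_pct"),
    time_to_peak_sl = agg("time_to_peak_sl"),
    relax_tau_sl = agg("relax_tau_sl"),
    max_shortening_rate = agg("max_shortening_rate"),
    max_relengthening_rate = agg("max_relengthening_rate"),
    n_beats = mb$n_raw_beats, flagged_nonphysiological = flagged,
    mode = mode), class = "shortening_metrics")
}

#' Group summary of per-cell transient metrics with hierarchical averaging
#'
#' Collapses per-cell metrics to per-animal means first, then summarizes each
#' genotype as mean +/- SD across animals (so the statistical unit is the
#' animal, matching designs with a few animals and 6-12 recordings each), and
#' runs two-tailed pooled-variance t-tests of every group against the
#' designated reference group(s), annotated with significance tiers
#' (`"*"` marks vs the first reference, `"#"` vs the second).
#'
#' @param metrics data.frame of per-cell metrics with a `cell_id` column and
#'   numeric metric columns.
#' @param meta data.frame mapping `cell_id` to `animal_id` and `genotype`.
#' @param reference reference genotype(s) (1 or 2).
#' @return A list of class `cell_summary` with `animal_means`, `group_summary`
#'   (mean/SD/n per genotype x metric) and `tests` (t, df, p, tier per
#'   genotype x metric x reference). Groups with a single animal are kept in
#'   descriptives but excluded from tests.
#' @export
summarize_cells <- function(metrics, meta, reference) {
  check_columns(metrics, "cell_id", "metrics")
  check_columns(meta, c("cell_id", "animal_id", "genotype"), "meta")
  if (length(reference) < 1 || length(reference) > 2)
    stop_bad_arg("supply 1 or 2 reference genotypes")
  df <- merge(metrics, meta, by = "cell_id")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (!length(num_cols)) stop_bad_arg("no numeric metric columns")
  if (length(unique(df$genotype)) < 2)
    stop_bad_arg("need at least 2 genotypes")
  if (!all(reference %in% df$genotype))
    stop_bad_arg("unknown reference genotype: ",
                 paste(setdiff(reference, df$genotype), collapse = ", "))

  animal_means <- stats::aggregate(df[num_cols],
                                   by = list(animal_id = df$animal_id,
                                             genotype = df$genotype),
                                   FUN = mean)
  group_summary <- do.call(rbind, lapply(split(animal_means, animal_means$genotype),
    function(g) {
      data.frame(genotype = g$genotype[1L], metric = num_cols,
                 mean = vapply(num_cols, function(m) mean(g[[m]]), numeric(1)),
                 sd = vapply(num_cols, function(m) stats::sd(g[[m]]), numeric(1)),
                 n_animals = nrow(g), stringsAsFactors = FALSE)
    }))
  rownames(group_summary) <- NULL

  tests <- list()
  marks <- c("*", "#")
  for (r in seq_along(reference)) {
    ref_g <- animal_means[animal_means$genotype == reference[r], , drop = FALSE]
    for (g in setdiff(unique(animal_means$genotype), reference[r])) {
      gg <- animal_means[animal_means$genotype == g, , drop = FALSE]
      if (nrow(gg) < 2 || nrow(ref_g) < 2) next  # singleton: descriptives only
      for (m in num_cols) {
        tt <- student_t(gg[[m]], ref_g[[m]])
        tests[[length(tests) + 1L]] <- data.frame(
          genotype = g, reference = reference[r], metric = m,
          t = tt$t, df = tt$df, p = tt$p,
          tier = tier_symbol(tt$p, marks[r]), stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  structure(list(animal_means = animal_means, group_summary = group_summary,
                 tests = tests, reference = reference),
            class = "cell_summary")
}
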