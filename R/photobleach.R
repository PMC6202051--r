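# Progressive acceptor-photobleaching analysis: donor-dequenching FRET and
# 1:1 vs higher-order stoichiometry classification from the donor-vs-acceptor
# trajectory.

check_bleach_series <- function(series, min_steps = 3L) {
  check_columns(series, c("step", "f_donor", "f_acceptor"), "series")
  series <- series[order(series$step), , drop = FALSE]
  if (nrow(series) < min_steps)
    stop_bad_arg(sprintf("bleach series needs at least %d steps", min_steps))
  series
}

#' Donor-dequenching FRET from a photobleaching trajectory
#'
#' Photobleaching the acceptor releases the donor from quenching, so the FRET
#' efficiency of the original complex is `1 - F_DA / F_D`, with `F_DA` the
#' donor intensity before bleaching and `F_D` after complete bleaching. `F_DA`
#' is averaged over the first `baseline_window` steps and `F_D` over the last
#' `plateau_window` steps. If the donor is still rising at the end of the
#' trajectory by more than `rise_tol` (relative), the bleach is incomplete
#' and an error is raised. Noise can make `F_DA > F_D`; the small negative
#' efficiency is returned and flagged, not clamped.
#'
#' @param series data.frame with columns `step`, `f_donor`, `f_acceptor`.
#' @param baseline_window,plateau_window number of steps averaged at either
#'   end of the trajectory.
#' @param rise_tol maximal tolerated relative donor rise across the final
#'   plateau window. The default (10%) accommodates a few percent of
#'   multiplicative measurement noise on a two-point plateau.
#' @return A list of class `pb_fret` with `fret_pb`, `f_da`, `f_d` and
#'   `flagged` (TRUE when `fret_pb < 0`).
#' @examples
#' s <- data.frame(step = 1:6, f_donor = c(70, 70, 80, 95, 100, 100),
#'                 f_acceptor = c(100, 100, 60, 20, 2, 0))
#' compute_pb_fret(s)$fret_pb  # 0.3
#' @export
compute_pb_fret <- function(series, baseline_window = 2L,
                            plateau_window = 2L, rise_tol = 0.10) {
  series <- check_bleach_series(series)
  n <- nrow(series)
  if (baseline_window + plateau_window > n)
    stop_bad_arg("baseline and plateau windows exceed the series length")
  f_da <- mean(series$f_donor[seq_len(baseline_window)])
  plateau <- series$f_donor[(n - plateau_window + 1L):n]
  f_d <- mean(plateau)
  if (f_d <= 0) stop_bad_arg("post-bleach donor intensity must be positive")
  rise <- (plateau[length(plateau)] - plateau[1L]) / f_d
  if (length(plateau) > 1L && rise > rise_tol)
    stop_bad_arg(sprintf(
      "incomplete bleach: donor still rising at trajectory end (%.1f%% over the plateau window)",
      100 * rise))
  fret_pb <- 1 - f_da / f_d
  structure(list(fret_pb = fret_pb, f_da = f_da, f_d = f_d,
                 flagged = fret_pb < 0),
            class = "pb_fret")
}

#' Classify complex stoichiometry from a photobleaching trajectory
#'
#' During progressive acceptor photobleaching, the donor intensity of a 1:1
#' complex rises linearly as the acceptor falls, whereas a donor surrounded by
#' several acceptors (an oligomer) dequenches along a convex curve, because a
#' single surviving acceptor still quenches it. The donor channel is regressed
#' on the acceptor channel with linear and quadratic models:
#' * `no_fret` — the linear slope is not significantly negative (no donor
#'   dequenching);
#' * `one_to_one` — dequenching present and the quadratic term is
#'   non-significant at `alpha` (linear relation);
#' * `higher_order` — the quadratic term is significant (curved relation).
#'
#' The curvature test is the nested linear-vs-quadratic F-test; a linear
#' relationship is taken to indicate a 1:1 complex. On top of the
#' significance tests, each effect must also be practically detectable
#' against the trajectory's own residual noise: the fitted donor dequench
#' across the observed acceptor range must exceed `min_slope_effect` residual
#' SDs, and the maximal divergence of the quadratic from the linear fit must
#' exceed `min_curve_effect` residual SDs. This mimics how linearity is
#' judged on such plots (a visible, not merely nominally significant,
#' deviation) and keeps misclassification rates below the nominal alpha.
#'
#' @param series data.frame with columns `step`, `f_donor`, `f_acceptor`
#'   (>= 6 steps).
#' @param alpha significance level for both the slope and curvature tests.
#' @param min_slope_effect,min_curve_effect detection floors in units of
#'   residual SD (defaults 3 and 2, the conventional detection thresholds).
#' @return A list of class `stoichiometry_call` with `call`, `linear_r2`,
#'   `curvature_p`, `slope_p` and `slope_sign` (`"+"`, `"-"` or `"0"`).
#' @export
classify_stoichiometry <- function(series, alpha = 0.05,
                                   min_slope_effect = 3,
                                   min_curve_effect = 2) {
  check_number(alpha, "alpha", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  series <- check_bleach_series(series, min_steps = 6L)
  acc <- series$f_acceptor
  don <- series$f_donor
  depth <- (max(acc) - min(acc)) / max(acc)
  if (!is.finite(depth) || depth < 0.20)
    stop_bad_arg(sprintf(
      "insufficient bleach depth: acceptor range is %.0f%% of its maximum (need >= 20%%)",
      100 * depth))

  lin <- stats::lm(don ~ acc)
  qua <- stats::lm(don ~ acc + I(acc^2))
  sl <- suppressWarnings(summary(lin))$coefficients
  tss <- sum((don - mean(don))^2)
  rss_lin <- sum(stats::residuals(lin)^2)
  linear_r2 <- if (tss > 0) 1 - rss_lin / tss else 1

  # one-sided p for a negative slope (donor dequenches as acceptor bleaches)
  slope_t <- sl["acc", "t value"]
  slope_p <- stats::pt(slope_t, df = lin$df.residual)

  # nested F-test for curvature; exactly collinear data leave no residual
  # variance, in which case there is no evidence of curvature
  if (rss_lin <= 1e-12 * max(tss, 1)) {
    curvature_p <- 1
  } else {
    curvature_p <- stats::anova(lin, qua)[2, "Pr(>F)"]
    if (is.na(curvature_p)) curvature_p <- 1
  }

  # practical-detectability floors (in residual-SD units)
  sigma_lin <- sqrt(rss_lin / lin$df.residual)
  dequench <- abs(sl["acc", "Estimate"]) * (max(acc) - min(acc))
  slope_effect <- if (sigma_lin > 0) dequench / sigma_lin
    else if (dequench > 0) Inf else 0
  sigma_qua <- sqrt(sum(stats::residuals(qua)^2) / qua$df.residual)
  bow <- max(abs(stats::fitted(qua) - stats::fitted(lin)))
  curve_effect <- if (sigma_qua > 0) bow / sigma_qua
    else if (bow > 0) Inf else 0

  slope_sign <- if (slope_p < alpha) "-"
    else if (stats::pt(slope_t, df = lin$df.residual,
                       lower.tail = FALSE) < alpha) "+"
    else "0"
  call <- if (slope_sign != "-" || slope_effect < min_slope_effect) "no_fret"
    else if (curvature_p < alpha && curve_effect >= min_curve_effect)
      "higher_order"
    else "one_to_one"

  structure(list(call = call, linear_r2 = linear_r2,
                 curvature_p = curvature_p, slope_p = slope_p,
                 slope_sign = slope_sign, slope_effect = slope_effect,
                 curve_effect = curve_effect, alpha = alpha,
                 method = "nested linear/quadratic F-test with residual-SD effect floors"),
            class = "stoichiometry_call")
}

#' Detect oligomerization FRET across replicate photobleaching series
#'
#' Summarizes a set of photobleaching trajectories for one labelling pair:
#' per-series dequenching FRET is tested against zero with a one-sample
#' two-tailed t-test (presence requires `p < alpha` *and* a positive mean),
#' and the stoichiometry calls are tallied with the majority reported. This
#' reproduces the logic of oligomerization screens: an all-flat set (e.g. a
#' strictly monomeric peptide probed against itself) is called "absent", a
#' pentameric one "present" with a higher-order majority.
#'
#' @param series_list list of >= 3 bleach-series data.frames.
#' @param alpha significance level.
#' @param ... passed on to [compute_pb_fret()] (windows, rise tolerance).
#' @return A list of class `oligomer_summary` with `present` ("present" /
#'   "absent"), `mean_fret_pb`, `p`, `calls` (table of stoichiometry calls),
#'   `majority_call`, and `note`.
#' @export
detect_oligomer_fret <- function(series_list, alpha = 0.05, ...) {
  if (!is.list(series_list) || length(series_list) < 3)
    stop_bad_arg("need at least 3 photobleaching series")
  fret <- vapply(series_list, function(s) compute_pb_fret(s, ...)$fret_pb,
                 numeric(1))
  calls <- vapply(series_list, function(s) classify_stoichiometry(s, alpha)$call,
                  character(1))
  note <- NA_character_
  if (stats::sd(fret) == 0) {
    p <- if (mean(fret) == 0) 1 else 0
    if (mean(fret) == 0) note <- "all efficiencies exactly 0; p set to 1"
  } else {
    p <- stats::t.test(fret, mu = 0)$p.value
  }
  present <- p < alpha && mean(fret) > 0
  tab <- table(calls)
  structure(list(
    present = if (present) "present" else "absent",
    mean_fret_pb = mean(fret), sd_fret_pb = stats::sd(fret),
    n = length(fret), p = p, calls = tab,
    majority_call = names(tab)[which.max(tab)], note = note),
    class = "oligomer_summary")
}
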