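# Acceptor-sensitization (three-cube) E-FRET analysis: bleed-through
# calibration, per-cell efficiency, and hyperbolic binding-curve fitting.

#' Calibration constants for three-cube E-FRET
#'
#' Container for the channel cross-talk constants: `a` (acceptor bleed-through
#' into the FRET channel), `d` (donor bleed-through), and `g_factor` (ratio of
#' sensitized acceptor emission to donor dequenching). The calibrated
#' reference values are `a = 0.075`, `d = 0.88`, `g_factor = 4.74`; a legacy
#' alternative `g_factor = 3.2` appears in some formulations of the efficiency
#' equation and is selectable (see the package vignette).
#'
#' @param a,d bleed-through fractions, >= 0.
#' @param g_factor sensitized-emission/donor-dequench ratio, > 0.
#' @param notes optional character metadata (e.g. provenance of constants).
#' @return A list of class `fret_calibration`.
#' @export
fret_calibration <- function(a = 0.075, d = 0.88, g_factor = 4.74,
                             notes = character()) {
  check_number(a, "a", lower = 0)
  check_number(d, "d", lower = 0)
  check_number(g_factor, "g_factor", lower = 0, allow_lower = FALSE)
  structure(list(a = a, d = d, g_factor = g_factor, notes = notes),
            class = "fret_calibration")
}

# robust slope through the origin with 3xMAD outlier rejection on the ratios
robust_origin_slope <- function(x, y) {
  r <- y / x
  med <- stats::median(r)
  mad <- stats::mad(r)
  keep <- if (mad > 0) abs(r - med) <= 3 * mad else rep(TRUE, length(r))
  sum(x[keep] * y[keep]) / sum(x[keep]^2)
}

#' Estimate bleed-through constants from single-label control cells
#'
#' The donor bleed-through `d` is the robust slope of `f_fret` on `f_cer` over
#' donor-only control cells, and the acceptor bleed-through `a` is the robust
#' slope of `f_fret` on `f_yfp` over acceptor-only cells (least squares
#' through the origin after 3xMAD outlier rejection on the per-cell ratios).
#' The g-factor cannot be estimated from these controls and is taken from
#' `g_factor`.
#'
#' Note on conventions: in the source protocol the acceptor constant is
#' defined as the FRET-to-acceptor channel ratio of acceptor-only cells (the
#' printed formula's `F_Cer` denominator is treated as a typo for `F_YFP`),
#' and the donor constant is the one printed as "b". Both readings are
#' recorded in the returned `notes`.
#'
#' @param donor_only data.frame of donor-only control cells (columns `f_cer`,
#'   `f_fret`).
#' @param acceptor_only data.frame of acceptor-only control cells (columns
#'   `f_yfp`, `f_fret`).
#' @param g_factor g-factor to carry into the calibration (not estimable from
#'   single-label controls).
#' @return A [fret_calibration()] object.
#' @export
calibrate_bleedthrough <- function(donor_only, acceptor_only,
                                   g_factor = 4.74) {
  check_columns(donor_only, c("f_cer", "f_fret"), "donor_only")
  check_columns(acceptor_only, c("f_yfp", "f_fret"), "acceptor_only")
  if (nrow(donor_only) < 5 || nrow(acceptor_only) < 5)
    stop_bad_arg("each control table needs at least 5 cells")
  if (any(donor_only$f_cer <= 0) || any(acceptor_only$f_yfp <= 0))
    stop_bad_arg("control intensities must be positive")

  d <- robust_origin_slope(donor_only$f_cer, donor_only$f_fret)
  a <- robust_origin_slope(acceptor_only$f_yfp, acceptor_only$f_fret)
  notes <- c("a = slope of f_fret on f_yfp over acceptor-only cells",
             "d = slope of f_fret on f_cer over donor-only cells ('b' in some protocols)")
  if (a < 0) {
    warning("negative fitted acceptor bleed-through; clamped to 0")
    notes <- c(notes, sprintf("a clamped to 0 (fitted %.4g)", a))
    a <- 0
  }
  if (d < 0) {
    warning("negative fitted donor bleed-through; clamped to 0")
    notes <- c(notes, sprintf("d clamped to 0 (fitted %.4g)", d))
    d <- 0
  }
  fret_calibration(a = a, d = d, g_factor = g_factor, notes = notes)
}

#' Per-cell E-FRET efficiency with bleed-through correction
#'
#' Computes the bleed-through-corrected sensitized emission
#' `fc = f_fret - a * f_yfp - d * f_cer` and the FRET efficiency
#' `e = fc / (fc + g_factor * f_cer)` for every cell. The acceptor-expression
#' index `x` is the raw `f_yfp` intensity (YFP intensity is used as an index
#' of protein expression). Cells with `f_cer <= 0` are excluded (count
#' recorded in the `"n_excluded"` attribute); negative `fc` under noise is
#' retained, not clamped.
#'
#' @param cells data.frame with columns `cell_id`, `f_cer`, `f_yfp`, `f_fret`.
#' @param cal a [fret_calibration()] object.
#' @return A data.frame with columns `cell_id`, `fc`, `e`, `x`, row-for-row
#'   with the retained input cells; attributes `n_excluded` and `calibration`.
#' @examples
#' cal <- fret_calibration()
#' compute_efficiency(
#'   data.frame(cell_id = "c1", f_cer = 100, f_yfp = 200, f_fret = 200), cal)
#' @export
compute_efficiency <- function(cells, cal = fret_calibration()) {
  check_columns(cells, c("cell_id", "f_cer", "f_yfp", "f_fret"), "cells")
  if (!inherits(cal, "fret_calibration"))
    cal <- do.call(fret_calibration, as.list(cal))
  bad <- !is.finite(cells$f_cer) | cells$f_cer <= 0
  if (any(bad)) {
    message(sprintf("compute_efficiency: excluded %d cell(s) with f_cer <= 0",
                    sum(bad)))
    cells <- cells[!bad, , drop = FALSE]
  }
  if (!nrow(cells)) stop_bad_arg("no cells with positive donor intensity")
  fc <- cells$f_fret - cal$a * cells$f_yfp - cal$d * cells$f_cer
  e <- fc / (fc + cal$g_factor * cells$f_cer)
  out <- data.frame(cell_id = cells$cell_id, fc = fc, e = e,
                    x = cells$f_yfp, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(bad)
  attr(out, "calibration") <- cal
  out
}

# single evaluation of the hyperbola residual sum of squares
hyperbola_rss <- function(fret_max, kd, x, e) {
  sum((e - fret_max * x / (kd + x))^2)
}

#' Fit the hyperbolic FRET-vs-expression binding curve
#'
#' Nonlinear least squares of per-cell efficiency against the binding
#' isotherm `e = FRET_max * x / (K_d + x)`, where `FRET_max` is the intrinsic
#' FRET of the bound complex and `K_d` the acceptor-expression level (AU) at
#' half-maximal FRET — the apparent dissociation constant; a lower `K_d`
#' means a higher apparent affinity. Fitting is per cell (not on binned
#' means), started from the best point of a 5x5 log-spaced grid over
#' `(FRET_max, K_d)`; ties are broken by lowest residual sum of squares, then
#' smallest `K_d`. Standard errors are obtained by case-resampling bootstrap.
#'
#' Cells with `e < -0.5` or `e > 1` are excluded as optical artifacts before
#' fitting (count in `n_excluded`); negative-`fc` cells within that range are
#' retained, since dropping them biases low-expression estimates.
#'
#' @param effs data.frame from [compute_efficiency()] (columns `e`, `x`).
#' @param bootstrap_n bootstrap replicates for standard errors (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `binding_fit` with `fret_max`, `kd`,
#'   `fret_max_se`, `kd_se`, `n_cells`, `n_excluded`, `rss`, `converged`,
#'   `unconstrained_kd` (TRUE when `kd` exceeds 10x the largest expression
#'   level), and `bootstrap` (replicate table, when run).
#' @export
fit_binding_curve <- function(effs, bootstrap_n = 200, seed = 1) {
  check_columns(effs, c("e", "x"), "effs")
  bootstrap_n <- check_count(bootstrap_n, "bootstrap_n", min = 0L)
  keep <- is.finite(effs$e) & is.finite(effs$x) &
    effs$e >= -0.5 & effs$e <= 1 & effs$x > 0
  n_excluded <- sum(!keep)
  effs <- effs[keep, , drop = FALSE]
  if (nrow(effs) < 10)
    stop_bad_arg("need at least 10 usable cells to fit the binding curve")
  if (max(effs$x) / min(effs$x) < 10)
    stop_bad_arg("expression index must span at least a 10-fold range")

  fit1 <- fit_hyperbola_core(effs$x, effs$e)
  if (!fit1$converged)
    stop_bad_arg(paste0("binding-curve fit did not converge from any of the ",
                        "multi-start grid points: ",
                        paste(sprintf("(%.3g, %.3g)", fit1$starts$fret_max,
                                      fit1$starts$kd), collapse = ", ")))

  boot <- NULL
  fret_max_se <- kd_se <- NA_real_
  if (bootstrap_n > 0) {
    set.seed(seed)
    n <- nrow(effs)
    reps <- vapply(seq_len(bootstrap_n), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- fit_hyperbola_core(effs$x[idx], effs$e[idx])
      if (f$converged) c(f$fret_max, f$kd) else c(NA_real_, NA_real_)
    }, numeric(2))
    boot <- data.frame(fret_max = reps[1, ], kd = reps[2, ])
    fret_max_se <- stats::sd(boot$fret_max, na.rm = TRUE)
    kd_se <- stats::sd(boot$kd, na.rm = TRUE)
  }

  structure(list(
    fret_max = fit1$fret_max, kd = fit1$kd,
    fret_max_se = fret_max_se, kd_se = kd_se,
    n_cells = nrow(effs), n_excluded = n_excluded, rss = fit1$rss,
    converged = fit1$converged,
    unconstrained_kd = fit1$kd > 10 * max(effs$x),
    bootstrap_n = bootstrap_n, bootstrap_seed = seed, bootstrap = boot),
    class = "binding_fit")
}

# Multi-start Gauss-Newton core for the hyperbola; log-parameterized kd keeps
# the search positive. Returns best local optimum over the start grid.
fit_hyperbola_core <- function(x, e) {
  f_grid <- exp(seq(log(0.02), log(0.9), length.out = 5))
  k_grid <- exp(seq(log(stats::quantile(x, 0.05)),
                    log(stats::quantile(x, 0.95)), length.out = 5))
  starts <- expand.grid(fret_max = f_grid, kd = k_grid)
  rss0 <- mapply(hyperbola_rss, starts$fret_max, starts$kd,
                 MoreArgs = list(x = x, e = e))
  ord <- order(rss0)
  best <- NULL
  df <- data.frame(x = x, e = e)
  for (i in ord[seq_len(min(3L, length(ord)))]) {
    fit <- tryCatch(
      stats::nls(e ~ fm * x / (exp(lk) + x), data = df,
                 start = list(fm = starts$fret_max[i],
                              lk = log(starts$kd[i])),
                 control = stats::nls.control(maxiter = 200, tol = 1e-9,
                                              scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    cand <- list(fret_max = unname(co["fm"]), kd = exp(unname(co["lk"])),
                 rss = sum(stats::residuals(fit)^2))
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 && cand$kd < best$kd))
      best <- cand
  }
  if (is.null(best))
    return(list(converged = FALSE, starts = starts))
  c(best, list(converged = TRUE, starts = starts))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic binding fit (n = %d cells, %d excluded)\n",
              x$n_cells, x$n_excluded))
  cat(sprintf("  FRET_max = %.4f (SE %.4f)\n", x$fret_max, x$fret_max_se))
  cat(sprintf("  K_d      = %.4g AU (SE %.4g)%s\n", x$kd, x$kd_se,
              if (isTRUE(x$unconstrained_kd)) "  [unconstrained]" else ""))
  cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Compare apparent affinities between two constructs
#'
#' Two-tailed pooled-variance Student t-test on per-experiment `K_d` values
#' (lower `K_d` = higher apparent affinity). Significance is annotated with
#' the conventional tier symbols.
#'
#' @param kd1,kd2 numeric vectors of per-experiment `K_d` estimates (>= 2
#'   each; the reference design used 4 independent experiments per construct).
#' @param labels length-2 character vector naming the groups.
#' @return A list of class `affinity_comparison` with group means/SDs, `t`,
#'   `df`, `p`, `tier`, and `higher_affinity` (label of the lower-`K_d` group,
#'   or `NA` if not significant at 0.05).
#' @export
compare_affinity <- function(kd1, kd2, labels = c("group1", "group2")) {
  tt <- student_t(kd1, kd2)
  tier <- tier_symbol(tt$p)
  structure(list(
    labels = labels, n = c(length(kd1), length(kd2)),
    mean = c(tt$mean_x, tt$mean_y), sd = c(tt$sd_x, tt$sd_y),
    t = tt$t, df = tt$df, p = tt$p, tier = tier, note = tt$note,
    higher_affinity = if (tt$p < 0.05)
      labels[which.min(c(tt$mean_x, tt$mean_y))] else NA_character_),
    class = "affinity_comparison")
}

#' @export
print.affinity_comparison <- function(x, ...) {
  cat(sprintf("K_d comparison: %s (%.4g +/- %.4g, n=%d) vs %s (%.4g +/- %.4g, n=%d)\n",
              x$labels[1], x$mean[1], x$sd[1], x$n[1],
              x$labels[2], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("  t = %.3f, df = %g, p = %.4g %s\n", x$t, x$df, x$p, x$tier))
  if (!is.na(x$higher_affinity))
    cat(sprintf("  higher apparent affinity: %s\n", x$higher_affinity))
  invisible(x)
}
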