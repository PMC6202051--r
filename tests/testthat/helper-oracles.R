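# Independent oracles used to freeze expected values. Each solves the same
# problem as the implementation by a different route (root bracketing,
# exhaustive enumeration, grid search, log-linear regression).

# Competition equilibrium via uniroot on the monotone mass-balance equation
# in the free-receptor concentration (independent of the damped fixed-point
# solver in the package).
oracle_competition <- function(s_total, l1_total, l2_total, kd1, kd2) {
  f <- function(s) s * (1 + l1_total / (kd1 + s) + l2_total / (kd2 + s)) -
    s_total
  s <- stats::uniroot(f, c(0, s_total), tol = 1e-14)$root
  l1f <- l1_total / (1 + s / kd1)
  l2f <- l2_total / (1 + s / kd2)
  list(s_free = s, bound1 = s * l1f / kd1, bound2 = s * l2f / kd2)
}

# Single-ligand binding closed form (quadratic in the complex concentration).
oracle_single_site <- function(s_total, l_total, kd) {
  b <- s_total + l_total + kd
  (b - sqrt(b^2 - 4 * s_total * l_total)) / 2
}

# Monomer/pentamer equilibrium by interval bisection.
oracle_pentamer <- function(total, k_assoc, iters = 200) {
  lo <- 0; hi <- total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + 5 * k_assoc * mid^5 > total) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Expected photobleaching trajectory by exhaustive enumeration over the
# binomial distribution of surviving acceptors per complex.
oracle_bleach_expectation <- function(n_steps, bleach_rate, e_pair, k,
                                      n_complexes, n_baseline = 2) {
  bleach_idx <- pmax(seq_len(n_baseline + n_steps) - n_baseline, 0)
  q <- (1 - bleach_rate)^bleach_idx
  donor <- vapply(q, function(qs) {
    j <- 0:k
    pj <- stats::dbinom(j, k, qs)
    n_complexes * sum(pj * (1 - e_pair)^j)
  }, numeric(1))
  acceptor <- n_complexes * k * q
  data.frame(step = seq_along(q), f_donor = donor, f_acceptor = acceptor)
}

# Dense 2-D grid search for the hyperbolic binding fit.
oracle_grid_hyperbola <- function(x, e, f_range = c(0.05, 0.6),
                                  k_range = NULL, n_grid = 120) {
  if (is.null(k_range)) k_range <- c(min(x), max(x))
  fs <- seq(f_range[1], f_range[2], length.out = n_grid)
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  best <- c(NA, NA, Inf)
  for (f in fs) {
    rss <- vapply(ks, function(k) sum((e - f * x / (k + x))^2), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(f, ks[i], rss[i])
  }
  list(fret_max = best[1], kd = best[2], rss = best[3],
       f_step = diff(fs[1:2]), k_ratio = ks[2] / ks[1])
}

# Dense 3-D grid search for the Hill uptake fit.
oracle_grid_hill <- function(ca, v, n_grid = 60) {
  vs <- seq(0.7 * max(v), 1.3 * max(v), length.out = n_grid)
  ks <- exp(seq(log(min(ca)), log(max(ca)), length.out = n_grid))
  hs <- seq(0.5, 4, length.out = n_grid)
  best <- c(NA, NA, NA, Inf)
  for (vm in vs) for (h in hs) {
    rss <- vapply(ks, function(k) sum((v - vm / (1 + (k / ca)^h))^2),
                  numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[4]) best <- c(vm, ks[i], h, rss[i])
  }
  list(vmax = best[1], k_ca = best[2], hill = best[3], rss = best[4],
       v_step = diff(vs[1:2]), k_ratio = ks[2] / ks[1], h_step = diff(hs[1:2]))
}

# Decay time constant by log-linear regression on a noiseless decay segment.
oracle_loglinear_tau <- function(t, y, baseline) {
  ok <- y - baseline > 0
  -1 / unname(stats::coef(stats::lm(log(y[ok] - baseline) ~ t[ok]))[2])
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
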