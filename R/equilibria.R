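# Binding equilibria used by the forward models: two ligands competing for a
# single site on the pump, and the monomer/pentamer self-association of PLN.

#' Equilibrium of two ligands competing for one binding site
#'
#' Solves the equilibrium of a receptor S (e.g. SERCA) with two ligands that
#' occupy the same site (e.g. PLN and DWORF): `bound_i = s_free * l_i_free /
#' kd_i` together with mass balance on all three species. This is the
#' mechanistic model behind dose-dependent displacement of one SERCA-binding
#' micropeptide by the other.
#'
#' The free-receptor concentration satisfies the monotone scalar equation
#' `s * (1 + l1/(kd1+s) + l2/(kd2+s)) = s_total`, which is solved by damped
#' fixed-point iteration to a relative tolerance of 1e-10.
#'
#' @param s_total,l1_total,l2_total total concentrations (uM), all >= 0.
#' @param kd1,kd2 dissociation constants (uM), > 0.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return A list of class `competition_state` with `s_total`, `l1_total`,
#'   `l2_total`, `kd1`, `kd2`, `bound1`, `bound2`, `s_free`, `l1_free`,
#'   `l2_free`, and `iterations`.
#' @examples
#' eq <- solve_competition(1, 1, 1, kd1 = 0.1, kd2 = 0.1)
#' eq$bound1 + eq$bound2 + eq$s_free  # mass balance: 1
#' @export
solve_competition <- function(s_total, l1_total, l2_total, kd1, kd2,
                              tol = 1e-10, max_iter = 1e5) {
  check_number(s_total, "s_total", lower = 0)
  check_number(l1_total, "l1_total", lower = 0)
  check_number(l2_total, "l2_total", lower = 0)
  check_number(kd1, "kd1", lower = 0, allow_lower = FALSE)
  check_number(kd2, "kd2", lower = 0, allow_lower = FALSE)

  # fixed point: s = s_total / (1 + l1_free/kd1 + l2_free/kd2) with
  # l_i_free = l_i_total / (1 + s/kd_i); damping stabilises stiff cases
  scale <- max(s_total, 1)
  s <- s_total
  lambda <- 0.5
  iter <- 0L
  repeat {
    iter <- iter + 1L
    l1f <- l1_total / (1 + s / kd1)
    l2f <- l2_total / (1 + s / kd2)
    s_new <- s_total / (1 + l1f / kd1 + l2f / kd2)
    s <- (1 - lambda) * s + lambda * s_new
    resid <- abs(s * (1 + l1_total / (kd1 + s) + l2_total / (kd2 + s)) -
                   s_total)
    if (resid <= tol * scale) break
    if (iter >= max_iter) {
      resid <- abs(s * (1 + l1_total / (kd1 + s) + l2_total / (kd2 + s)) -
                     s_total)
      stop_bad_arg(sprintf(
        "competition solver did not converge after %d iterations (mass-balance residual %.3e)",
        iter, resid))
    }
  }
  l1_free <- l1_total / (1 + s / kd1)
  l2_free <- l2_total / (1 + s / kd2)
  structure(list(
    s_total = s_total, l1_total = l1_total, l2_total = l2_total,
    kd1 = kd1, kd2 = kd2,
    bound1 = s * l1_free / kd1, bound2 = s * l2_free / kd2,
    s_free = s, l1_free = l1_free, l2_free = l2_free,
    iterations = iter), class = "competition_state")
}

#' Monomer/pentamer self-association equilibrium
#'
#' PLN partitions between an inhibitory monomer and a less inhibitory
#' pentamer; DWORF is treated as a pure monomer (`k_assoc = 0`). Intermediate
#' oligomers (dimer-tetramer) are ignored. Solves
#' `m + 5 * k_assoc * m^5 = total` for the monomer concentration `m` on
#' `[0, total]` (the left side is strictly increasing in `m`, so the root is
#' unique).
#'
#' @param total total protomer concentration (uM), >= 0.
#' @param k_assoc association constant for 5 M <-> P, in (uM)^-4, >= 0.
#' @param tol absolute tolerance on the root.
#' @return A list of class `pentamer_state` with `total`, `k_assoc`,
#'   `monomer` and `pentamer` (uM of pentamer particles, so
#'   `monomer + 5 * pentamer = total`).
#' @examples
#' pentamer_equilibrium(10, 1)
#' pentamer_equilibrium(10, 0)  # pure monomer
#' @export
pentamer_equilibrium <- function(total, k_assoc, tol = 1e-12) {
  check_number(total, "total", lower = 0)
  check_number(k_assoc, "k_assoc", lower = 0)
  if (total == 0 || k_assoc == 0) {
    m <- total
  } else {
    f <- function(m) m + 5 * k_assoc * m^5 - total
    m <- stats::uniroot(f, c(0, total), tol = tol * max(total, 1))$root
  }
  structure(list(total = total, k_assoc = k_assoc,
                 monomer = m, pentamer = k_assoc * m^5),
            class = "pentamer_state")
}
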