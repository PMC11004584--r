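#' Characteristic-polynomial coefficients of a 3x3 matrix
#'
#' Coefficients `(c1, c2, c3)` of `lambda^3 + c1 lambda^2 + c2 lambda + c3`:
#' `c1 = -trace(J)`, `c2` the sum of principal 2x2 minors, `c3 = -det(J)`.
#' At the coexistence equilibrium these are the quantities usually written
#' `G11, G22, G33`; at the boundary states they play the same role.
#'
#' @param J a finite 3x3 numeric matrix.
#' @return numeric vector `c(c1, c2, c3)`.
#' @export
characteristic_coefficients <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(3, 3)), all(is.finite(J)))
  c1 <- -(J[1, 1] + J[2, 2] + J[3, 3])
  c2 <- (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) +
        (J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]) +
        (J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2])
  c3 <- -det(J)
  stats::setNames(c(c1, c2, c3), c("c1", "c2", "c3"))
}

#' Routh-Hurwitz test for a cubic characteristic polynomial
#'
#' All roots of `lambda^3 + c1 lambda^2 + c2 lambda + c3` have negative
#' real parts iff `c1 > 0`, `c3 > 0` and `c1 c2 - c3 > 0`.
#'
#' @param c1,c2,c3 coefficients (finite numbers).
#' @param tol marginality tolerance: when any test quantity lies within
#'   `tol` of zero the verdict is `"marginal"` (needed near bifurcations).
#' @return a list with the three booleans, the discriminant-like value
#'   `c1c2_minus_c3`, and `classification` among
#'   `"stable"`, `"unstable"`, `"marginal"`.
#' @export
#' @examples
#' routh_hurwitz(0.844371, 1.96046, 1.22722)$classification
routh_hurwitz <- function(c1, c2, c3, tol = 1e-8) {
  stopifnot(is.finite(c1), is.finite(c2), is.finite(c3))
  v <- c1 * c2 - c3
  cls <- if (min(abs(c(c1, c3, v))) <= tol) "marginal"
         else if (c1 > 0 && c3 > 0 && v > 0) "stable"
         else "unstable"
  list(c1_positive = c1 > 0, c3_positive = c3 > 0,
       c1c2_minus_c3 = v, c1c2_minus_c3_positive = v > 0,
       classification = cls)
}

#' Stability report at a single equilibrium
#'
#' Combines the exact Jacobian, its characteristic coefficients, the
#' Routh-Hurwitz verdict, and an eigenvalue cross-check.
#'
#' @param eq a `klepto_equilibrium` (or bare numeric 3-vector).
#' @param params a [klepto_params] object.
#' @param tol marginality tolerance on eigenvalue real parts.
#' @return an object of class `klepto_stability` with fields `label`,
#'   `state`, `eigenvalues`, `char_coeffs`, `routh_hurwitz`, and
#'   `classification` (from eigenvalue real parts; agrees with the
#'   Routh-Hurwitz verdict away from marginal cases).
#' @export
stability_report <- function(eq, params, tol = 1e-8) {
  if (is.numeric(eq)) eq <- new_equilibrium("point", eq, TRUE, params)
  J <- klepto_jacobian(eq$state, params)
  cc <- characteristic_coefficients(J)
  rh <- routh_hurwitz(cc[1], cc[2], cc[3], tol = tol)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  cls <- if (any(abs(re) <= tol)) "marginal"
         else if (all(re < 0)) "stable" else "unstable"
  structure(list(label = eq$label, state = eq$state, eigenvalues = ev,
                 char_coeffs = cc, routh_hurwitz = rh,
                 classification = cls),
            class = "klepto_stability")
}

#' @export
print.klepto_stability <- function(x, ...) {
  cat(sprintf("%s: %s  (c1 = %.6g, c2 = %.6g, c3 = %.6g, c1c2-c3 = %.6g)\n",
              x$label, x$classification, x$char_coeffs[1], x$char_coeffs[2],
              x$char_coeffs[3], x$routh_hurwitz$c1c2_minus_c3))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Parametric stability conditions for every equilibrium
#'
#' Evaluates the closed-form local-stability criteria at each equilibrium
#' and cross-checks every verdict against the eigenvalues of the exact
#' Jacobian:
#' * `E0` is always an unstable saddle (eigenvalues `1, -A3, -A7`);
#' * `E1` is stable iff `A1 A3 > A4` and `A7 > A5`;
#' * `E2` is stable if `A1 A3 < A4`,
#'   `A5 > (A4 A6 - A1 A3 A6)/(A1 A3)` (the direction the proof and the
#'   numerical verification use; note the transverse eigenvalue analysis
#'   makes the `A8` inequality the decisive one), and
#'   `A8 < (A1 A3 A4 A5 + A1 A3 A4 A6 - A4^2 A6 - A4^2 A7) /
#'   (A1^2 A3^2 - A1 A3 A4)`; the additional proof-level inequality
#'   `A7 > (A1 A3 A5 + A1 A3 A6 - A4 A6)/A4` is evaluated and flagged
#'   as such;
#' * `E3` is stable if `A5 > A7` and `A4 <= (A2 A5^2 - 2 A2 A5 A7 +
#'   A2 A7^2 + A3 A5^2 - A3 A5 A7)/(A5 A7)`;
#' * the coexistence state is classified by [routh_hurwitz()].
#'
#' @param params a [klepto_params] object.
#' @return a named list of per-equilibrium reports.  Each report carries
#'   `applicable` (the equilibrium exists), `conditions` (named booleans),
#'   `values` (the numeric quantities entering each inequality), and the
#'   `stability` report ([stability_report()]) when applicable.
#' @export
#' @examples
#' rep <- stability_conditions(set_params(baseline_params(),
#'                                        A3 = 0.875, A4 = 0.0125))
#' rep$E1$conditions
stability_conditions <- function(params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  A5 <- p[["A5"]]; A6 <- p[["A6"]]; A7 <- p[["A7"]]; A8 <- p[["A8"]]
  bd <- boundary_equilibria(params)
  ints <- interior_equilibria(params)
  rep1 <- list(applicable = TRUE,
               conditions = c(A1A3_gt_A4 = A1 * A3 > A4, A7_gt_A5 = A7 > A5),
               values = c(A1A3 = A1 * A3, A4 = A4, A7 = A7, A5 = A5),
               stability = stability_report(bd$E1, params))
  e2_thr_A5 <- (A4 * A6 - A1 * A3 * A6) / (A1 * A3)
  e2_thr_A8 <- (A1 * A3 * A4 * A5 + A1 * A3 * A4 * A6 - A4^2 * A6 -
                  A4^2 * A7) / (A1^2 * A3^2 - A1 * A3 * A4)
  e2_thr_A7 <- (A1 * A3 * A5 + A1 * A3 * A6 - A4 * A6) / A4
  rep2 <- list(applicable = bd$E2$exists,
               conditions = c(A1A3_lt_A4 = A1 * A3 < A4,
                              A5_gt_threshold = A5 > e2_thr_A5,
                              A8_lt_threshold = A8 < e2_thr_A8,
                              A7_gt_threshold_prooflevel = A7 > e2_thr_A7),
               values = c(A1A3 = A1 * A3, A5_threshold = e2_thr_A5,
                          A8_threshold = e2_thr_A8,
                          A7_threshold_prooflevel = e2_thr_A7),
               stability = if (bd$E2$exists)
                 stability_report(bd$E2, params) else NULL)
  e3_thr <- e3_stability_threshold(params)
  rep3 <- list(applicable = bd$E3$exists,
               conditions = c(A5_gt_A7 = A5 > A7,
                              A4_le_threshold = A4 <= e3_thr),
               values = c(A5 = A5, A7 = A7, A4 = A4, A4_threshold = e3_thr),
               stability = if (bd$E3$exists)
                 stability_report(bd$E3, params) else NULL)
  out <- list(E0 = list(applicable = TRUE, conditions = c(always_unstable = TRUE),
                        values = c(eig1 = 1, eig2 = -A3, eig3 = -A7),
                        stability = stability_report(bd$E0, params)),
              E1 = rep1, E2 = rep2, E3 = rep3)
  for (e in ints)
    out[[e$label]] <- list(applicable = TRUE, conditions = NULL,
                           values = NULL,
                           stability = stability_report(e, params))
  out
}

# stability threshold on A4 for the host-free equilibrium E3
e3_stability_threshold <- function(params) {
  p <- unclass(params)
  A2 <- p[["A2"]]; A3 <- p[["A3"]]; A5 <- p[["A5"]]; A7 <- p[["A7"]]
  (A2 * A5^2 - 2 * A2 * A5 * A7 + A2 * A7^2 + A3 * A5^2 - A3 * A5 * A7) /
    (A5 * A7)
}

#' Box-and-weights configuration for global-stability certificates
#'
#' The Lyapunov-function arguments for global stability are sufficient
#' conditions parameterized by positive weights `L1, L2, L3` and a box
#' `lower < (S, P1, P2) < upper` assumed to contain the dynamics.
#'
#' @param L weights, positive numeric 3-vector.
#' @param lower,upper box bounds, positive numeric 3-vectors with
#'   `lower < upper` componentwise.
#' @return a `klepto_gs_config` object.
#' @export
global_stability_config <- function(L, lower, upper) {
  stopifnot(length(L) == 3, length(lower) == 3, length(upper) == 3,
            all(L > 0), all(lower > 0), all(lower < upper))
  structure(list(L = as.numeric(L), lower = as.numeric(lower),
                 upper = as.numeric(upper)), class = "klepto_gs_config")
}

#' Global-stability certificate for the predator-free state
#'
#' Checks the two sufficient inequalities under which the Lyapunov function
#' `V = L1 (S - 1 - log S) + L2 P1 + L3 P2` decreases along solutions in
#' the configured box (bounds `rho` on `S`, `vrho` on `P1`, `Gam` on `P2`):
#' \deqn{A_4 L_2 \varrho_2 \rho_2 < A_1 \Gamma_1 (A_2 L_2 \varrho_1 + A_7 L_3)}
#' \deqn{L_1(\varrho_2+\Gamma_2) + L_3 (A_5 + A_8 \varrho_2)\Gamma_2\rho_2
#'       < A_3 L_2 \varrho_1}
#' These are sufficient only: failure does not disprove global stability.
#'
#' @param params a [klepto_params] object.
#' @param cfg a [global_stability_config()].
#' @return list with `satisfied` (both inequalities hold), per-inequality
#'   booleans and margins (right side minus left side).
#' @export
global_stability_axial <- function(params, cfg) {
  stopifnot(inherits(cfg, "klepto_gs_config"))
  p <- unclass(params)
  L1 <- cfg$L[1]; L2 <- cfg$L[2]; L3 <- cfg$L[3]
  rho2 <- cfg$upper[1]
  vr1 <- cfg$lower[2]; vr2 <- cfg$upper[2]
  Gam1 <- cfg$lower[3]; Gam2 <- cfg$upper[3]
  lhs1 <- p[["A4"]] * L2 * vr2 * rho2
  rhs1 <- p[["A1"]] * Gam1 * (p[["A2"]] * L2 * vr1 + p[["A7"]] * L3)
  lhs2 <- L1 * (vr2 + Gam2) +
    L3 * (p[["A5"]] + p[["A8"]] * vr2) * Gam2 * rho2
  rhs2 <- p[["A3"]] * L2 * vr1
  list(satisfied = lhs1 < rhs1 && lhs2 < rhs2,
       ineq1 = lhs1 < rhs1, margin1 = rhs1 - lhs1,
       ineq2 = lhs2 < rhs2, margin2 = rhs2 - lhs2)
}

#' Global-stability certificate for a coexistence state
#'
#' Evaluates the five sufficient conditions under which the Lyapunov
#' function `W = L1 (S - S* - S* log(S/S*)) + L2 (...) + L3 (...)`
#' decreases in the configured box (bounds `theta` on `S`, `vtheta` on
#' `P1`, `Theta` on `P2`; the construction fixes `L1 = A5 L3`):
#' `P2* <= Theta2`; `L2 > Y2`; `A5 vt1 (P1* P2* (A6 - A8 S*) +
#' A5 (vt1 th1 - S* vt2)) > 0`; `A4 < Y3`; and `vt1 > Y4`, with the
#' thresholds
#' `Y2 = L3 (A6 P2* vt2 + A6 P1* Th2 + A5 P1* th2 + A8 vt2 Th2 th2) /
#' (A2 (vt1 Th1 - P2* vt2 + P1* (P2* - Th2)))`,
#' `Y3 = A1 A6 vt1 Th1 L3 (A1 + P2*) /
#' (L2 (2 A1 P1* S* + A1 vt2 th2 + P2* vt2 th2))` and
#' `Y4 = (P2* vt2 + P1* (Th2 - P2*)) / Th1`.
#'
#' @param params a [klepto_params] object.
#' @param eq an admissible interior `klepto_equilibrium`.
#' @param cfg a [global_stability_config()]; `cfg$L[1]` is overridden by
#'   `A5 * L3` as required by the construction.
#' @return list with `satisfied`, the named condition booleans, the
#'   computed thresholds `Y2, Y3, Y4`, and margins.
#' @export
global_stability_interior <- function(params, eq, cfg) {
  stopifnot(inherits(cfg, "klepto_gs_config"))
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A4 <- p[["A4"]]; A5 <- p[["A5"]]
  A6 <- p[["A6"]]; A8 <- p[["A8"]]
  Ss <- eq$state[[1]]; P1s <- eq$state[[2]]; P2s <- eq$state[[3]]
  L2 <- cfg$L[2]; L3 <- cfg$L[3]
  th1 <- cfg$lower[1]; th2 <- cfg$upper[1]
  vt1 <- cfg$lower[2]; vt2 <- cfg$upper[2]
  Th1 <- cfg$lower[3]; Th2 <- cfg$upper[3]
  Y2den <- A2 * (vt1 * Th1 - P2s * vt2 + P1s * (P2s - Th2))
  Y2 <- L3 * (A6 * P2s * vt2 + A6 * P1s * Th2 + A5 * P1s * th2 +
                A8 * vt2 * Th2 * th2) / Y2den
  Y3 <- A1 * A6 * vt1 * Th1 * L3 * (A1 + P2s) /
    (L2 * (2 * A1 * P1s * Ss + A1 * vt2 * th2 + P2s * vt2 * th2))
  Y4 <- (P2s * vt2 + P1s * (Th2 - P2s)) / Th1
  cond3 <- A5 * vt1 * (P1s * P2s * (A6 - A8 * Ss) +
                         A5 * (vt1 * th1 - Ss * vt2))
  conds <- c(P2star_le_Theta2 = P2s <= Th2,
             L2_gt_Y2 = L2 > Y2,
             cross_term_positive = cond3 > 0,
             A4_lt_Y3 = A4 < Y3,
             vtheta1_gt_Y4 = vt1 > Y4)
  list(satisfied = all(conds), conditions = conds,
       thresholds = c(Y2 = Y2, Y3 = Y3, Y4 = Y4),
       margins = c(Th2 - P2s, L2 - Y2, cond3, Y3 - A4, vt1 - Y4))
}

#' Sample the Lyapunov derivative inside a certificate box
#'
#' Monte-Carlo check that the Lyapunov function underlying a certificate
#' actually decreases: samples states uniformly in the box and evaluates
#' `dV/dt` (axial certificate, target `E1`) or `dW/dt` (interior
#' certificate, target `eq`).
#'
#' @inheritParams global_stability_interior
#' @param target `"axial"` or an interior `klepto_equilibrium`.
#' @param n number of sample states.
#' @param seed RNG seed (recorded in the output).
#' @return list with `max_derivative`, `all_negative`, `n`, `seed`.
#' @export
lyapunov_derivative_sample <- function(params, cfg, target = "axial",
                                       n = 10000, seed = 1) {
  stopifnot(inherits(cfg, "klepto_gs_config"))
  set.seed(seed)
  L <- cfg$L
  if (identical(target, "axial")) {
    star <- c(1, 0, 0)
    dV <- function(x) {
      r <- klepto_rhs(x, params)
      L[1] * (x[1] - 1) / x[1] * r[1] + L[2] * r[2] + L[3] * r[3]
    }
  } else {
    star <- target$state
    L[1] <- unclass(params)[["A5"]] * L[3]
    dV <- function(x) {
      r <- klepto_rhs(x, params)
      sum(L * (x - star) / x * r)
    }
  }
  u <- matrix(stats::runif(3 * n), ncol = 3)
  xs <- sweep(sweep(u, 2, cfg$upper - cfg$lower, "*"), 2, cfg$lower, "+")
  d <- apply(xs, 1, dV)
  list(max_derivative = max(d), all_negative = all(d < 0),
       n = n, seed = seed)
}

#' Search for a certificate configuration on a deterministic lattice
#'
#' Coarse grid search over weights and box bounds for
#' [global_stability_axial()].  The lattice spans weight ratios of
#' `10^-2 .. 10^2` and a family of boxes (full-orthant boxes with several
#' floor levels, plus thin slabs at low prey density, where the two
#' inequalities are easiest to reconcile).  Deterministic (no
#' randomness); returns the first satisfying configuration, or `NULL`
#' when none is found at this resolution -- which proves nothing about
#' instability.
#'
#' @param params a [klepto_params] object.
#' @param n_grid lattice resolution per weight dimension.
#' @return a [global_stability_config()] or `NULL`.
#' @export
search_axial_certificate <- function(params, n_grid = 4) {
  weights <- 10^seq(-2, 2, length.out = n_grid + 1)
  boxes <- list()
  for (lo in c(1e-4, 1e-3, 1e-2))
    boxes[[length(boxes) + 1]] <- list(lower = rep(lo, 3),
                                       upper = rep(1.05, 3))
  for (s in list(c(1e-3, 0.01), c(0.01, 0.1), c(0.05, 0.5)))
    boxes[[length(boxes) + 1]] <- list(lower = c(s[1], 0.9, 0.9),
                                       upper = c(s[2], 1.1, 1.1))
  for (L1 in c(1e-3, 1e-2)) for (L2 in weights) for (L3 in weights)
    for (b in boxes) {
      cfg <- global_stability_config(L = c(L1, L2, L3),
                                     lower = b$lower, upper = b$upper)
      if (global_stability_axial(params, cfg)$satisfied) return(cfg)
    }
  NULL
}
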