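#' Boundary equilibria in closed form
#'
#' The system always has the extinction state `E0 = (0,0,0)` and the
#' predator-free state `E1 = (1,0,0)` (prey at carrying capacity).  The
#' kleptoparasite-free state `E2 = (A1 A3/A4, 1 - A1 A3/A4, 0)` exists iff
#' `A4 > A1 A3` (host growth exceeds death at full prey density), and the
#' host-free state `E3 = (A7/A5, 0, 1 - A7/A5)` exists iff `A5 > A7`.  The
#' prey-free candidate `E4 = (0, -A7/A6, -A3/A2)` has negative coordinates
#' and is always reported as non-existent.
#'
#' @param params a [klepto_params] object.
#' @return a named list of `klepto_equilibrium` objects
#'   (`E0, E1, E2, E3, E4`), each with fields `label`, `state`, `exists`
#'   and `residual` (norm of the vector field at the point).
#' @export
#' @examples
#' boundary_equilibria(baseline_params())$E2$state  # (0.1, 0.9, 0)
boundary_equilibria <- function(params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  A5 <- p[["A5"]]; A6 <- p[["A6"]]; A7 <- p[["A7"]]
  mk <- function(label, state, exists)
    new_equilibrium(label, state, exists, params)
  out <- list(
    E0 = mk("E0", c(0, 0, 0), TRUE),
    E1 = mk("E1", c(1, 0, 0), TRUE),
    E2 = mk("E2", c(A1 * A3 / A4, (A4 - A1 * A3) / A4, 0), A4 > A1 * A3),
    E3 = mk("E3", c(A7 / A5, 0, (A5 - A7) / A5), A5 > A7),
    E4 = mk("E4", c(0, -A7 / A6, -A3 / A2), FALSE)
  )
  out
}

new_equilibrium <- function(label, state, exists, params) {
  res <- sqrt(sum(klepto_rhs(state, params)^2))
  structure(list(label = label,
                 state = stats::setNames(as.numeric(state),
                                         c("S", "P1", "P2")),
                 exists = isTRUE(exists), residual = res),
            class = "klepto_equilibrium")
}

#' @export
print.klepto_equilibrium <- function(x, ...) {
  cat(sprintf("%s: (S, P1, P2) = (%.6g, %.6g, %.6g)  [%s, |rhs| = %.2e]\n",
              x$label, x$state[1], x$state[2], x$state[3],
              if (x$exists) "exists" else "not admissible", x$residual))
  invisible(x)
}

#' Coefficients of the prey-density quartic
#'
#' Eliminating `P1` and `P2` from the three nullclines reduces the interior
#' equilibrium condition to a degree-4 polynomial
#' `g1 S^4 + g2 S^3 + g3 S^2 + g4 S + g5 = 0` in the prey density.  The
#' closed-form coefficients are returned in decreasing degree; `g1` and
#' `g5` are positive for any admissible parameter set.
#'
#' @param params a [klepto_params] object.
#' @return numeric vector `c(g1, g2, g3, g4, g5)`.
#' @seealso [interior_equilibria()] which cross-checks its roots against
#'   this polynomial.
#' @export
quartic_coefficients <- function(params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  A5 <- p[["A5"]]; A6 <- p[["A6"]]; A7 <- p[["A7"]]; A8 <- p[["A8"]]
  g1 <- 4 * A2^2 * A8^2
  g2 <- -4 * A2 * A8 *
    (2 * A2 * (A5 + A6) + ((2 + A1) * A2 + A3 + A4) * A8)
  g3 <- 4 * A2 * (A2 * (A5 + A6)^2 +
    (A3 * A5 + 2 * (A3 + A4) * A6 + (2 + A1) * A2 * (A5 + 2 * A6) +
       2 * A2 * A7) * A8 +
    (1 + A1) * (A2 + A3) * A8^2)
  g4 <- -4 * A2 * (A4 * A6^2 + A3 * A6 * (A5 + A6) +
    A2 * (A5 + A6) * ((2 + A1) * A6 + 2 * A7) +
    A3 * (2 * (1 + A1) * A6 + A7) * A8 +
    A2 * (2 * (1 + A1) * A6 + (2 + A1) * A7) * A8)
  g5 <- 4 * A2 * (A6 + A1 * A6 + A7) * (A3 * A6 + A2 * (A6 + A7))
  stats::setNames(c(g1, g2, g3, g4, g5), paste0("g", 1:5))
}

# elimination quartic derived independently of the tabulated coefficients:
# substitute P1 = (A7 - A5 S)/(A8 S - A6), P2 = 1 - S - P1 into the host
# nullcline quadratic A2 P2^2 + (A1 A2 + A3) P2 + (A1 A3 - A4 S) = 0 and
# clear the denominator (A8 S - A6)^2.  Agrees with quartic_coefficients()
# up to the common positive factor 4 A2.
elimination_quartic <- function(params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  A5 <- p[["A5"]]; A6 <- p[["A6"]]; A7 <- p[["A7"]]; A8 <- p[["A8"]]
  # q(S) = P2 * (A8 S - A6) = (1 - S)(A8 S - A6) - (A7 - A5 S), quadratic
  q <- c(-A8, A8 + A6 + A5, -A6 - A7)              # S^2, S, 1
  den <- c(A8, -A6)                                # A8 S - A6
  polymul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
        out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  t1 <- A2 * polymul(q, q)                                    # deg 4
  t2 <- (A1 * A2 + A3) * polymul(q, den)                      # deg 3
  t3 <- polymul(c(-A4, A1 * A3), polymul(den, den))           # deg 3
  pad <- function(v, n) c(numeric(n - length(v)), v)
  pad(t1, 5) + pad(t2, 5) + pad(t3, 5)
}

# positive root of the host nullcline quadratic
# A2 z^2 + (A1 A2 + A3) z + (A1 A3 - A4 S) = 0; NA when no real root,
# negative value allowed (caller filters)
p2_of_s <- function(S, params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  disc <- (A1 * A2 + A3)^2 - 4 * A2 * (A1 * A3 - A4 * S)
  ifelse(disc < 0, NA_real_,
         (-(A1 * A2 + A3) + sqrt(pmax(disc, 0))) / (2 * A2))
}

# closed forms for P1*, P2* in terms of S*; kept as a consistency
# check on the nullcline reduction, not as the primary route
closed_form_interior <- function(S, params) {
  p <- unclass(params)
  A1 <- p[["A1"]]; A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  rt <- sqrt(A1^2 * A2^2 - 2 * A1 * A2 * A3 + 4 * A2 * A4 * S + A3^2)
  P1 <- 0.5 * (-rt / A2 + A1 + A3 / A2 - 2 * S + 2)
  P2 <- (rt - A1 * A2 - A3) / (2 * A2)
  c(S = S, P1 = P1, P2 = P2)
}

# f(S): kleptoparasite nullcline along the curve
# (S, P1(S), P2(S)) defined by the prey and host nullclines
interior_fS <- function(S, params) {
  p <- unclass(params)
  P2 <- p2_of_s(S, params)
  P1 <- 1 - S - P2
  p[["A5"]] * S - p[["A6"]] * P1 - p[["A7"]] + p[["A8"]] * P1 * S
}

#' Interior (coexistence) equilibria
#'
#' Finds every admissible interior equilibrium by nullcline reduction: on
#' the prey nullcline `P1 + P2 = 1 - S`; the host nullcline gives `P2(S)`
#' as the positive root of a quadratic (admissible only when
#' `A4 S > A1 A3`); the remaining scalar equation
#' `f(S) = A5 S - A6 P1 + A8 P1 S - A7 = 0` is solved on `(0, 1)` by a
#' uniform bracketing scan followed by bisection/secant refinement
#' ([stats::uniroot()] with tolerance near machine precision).  Roots are
#' admissible when all three coordinates exceed `tol`.  Each solution is
#' cross-checked against the prey-density quartic
#' ([quartic_coefficients()]).
#'
#' Multiple coexistence states can occur (the model is bistable in parts
#' of parameter space); they are labeled `interior-1`, `interior-2`, ...
#' by ascending prey density.
#'
#' @param params a [klepto_params] object.
#' @param tol admissibility tolerance: a coordinate counts as positive
#'   when it exceeds `tol`.  Boundary-grazing roots are returned with
#'   `exists = FALSE` and a warning.
#' @param n_scan number of subintervals in the bracketing scan of `(0, 1)`.
#' @return a list of `klepto_equilibrium` objects (possibly empty),
#'   ordered by ascending `S`.
#' @export
#' @examples
#' eq <- interior_equilibria(baseline_params())
#' eq[[1]]$state["S"]  # ~0.844371
interior_equilibria <- function(params, tol = 1e-9, n_scan = 4096) {
  f <- function(S) interior_fS(S, params)
  Sg <- seq(1e-12, 1 - 1e-12, length.out = n_scan + 1)
  fv <- f(Sg)
  roots <- numeric(0)
  for (i in seq_len(n_scan)) {
    a <- fv[i]; b <- fv[i + 1]
    if (is.na(a) || is.na(b)) next
    if (a == 0) roots <- c(roots, Sg[i])
    else if (a * b < 0)
      roots <- c(roots, stats::uniroot(f, c(Sg[i], Sg[i + 1]),
                                       tol = 1e-14)$root)
  }
  out <- list()
  grazing <- 0L
  for (S in roots) {
    P2 <- p2_of_s(S, params)
    if (is.na(P2)) next
    P1 <- 1 - S - P2
    admissible <- S > tol && P1 > tol && P2 > tol
    if (!admissible && P1 > -tol && P2 > -tol) grazing <- grazing + 1L
    if (admissible)
      out[[length(out) + 1L]] <- new_equilibrium("interior",
                                                 c(S, P1, P2), TRUE, params)
  }
  if (grazing > 0L)
    warning(grazing, " boundary-grazing interior root(s) discarded")
  if (length(out) > 1L) {
    ord <- order(vapply(out, function(e) e$state[["S"]], 0))
    out <- out[ord]
  }
  for (k in seq_along(out)) out[[k]]$label <- paste0("interior-", k)
  out
}

#' Interior equilibria via the prey-density quartic
#'
#' Independent second route to the coexistence equilibria: the roots of
#' the degree-4 elimination polynomial ([quartic_coefficients()]) are
#' computed with [base::polyroot()]; real roots in `(0, 1)` are completed
#' to full states with the closed-form predator densities and filtered
#' for admissibility.  Used to cross-check [interior_equilibria()].
#'
#' @inheritParams interior_equilibria
#' @param imag_tol magnitude below which a root's imaginary part is
#'   treated as numerical noise.
#' @return a list of `klepto_equilibrium` objects ordered by ascending
#'   prey density.
#' @export
interior_equilibria_quartic <- function(params, tol = 1e-9,
                                        imag_tol = 1e-7) {
  g <- quartic_coefficients(params)
  roots <- polyroot(rev(g))          # polyroot wants ascending degree
  S <- Re(roots[abs(Im(roots)) < imag_tol * pmax(1, Mod(roots))])
  S <- S[S > tol & S < 1 - tol]
  out <- list()
  for (s in S) {
    P2 <- p2_of_s(s, params)
    if (is.na(P2)) next
    P1 <- 1 - s - P2
    if (P2 > tol && P1 > tol) {
      e <- new_equilibrium("interior", c(s, P1, P2), TRUE, params)
      # the quartic also carries roots belonging to the negative branch of
      # the host-nullcline quadratic; keep genuine equilibria only
      if (e$residual < 1e-6) out[[length(out) + 1L]] <- e
    }
  }
  if (length(out) > 1L)
    out <- out[order(vapply(out, function(e) e$state[["S"]], 0))]
  for (k in seq_along(out)) out[[k]]$label <- paste0("interior-", k)
  out
}

#' All equilibria of the scaled system
#'
#' @inheritParams interior_equilibria
#' @return a list combining [boundary_equilibria()] and
#'   [interior_equilibria()].
#' @export
equilibria <- function(params, tol = 1e-9) {
  c(boundary_equilibria(params), interior_equilibria(params, tol = tol))
}

#' @export
as.data.frame.klepto_equilibrium <- function(x, ...) {
  data.frame(label = x$label, S = x$state[[1]], P1 = x$state[[2]],
             P2 = x$state[[3]], exists = x$exists, residual = x$residual)
}

equilibria_table <- function(eqs) {
  do.call(rbind, lapply(eqs, as.data.frame))
}
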