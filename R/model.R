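#' Scaled vector field of the kleptoparasitism model
#'
#' Right-hand side of the nondimensional system in the scaled densities
#' `(S, P1, P2)` (prey, host predator, kleptoparasite):
#' \deqn{dS/dt = S(1-S) - S P_1 - S P_2}
#' \deqn{dP_1/dt = A_4 S P_1/(A_1+P_2) - A_2 P_1 P_2 - A_3 P_1}
#' \deqn{dP_2/dt = A_5 S P_2 - A_6 P_1 P_2 - A_7 P_2 + A_8 P_1 P_2 S}
#' The field is smooth on the closed positive orthant (`A1 > 0` keeps the
#' host's food-share denominator away from zero) and each coordinate
#' hyperplane is invariant: a species absent at time zero stays absent.
#'
#' @param state numeric 3-vector `(S, P1, P2)`, all non-negative.
#' @param params a [klepto_params] object (or coercible named vector).
#' @return numeric 3-vector of growth rates.
#' @export
#' @examples
#' klepto_rhs(c(1, 0, 0), baseline_params())  # predator-free equilibrium
klepto_rhs <- function(state, params) {
  p <- unclass(params)
  S <- state[[1]]; P1 <- state[[2]]; P2 <- state[[3]]
  c(S * (1 - S) - S * P1 - S * P2,
    p[["A4"]] * S * P1 / (p[["A1"]] + P2) - p[["A2"]] * P1 * P2 -
      p[["A3"]] * P1,
    p[["A5"]] * S * P2 - p[["A6"]] * P1 * P2 - p[["A7"]] * P2 +
      p[["A8"]] * P1 * P2 * S)
}

#' Dimensional vector field
#'
#' The original (unscaled) system in densities `(s, p1, p2)`:
#' prey grows logistically and is consumed by both predators with linear
#' (Holling type-I) responses; the host predator converts only the fraction
#' `1/(1 + a p2)` of its kills that the kleptoparasite does not steal; the
#' kleptoparasite gains `r6 s p1 p2` from stolen food (with
#' `r6 = r6_prime a r2`, the counter-attack-discounted conversion) on top
#' of its own predation.
#'
#' @param state numeric 3-vector `(s, p1, p2)` in original units.
#' @param dparams a [dimensional_params] object.
#' @return numeric 3-vector of growth rates.
#' @export
klepto_rhs_dimensional <- function(state, dparams) {
  d <- unclass(dparams)
  s <- state[[1]]; p1 <- state[[2]]; p2 <- state[[3]]
  r6 <- d[["r6_prime"]] * d[["a"]] * d[["r2"]]
  c(d[["r1"]] * s * (1 - s / d[["k"]]) - s * p1 * d[["r2"]] -
      s * p2 * d[["r3"]],
    d[["r4"]] * d[["r2"]] * s * p1 / (1 + d[["a"]] * p2) -
      d[["k1"]] * p1 * p2 - d[["d2"]] * p1,
    d[["r5"]] * s * p2 * d[["r3"]] - d[["k2"]] * p1 * p2 -
      d[["d3"]] * p2 + r6 * p1 * p2 * s)
}

#' Exact Jacobian of the scaled vector field
#'
#' Closed-form variational matrix; no numerical differentiation.
#'
#' @inheritParams klepto_rhs
#' @return a 3x3 numeric matrix.
#' @export
klepto_jacobian <- function(state, params) {
  p <- unclass(params)
  S <- state[[1]]; P1 <- state[[2]]; P2 <- state[[3]]
  u <- p[["A1"]] + P2
  A2 <- p[["A2"]]; A3 <- p[["A3"]]; A4 <- p[["A4"]]
  A5 <- p[["A5"]]; A6 <- p[["A6"]]; A7 <- p[["A7"]]; A8 <- p[["A8"]]
  matrix(c(
    1 - 2 * S - P1 - P2,            -S,                        -S,
    A4 * P1 / u,  A4 * S / u - A2 * P2 - A3,  -A4 * S * P1 / u^2 - A2 * P1,
    A5 * P2 + A8 * P1 * P2,  -A6 * P2 + A8 * P2 * S,
    A5 * S - A6 * P1 - A7 + A8 * P1 * S),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("S", "P1", "P2"), c("S", "P1", "P2")))
}

# Contraction of the r-th derivative tensor of the scaled vector field at
# `state` with the vectors in `vs` (list of length r; complex allowed --
# the forms are multilinear so plain complex arithmetic is exact).
# Orders 2..5 are exact closed forms: the only non-polynomial term is the
# host growth A4*S*P1/(A1+P2), for which d^m/dP2^m 1/(A1+P2) =
# (-1)^m m!/(A1+P2)^(m+1); the P2-equation is cubic, the prey equation
# quadratic.
deriv_tensor <- function(state, params, vs) {
  p <- unclass(params)
  r <- length(vs)
  S <- state[[1]]; P1 <- state[[2]]; P2 <- state[[3]]
  u <- p[["A1"]] + P2
  A2 <- p[["A2"]]; A4 <- p[["A4"]]; A5 <- p[["A5"]]
  A6 <- p[["A6"]]; A8 <- p[["A8"]]
  gm <- function(m) if (m < 0) 0 else (-1)^m * factorial(m) / u^(m + 1)
  vS <- vapply(vs, function(v) v[[1]], complex(1))
  vP1 <- vapply(vs, function(v) v[[2]], complex(1))
  vP2 <- vapply(vs, function(v) v[[3]], complex(1))
  # rational host-growth term: at most one slot differentiates S, one P1,
  # the rest act on 1/(A1+P2)
  f2 <- S * P1 * gm(r) * prod(vP2)
  for (i in seq_len(r)) {
    rest <- prod(vP2[-i])
    f2 <- f2 + (vS[i] * P1 + S * vP1[i]) * gm(r - 1) * rest
    if (r >= 2) for (j in seq_len(r)) if (j != i)
      f2 <- f2 + vS[i] * vP1[j] * gm(r - 2) * prod(vP2[-c(i, j)])
  }
  f2 <- A4 * f2
  if (r == 2) {
    f1 <- -2 * vS[1] * vS[2] - (vS[1] * vP1[2] + vS[2] * vP1[1]) -
      (vS[1] * vP2[2] + vS[2] * vP2[1])
    f2 <- f2 - A2 * (vP1[1] * vP2[2] + vP1[2] * vP2[1])
    f3 <- (A5 + A8 * P1) * (vS[1] * vP2[2] + vS[2] * vP2[1]) +
      (-A6 + A8 * S) * (vP1[1] * vP2[2] + vP1[2] * vP2[1]) +
      A8 * P2 * (vS[1] * vP1[2] + vS[2] * vP1[1])
  } else if (r == 3) {
    f1 <- 0 + 0i
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    f3 <- A8 * sum(vapply(perms,
      function(pp) vS[pp[1]] * vP1[pp[2]] * vP2[pp[3]], complex(1)))
  } else {
    f1 <- 0 + 0i
    f3 <- 0 + 0i
  }
  c(f1, f2, f3)
}

# real-valued convenience wrappers used by tests and the Sotomayor report
bilinear_form <- function(state, params, v, w) {
  out <- deriv_tensor(state, params, list(as.complex(v), as.complex(w)))
  if (all(Im(out) == 0)) Re(out) else out
}

trilinear_form <- function(state, params, v, w, z) {
  out <- deriv_tensor(state, params,
                      list(as.complex(v), as.complex(w), as.complex(z)))
  if (all(Im(out) == 0)) Re(out) else out
}

check_state <- function(state, tol = 0) {
  if (length(state) != 3 || !is.numeric(state) || anyNA(state))
    stop("state must be a numeric 3-vector (S, P1, P2)")
  if (any(state < -tol))
    stop("state components must be non-negative")
  invisible(state)
}
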