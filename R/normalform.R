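#' Hopf normal form on the center manifold
#'
#' At an equilibrium whose Jacobian has a simple purely imaginary pair
#' `+/- i omega` (and a third eigenvalue off the imaginary axis), the flow
#' restricted to the two-dimensional center manifold reduces, in a complex
#' coordinate `w`, to the Poincare normal form
#' \deqn{\dot w = i\omega w + \sigma_1 w|w|^2 + \sigma_2 w|w|^4 + \dots}
#' The first and second Lyapunov coefficients reported here are
#' `l1 = Re(sigma1)/omega` and `l2 = Re(sigma2)/omega`: `l1 > 0` marks a
#' subcritical Hopf bifurcation (unstable cycle), `l1 < 0` a supercritical
#' one (stable cycle); `l1 = 0` with `l2 != 0` is a Bautin (generalized
#' Hopf) point.
#'
#' The computation follows the standard projection/center-manifold
#' procedure: the critical eigenvectors `q` (with `A q = i omega q`,
#' normalized to `<q,q> = 1`) and adjoint `p` (`A^T p = -i omega p`,
#' `<p,q> = 1`) are combined with the exact multilinear forms of the
#' vector field (orders 2-5, closed form), and the homological equations
#' are solved order by order; the resonant projections yield `sigma1`
#' (order 3) and `sigma2` (order 5, computed with the order-3 and order-4
#' manifold coefficients and the `sigma1` transport corrections).  The
#' resonant solve for the `w^2 \bar w` manifold coefficient uses a
#' bordered system with the normalization `<p, h21> = 0`.
#'
#' `l1` is invariant under the remaining eigenvector phase freedom
#' `q -> exp(i phi) q`; `l2` is reported in the same convention and is
#' meaningful by sign (and as a scale-consistent magnitude within this
#' package).  Quadratic projections `g20 = <p, B(q,q)>`,
#' `g11 = <p, B(q,qbar)>` and the cubic projection `g21 = 2 sigma1` are
#' returned for reference; they are phase-convention dependent.
#'
#' @param eq a `klepto_equilibrium` or numeric 3-vector at (or very near)
#'   a Hopf point.
#' @param params a [klepto_params] object.
#' @param order `1` for `l1` only, `2` to also compute `l2`.
#' @param re_tol maximum allowed `|Re lambda|` of the critical pair.
#' @param phase optional rotation applied to `q` (used to test phase
#'   invariance).
#' @return an object of class `klepto_normalform`: list with `omega`,
#'   `q`, `p`, `g20`, `g11`, `g21`, `sigma1`, `l1`, and (for
#'   `order >= 2`) `sigma2`, `l2`.
#' @export
#' @examples
#' p <- set_params(baseline_params(), A5 = 2.007197)
#' eq <- interior_equilibria(p)[[1]]
#' hopf_normal_form(eq, p)$l1  # < 0: supercritical
hopf_normal_form <- function(eq, params, order = 1, re_tol = 1e-6,
                             phase = 0) {
  x <- if (inherits(eq, "klepto_equilibrium")) eq$state else eq
  A <- klepto_jacobian(x, params)
  ev <- eigen(A)
  iu <- which(Im(ev$values) > 0)
  if (length(iu) == 0)
    stop("Jacobian has no complex eigenvalue pair")
  iu <- iu[which.min(abs(Re(ev$values[iu])))]
  lam <- ev$values[iu]
  if (abs(Re(lam)) > re_tol)
    stop(sprintf("critical pair is not purely imaginary (Re = %.3g)",
                 Re(lam)))
  om <- Im(lam)
  q <- ev$vectors[, iu]
  q <- q / sqrt(sum(Conj(q) * q))
  if (phase != 0) q <- exp(1i * phase) * q
  evt <- eigen(t(A))
  ia <- which.min(Mod(evt$values - Conj(lam)))
  pv <- evt$vectors[, ia]
  pv <- pv / Conj(sum(Conj(pv) * q))        # <p, q> = 1
  ip <- function(a, b) sum(Conj(a) * b)

  xs <- list()
  key <- function(j, k) paste0(j, ",", k)
  xs[[key(1, 0)]] <- q
  xs[[key(0, 1)]] <- Conj(q)
  getx <- function(j, k) xs[[key(j, k)]]

  # coefficient of w^a wbar^b in the nonlinear part of F(H(w, wbar)),
  # H = sum x_jk w^j wbar^k over the coefficients known so far
  n_coef <- function(a, b) {
    idx <- lapply(strsplit(names(xs), ","), as.integer)
    tot <- c(0, 0, 0) + 0i
    rec <- function(r, parts) {
      if (length(parts) == r) {
        sj <- sum(vapply(parts, `[`, 1L, 1))
        sk <- sum(vapply(parts, `[`, 1L, 2))
        if (sj == a && sk == b)
          tot <<- tot + deriv_tensor(x, params,
                                     lapply(parts, function(jk)
                                       getx(jk[1], jk[2]))) / factorial(r)
        return(invisible())
      }
      used <- if (length(parts))
        sum(vapply(parts, function(jk) jk[1] + jk[2], 1L)) else 0L
      rem <- a + b - used
      for (jk in idx)
        if (jk[1] + jk[2] <= rem - (r - length(parts) - 1L))
          rec(r, c(parts, list(jk)))
    }
    for (r in 2:min(5L, a + b)) rec(r, list())
    tot
  }
  solve_h <- function(a, b, rhsv)
    solve((1i * om * (a - b)) * diag(3) - A, rhsv)

  xs[[key(2, 0)]] <- solve_h(2, 0, n_coef(2, 0))
  xs[[key(1, 1)]] <- solve_h(1, 1, n_coef(1, 1))
  xs[[key(0, 2)]] <- Conj(getx(2, 0))

  N21 <- n_coef(2, 1)
  sigma1 <- ip(pv, N21)
  # singular resonant solve, bordered with the adjoint vector
  M <- rbind(cbind(1i * om * diag(3) - A, q), c(Conj(pv), 0))
  xs[[key(2, 1)]] <- solve(M, c(N21 - sigma1 * q, 0))[1:3]

  out <- list(omega = om, q = q, p = pv,
              g20 = ip(pv, deriv_tensor(x, params, list(q, q))),
              g11 = ip(pv, deriv_tensor(x, params, list(q, Conj(q)))),
              g21 = 2 * sigma1,
              sigma1 = sigma1, l1 = Re(sigma1) / om)
  class(out) <- "klepto_normalform"
  if (order < 2) return(out)

  xs[[key(3, 0)]] <- solve_h(3, 0, n_coef(3, 0))
  xs[[key(1, 2)]] <- Conj(getx(2, 1))
  xs[[key(0, 3)]] <- Conj(getx(3, 0))
  # order 4: transport corrections from the cubic normal-form term
  for (ab in list(c(3, 1), c(2, 2))) {
    a <- ab[1]; b <- ab[2]
    corr <- ((a - 1) * sigma1 + (b - 1) * Conj(sigma1)) * getx(a - 1, b - 1)
    xs[[key(a, b)]] <- solve_h(a, b, n_coef(a, b) - corr)
  }
  xs[[key(1, 3)]] <- Conj(getx(3, 1))
  N32 <- n_coef(3, 2)
  sigma2 <- ip(pv, N32 - (2 * sigma1 + Conj(sigma1)) * getx(2, 1))
  out$sigma2 <- sigma2
  out$l2 <- Re(sigma2) / om
  out
}

#' @export
print.klepto_normalform <- function(x, ...) {
  cat(sprintf("Hopf normal form: omega = %.6g\n", x$omega))
  cat(sprintf("  g20 = %s, g11 = %s, g21 = %s\n",
              format(x$g20, digits = 6), format(x$g11, digits = 6),
              format(x$g21, digits = 6)))
  cat(sprintf("  l1 = %.6g  (%s)\n", x$l1,
              if (x$l1 > 0) "subcritical" else "supercritical"))
  if (!is.null(x$l2)) cat(sprintf("  l2 = %.6g\n", x$l2))
  invisible(x)
}
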