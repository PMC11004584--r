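#' Continue equilibrium families across a parameter range
#'
#' Natural-parameter continuation by direct re-solve: at each grid value
#' the full set of interior equilibria is recomputed from the nullcline
#' reduction (which finds every admissible root, so branches are never
#' lost through folds), and families are stitched together by
#' prey-density continuity.  Boundary families (`E1`, `E2`, `E3`) are
#' evaluated from their closed forms.  Stability is recomputed at every
#' sample.
#'
#' @param params a [klepto_params] object (values off `param` are held
#'   fixed).
#' @param param name of the continuation parameter (`"A1"` ... `"A8"`).
#' @param range numeric length-2 vector, continuation interval.
#' @param n number of grid points.
#' @param match_tol relative prey-density jump allowed when stitching a
#'   family between consecutive grid values.
#' @return a `klepto_branch`: list with `param`, `range`, and `samples`,
#'   a data frame with columns `value`, `family` (`"interior-k"` or
#'   boundary label), `S`, `P1`, `P2`, `c1`, `c2`, `c3`, `V = c1 c2 - c3`,
#'   `re_max` (largest eigenvalue real part), `stable`, `exists`,
#'   `residual`.
#' @seealso [detect_fold()], [detect_hopf()], [detect_transcritical()]
#' @export
#' @examples
#' br <- continue_branch(baseline_params(), "A4", c(0.1, 2), n = 60)
#' subset(br$samples, family == "interior-1" & stable)[1, ]
continue_branch <- function(params, param, range, n = 401,
                            match_tol = 0.05) {
  stopifnot(param %in% param_names(), length(range) == 2)
  grid <- seq(range[1], range[2], length.out = max(n, 2))
  rows <- list()
  prev <- list()   # family name -> last S
  next_id <- 1L
  for (v in grid) {
    p <- set_params(params, stats::setNames(v, param))
    ints <- suppressWarnings(interior_equilibria(p))
    Ss <- vapply(ints, function(e) e$state[["S"]], 0)
    assigned <- character(length(ints))
    taken <- character(0)
    if (length(ints) > 0 && length(prev) > 0) {
      for (k in order(Ss)) {
        cand <- names(prev)[!(names(prev) %in% taken)]
        if (length(cand) == 0) break
        d <- abs(unlist(prev[cand]) - Ss[k])
        j <- which.min(d)
        if (d[j] < max(match_tol, match_tol * abs(Ss[k]))) {
          assigned[k] <- cand[j]
          taken <- c(taken, cand[j])
        }
      }
    }
    for (k in seq_along(ints)) {
      if (assigned[k] == "") {
        assigned[k] <- paste0("interior-", next_id)
        next_id <- next_id + 1L
      }
    }
    prev <- stats::setNames(as.list(Ss), assigned)
    eqs <- ints
    labels <- assigned
    bd <- boundary_equilibria(p)
    for (lb in c("E1", "E2", "E3")) {
      eqs <- c(eqs, list(bd[[lb]]))
      labels <- c(labels, lb)
    }
    for (k in seq_along(eqs)) {
      e <- eqs[[k]]
      st <- stability_report(e, p)
      cc <- st$char_coeffs
      rows[[length(rows) + 1L]] <- data.frame(
        value = v, family = labels[k],
        S = e$state[[1]], P1 = e$state[[2]], P2 = e$state[[3]],
        c1 = cc[[1]], c2 = cc[[2]], c3 = cc[[3]],
        V = cc[[1]] * cc[[2]] - cc[[3]],
        re_max = max(Re(st$eigenvalues)),
        stable = st$classification == "stable",
        exists = e$exists, residual = e$residual)
    }
  }
  structure(list(param = param, range = range, base = params,
                 samples = do.call(rbind, rows)),
            class = "klepto_branch")
}

#' @export
print.klepto_branch <- function(x, ...) {
  fams <- unique(x$samples$family)
  cat(sprintf("branch in %s over [%g, %g]: %d samples, families: %s\n",
              x$param, x$range[1], x$range[2], nrow(x$samples),
              paste(fams, collapse = ", ")))
  invisible(x)
}

# track one interior family: equilibrium nearest in S to Sref
family_member <- function(params, Sref) {
  ints <- suppressWarnings(interior_equilibria(params))
  if (length(ints) == 0) return(NULL)
  Ss <- vapply(ints, function(e) e$state[["S"]], 0)
  ints[[which.min(abs(Ss - Sref))]]
}

# Liu test function V = c1 c2 - c3 on the family nearest Sref
liu_V <- function(params, param, value, Sref) {
  p <- set_params(params, stats::setNames(value, param))
  e <- family_member(p, Sref)
  if (is.null(e)) return(NA_real_)
  cc <- characteristic_coefficients(klepto_jacobian(e$state, p))
  cc[[1]] * cc[[2]] - cc[[3]]
}

#' Locate fold (saddle-node) bifurcations
#'
#' A fold of the coexistence family is a parameter value at which two
#' interior equilibria coalesce and vanish.  The detector counts
#' admissible interior equilibria along the branch grid and refines every
#' change in count by bisection on the count transition (equivalent to a
#' zero of `det J` on the merging pair); the refined point is annotated
#' with the near-double equilibrium and its `det J`.
#'
#' @param branch a `klepto_branch` from [continue_branch()].
#' @param tol parameter tolerance of the bisection refinement.
#' @return a list of fold events: `value` (parameter), `state` (merging
#'   equilibrium), `det_jacobian`, `count_low`, `count_high`.
#' @export
#' @examples
#' br <- continue_branch(baseline_params(), "A3", c(0.02, 0.08), n = 40)
#' detect_fold(br)[[1]]$value  # ~0.04267
detect_fold <- function(branch, tol = 1e-10) {
  params <- branch$base; param <- branch$param
  grid <- sort(unique(branch$samples$value))
  ints <- branch$samples[grepl("^interior", branch$samples$family), ]
  counts <- vapply(grid, function(v) sum(ints$value == v), 0L)
  events <- list()
  n_at <- function(v)
    length(suppressWarnings(interior_equilibria(
      set_params(params, stats::setNames(v, param)))))
  for (i in seq_len(length(grid) - 1)) {
    if (counts[i] == counts[i + 1]) next
    lo <- grid[i]; hi <- grid[i + 1]
    clo <- counts[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (n_at(mid) == clo) lo <- mid else hi <- mid
    }
    vstar <- (lo + hi) / 2
    # annotate with the merging pair on the richer side
    rich <- if (n_at(lo) > n_at(hi)) lo else hi
    p <- set_params(params, stats::setNames(rich, param))
    es <- suppressWarnings(interior_equilibria(p))
    Ss <- vapply(es, function(e) e$state[["S"]], 0)
    if (length(es) < 2) next          # lone appearance: not a turning point
    j <- which.min(diff(sort(Ss)))
    pair <- es[order(Ss)][j:(j + 1)]
    # a genuine fold has the two roots coalescing at the refined value; a
    # count change with well-separated roots is an admissibility crossing
    # (a root entering or leaving the positive orthant), not a fold
    if (abs(pair[[2]]$state[["S"]] - pair[[1]]$state[["S"]]) > 1e-3) next
    state <- (pair[[1]]$state + pair[[2]]$state) / 2
    dj <- det(klepto_jacobian(state, p))
    events[[length(events) + 1L]] <- list(
      kind = "fold", value = vstar, state = state, det_jacobian = dj,
      count_low = n_at(vstar - 10 * tol - 1e-12),
      count_high = n_at(vstar + 10 * tol + 1e-12))
  }
  events
}

#' Locate Hopf bifurcations on interior families
#'
#' Applies the Liu criterion along each interior family of the branch:
#' a Hopf point is a zero of `V = c1 c2 - c3` with `c1, c2, c3 > 0`
#' (then the eigenvalues are `-c1` and `+/- i sqrt(c2)`).  Each sign
#' change is refined by bisection/secant on `V` while tracking the family
#' by prey-density continuity; the refined point is annotated with
#' `omega = sqrt(c2)`, the critical eigenvalues, the transversality value
#' of the eigenvalue-crossing speed, and the Hopf normal form
#' ([hopf_normal_form()]).  Transversality values within `degenerate_tol`
#' of zero are flagged degenerate.
#'
#' @param branch a `klepto_branch`.
#' @param tol parameter tolerance for the `V` root.
#' @param degenerate_tol threshold for flagging a degenerate crossing.
#' @return a list of Hopf events: `value`, `family`, `state`, `omega`,
#'   `transversality` (list with `numerator` and `d_re_lambda`),
#'   `normal_form`, `degenerate`.
#' @export
detect_hopf <- function(branch, tol = 1e-10, degenerate_tol = 1e-8) {
  params <- branch$base; param <- branch$param
  sm <- branch$samples[grepl("^interior", branch$samples$family), ]
  events <- list()
  for (fam in unique(sm$family)) {
    fs <- sm[sm$family == fam, ]
    fs <- fs[order(fs$value), ]
    for (i in seq_len(nrow(fs) - 1)) {
      V1 <- fs$V[i]; V2 <- fs$V[i + 1]
      if (!is.finite(V1) || !is.finite(V2) || V1 * V2 >= 0) next
      if (min(fs$c1[i:(i + 1)]) <= 0 || min(fs$c2[i:(i + 1)]) <= 0 ||
          min(fs$c3[i:(i + 1)]) <= 0) next
      Sref <- fs$S[i]
      f <- function(v) liu_V(params, param, v, Sref)
      root <- stats::uniroot(f, c(fs$value[i], fs$value[i + 1]),
                             tol = tol)$root
      p <- set_params(params, stats::setNames(root, param))
      e <- family_member(p, Sref)
      cc <- characteristic_coefficients(klepto_jacobian(e$state, p))
      tv <- hopf_transversality(params, param, root, Sref)
      nf <- try(hopf_normal_form(e, p, order = 1, re_tol = 1e-5),
                silent = TRUE)
      events[[length(events) + 1L]] <- list(
        kind = "hopf", value = root, family = fam, state = e$state,
        omega = sqrt(cc[[2]]),
        eigenvalues = eigen(klepto_jacobian(e$state, p),
                            only.values = TRUE)$values,
        transversality = tv,
        normal_form = if (inherits(nf, "try-error")) NULL else nf,
        degenerate = abs(tv$numerator) < degenerate_tol)
    }
  }
  events
}

#' Transversality of a Hopf eigenvalue crossing
#'
#' The non-degeneracy quantity `c1' c2 + c1 c2' - c3'` (primes are
#' derivatives of the characteristic coefficients with respect to the
#' bifurcation parameter) and the induced crossing speed of the critical
#' eigenvalue pair,
#' \deqn{\frac{d\,\mathrm{Re}\,\lambda}{d\mu} =
#'   -\frac{c_1' c_2 + c_1 c_2' - c_3'}{2(c_2 + c_1^2)},}
#' so a positive numerator (the Liu function `V = c1 c2 - c3` increasing)
#' moves the pair into the stable half-plane.
#'
#' Two derivative conventions are reported, both by central differences of
#' exactly recomputed coefficients:
#' * `numerator` -- total derivative along the equilibrium family (the
#'   equilibrium moves with the parameter); this is the convention under
#'   which the sign predicts the observed eigenvalue crossing and is the
#'   one used by [detect_hopf()];
#' * `numerator_frozen_prey` -- prey density frozen at its critical
#'   value while the predator densities follow their closed forms (a
#'   partial-derivative convention that some symbolic treatments of the
#'   crossing condition use); reported for reference, meaningful mainly
#'   by sign and nonzeroness.
#'
#' @param params base parameter set.
#' @param param continuation parameter name.
#' @param value parameter value (at the Hopf point).
#' @param Sref prey density identifying the family.
#' @param h relative finite-difference step.
#' @return list with `numerator`, `d_re_lambda`,
#'   `numerator_frozen_prey`, and the coefficient derivatives.
#' @export
hopf_transversality <- function(params, param, value, Sref,
                                h = 1e-6) {
  step <- h * max(1, abs(value))
  cc_at <- function(v) {
    p <- set_params(params, stats::setNames(v, param))
    e <- family_member(p, Sref)
    characteristic_coefficients(klepto_jacobian(e$state, p))
  }
  cp <- cc_at(value + step); cm <- cc_at(value - step)
  c0 <- cc_at(value)
  d <- (cp - cm) / (2 * step)
  num <- d[[1]] * c0[[2]] + c0[[1]] * d[[2]] - d[[3]]

  Sstar <- family_member(set_params(params, stats::setNames(value, param)),
                         Sref)$state[["S"]]
  cc_frozen <- function(v) {
    p <- set_params(params, stats::setNames(v, param))
    st <- closed_form_interior(Sstar, p)
    characteristic_coefficients(klepto_jacobian(st, p))
  }
  df <- (cc_frozen(value + step) - cc_frozen(value - step)) / (2 * step)
  cf <- cc_frozen(value)
  numf <- df[[1]] * cf[[2]] + cf[[1]] * df[[2]] - df[[3]]
  list(numerator = num,
       d_re_lambda = -num / (2 * (c0[[2]] + c0[[1]]^2)),
       numerator_frozen_prey = numf,
       dc = d, cc = c0)
}

#' Locate transcritical bifurcations
#'
#' A transcritical bifurcation occurs where an interior family crosses a
#' boundary family and the two exchange stability; at the crossing the
#' boundary equilibrium's Jacobian has a simple zero eigenvalue, so
#' `det J` vanishes there.  The detector scans `det J` along each
#' existing boundary family of the branch, refines each sign change by
#' bisection, reports which interior coordinate vanishes at the crossing,
#' and verifies the stability exchange on the two sides.
#'
#' @param branch a `klepto_branch`.
#' @param tol parameter tolerance of the refinement.
#' @return list of events: `value`, `boundary` (label), `state`,
#'   `vanishing` (`"P1"` or `"P2"`), `exchange` (stability verdicts on
#'   both sides for the boundary family), `sotomayor` (quantities from
#'   [sotomayor_quantities()], when the zero eigenvalue is simple).
#' @export
detect_transcritical <- function(branch, tol = 1e-12) {
  params <- branch$base; param <- branch$param
  events <- list()
  bd_at <- function(v, lb)
    boundary_equilibria(set_params(params,
                                   stats::setNames(v, param)))[[lb]]
  det_at <- function(v, lb) {
    p <- set_params(params, stats::setNames(v, param))
    det(klepto_jacobian(bd_at(v, lb)$state, p))
  }
  sm <- branch$samples
  for (lb in c("E1", "E2", "E3")) {
    fs <- sm[sm$family == lb & sm$exists, ]
    fs <- fs[order(fs$value), ]
    if (nrow(fs) < 2) next
    dets <- -(fs$c3)   # c3 = -det J
    for (i in seq_len(nrow(fs) - 1)) {
      if (!is.finite(dets[i]) || !is.finite(dets[i + 1]) ||
          dets[i] * dets[i + 1] >= 0) next
      root <- stats::uniroot(function(v) det_at(v, lb),
                             c(fs$value[i], fs$value[i + 1]),
                             tol = tol)$root
      p <- set_params(params, stats::setNames(root, param))
      e <- bd_at(root, lb)
      vanishing <- if (e$state[["P2"]] == 0) "P2" else "P1"
      sides <- vapply(c(fs$value[i], fs$value[i + 1]), function(v) {
        q <- set_params(params, stats::setNames(v, param))
        stability_report(bd_at(v, lb), q)$classification
      }, "")
      soto <- try(sotomayor_quantities(e, p, param), silent = TRUE)
      events[[length(events) + 1L]] <- list(
        kind = "transcritical", value = root, boundary = lb,
        state = e$state, vanishing = vanishing,
        exchange = stats::setNames(sides, c("below", "above")),
        sotomayor = if (inherits(soto, "try-error")) NULL else soto)
    }
  }
  events
}

# analytic derivative of the scaled vector field with respect to one
# parameter, and its state-Jacobian
param_derivative <- function(state, params, param) {
  S <- state[[1]]; P1 <- state[[2]]; P2 <- state[[3]]
  p <- unclass(params)
  u <- p[["A1"]] + P2
  A4 <- p[["A4"]]
  K <- c(0, 0, 0)
  DK <- matrix(0, 3, 3)
  switch(param,
    A1 = { K[2] <- -A4 * S * P1 / u^2
           DK[2, ] <- c(-A4 * P1 / u^2, -A4 * S / u^2,
                        2 * A4 * S * P1 / u^3) },
    A2 = { K[2] <- -P1 * P2; DK[2, ] <- c(0, -P2, -P1) },
    A3 = { K[2] <- -P1; DK[2, ] <- c(0, -1, 0) },
    A4 = { K[2] <- S * P1 / u
           DK[2, ] <- c(P1 / u, S / u, -S * P1 / u^2) },
    A5 = { K[3] <- S * P2; DK[3, ] <- c(P2, 0, S) },
    A6 = { K[3] <- -P1 * P2; DK[3, ] <- c(0, -P2, -P1) },
    A7 = { K[3] <- -P2; DK[3, ] <- c(0, 0, -1) },
    A8 = { K[3] <- P1 * P2 * S
           DK[3, ] <- c(P1 * P2, P2 * S, P1 * S) },
    stop("unknown parameter: ", param))
  list(K = K, DK = DK)
}

#' Sotomayor quantities at a degenerate equilibrium
#'
#' For an equilibrium whose Jacobian has a simple zero eigenvalue, the
#' transcritical scenario is characterized by the three quantities
#' `Q^T F_mu`, `Q^T (D F_mu) P` and `Q^T D^2 F (P, P)`, where `P` and `Q`
#' are right and left null vectors, `F_mu` is the parameter derivative of
#' the vector field (computed analytically) and `D^2 F (P, P)` is the full
#' second-derivative contraction (note: twice the symmetric-form value
#' some texts use).  Transcritical: first quantity zero, the others
#' nonzero.
#'
#' @param eq a `klepto_equilibrium` (or 3-vector).
#' @param params a [klepto_params] object.
#' @param param parameter name (`"A1"` ... `"A8"`).
#' @param P,Q optional null vectors; when `NULL` they are computed from
#'   the Jacobian and scaled so the largest-magnitude entry is `+1`
#'   (the normalization is recorded in the output).
#' @param zero_tol eigenvalue magnitude below which the zero eigenvalue is
#'   accepted; an error is thrown when it is absent or not simple.
#' @return list with `P`, `Q`, `q_Fmu`, `q_DFmu_P`, `q_D2F_PP`,
#'   `transcritical` (boolean pattern check), `normalization`.
#' @export
sotomayor_quantities <- function(eq, params, param, P = NULL, Q = NULL,
                                 zero_tol = 1e-7) {
  x <- if (inherits(eq, "klepto_equilibrium")) eq$state else eq
  J <- klepto_jacobian(x, params)
  ev <- eigen(J)
  iz <- which(abs(ev$values) < zero_tol)
  if (length(iz) != 1)
    stop("Jacobian does not have a simple zero eigenvalue")
  norm_rec <- "user-supplied null vectors"
  if (is.null(P)) {
    P <- Re(ev$vectors[, iz])
    P <- P / P[which.max(abs(P))]
    norm_rec <- "largest-magnitude entry scaled to +1"
  }
  if (is.null(Q)) {
    evt <- eigen(t(J))
    izt <- which(abs(evt$values) < zero_tol)[1]
    Q <- Re(evt$vectors[, izt])
    Q <- Q / Q[which.max(abs(Q))]
  }
  pd <- param_derivative(x, params, param)
  list(P = P, Q = Q,
       q_Fmu = sum(Q * pd$K),
       q_DFmu_P = sum(Q * (pd$DK %*% P)),
       q_D2F_PP = sum(Q * Re(bilinear_form(x, params, P, P))),
       transcritical = abs(sum(Q * pd$K)) < 1e-8 &&
         abs(sum(Q * (pd$DK %*% P))) > 1e-8 &&
         abs(sum(Q * Re(bilinear_form(x, params, P, P)))) > 1e-8,
       normalization = norm_rec)
}

#' Continue a Hopf curve in two parameters
#'
#' Traces the locus of Hopf points in the `(par1, par2)` plane: for each
#' value of `par1` on the grid, the Hopf condition `V = c1 c2 - c3 = 0`
#' (with `c1, c2, c3 > 0`) is solved for `par2` near the previous solution
#' (bracketing scan in a trust window, then bisection), with the interior
#' family tracked by prey-density continuity.  The first Lyapunov
#' coefficient is evaluated at every curve point.
#'
#' @param params base parameter set.
#' @param par1,par2 parameter names.
#' @param range1 grid interval for `par1` (traversed from `start1`
#'   outward is not needed: the grid runs from `range1[1]` to
#'   `range1[2]`, which should start near a known Hopf point).
#' @param start2 starting guess for `par2` at `range1[1]`.
#' @param Sref prey density identifying the interior family at the start.
#' @param n number of `par1` grid points.
#' @param window relative half-width of the `par2` search window.
#' @return a `klepto_hopf_curve`: data frame with columns `par1`, `par2`,
#'   `S`, `P1`, `P2`, `omega`, `l1`, plus attributes recording the
#'   parameter names and base set.  Rows where the curve left the window
#'   are dropped (curve truncated, with a warning).
#' @export
hopf_curve <- function(params, par1, par2, range1, start2, Sref,
                       n = 60, window = 0.5) {
  grid <- seq(range1[1], range1[2], length.out = n)
  cur2 <- start2; Sc <- Sref
  rows <- list()
  truncated <- FALSE
  for (v1 in grid) {
    base1 <- set_params(params, stats::setNames(v1, par1))
    f <- function(v2) liu_V(base1, par2, v2, Sc)
    lo <- cur2 * (1 - window); hi <- cur2 * (1 + window)
    vs <- seq(lo, hi, length.out = 81)
    Vv <- vapply(vs, f, 0)
    root <- NA_real_
    ord <- order(abs(vs - cur2))
    for (i in ord) {
      if (i >= length(vs)) next
      if (is.finite(Vv[i]) && is.finite(Vv[i + 1]) &&
          Vv[i] * Vv[i + 1] < 0) {
        root <- stats::uniroot(f, c(vs[i], vs[i + 1]), tol = 1e-12)$root
        break
      }
    }
    if (is.na(root)) { truncated <- TRUE; break }
    cur2 <- root
    p <- set_params(base1, stats::setNames(root, par2))
    e <- family_member(p, Sc)
    Sc <- e$state[["S"]]
    nf <- try(hopf_normal_form(e, p, order = 1, re_tol = 1e-5),
              silent = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      par1 = v1, par2 = root, S = e$state[[1]], P1 = e$state[[2]],
      P2 = e$state[[3]],
      omega = if (inherits(nf, "try-error")) NA_real_ else nf$omega,
      l1 = if (inherits(nf, "try-error")) NA_real_ else nf$l1)
  }
  if (truncated)
    warning("Hopf curve left the search window; curve truncated")
  out <- do.call(rbind, rows)
  attr(out, "par1") <- par1; attr(out, "par2") <- par2
  attr(out, "base") <- params; attr(out, "truncated") <- truncated
  class(out) <- c("klepto_hopf_curve", class(out))
  out
}

#' Locate Bautin (generalized Hopf) points on a Hopf curve
#'
#' Brackets every sign change of the first Lyapunov coefficient along a
#' computed Hopf curve and refines it by bisection in `par1` (re-solving
#' the Hopf condition in `par2` at every step), then evaluates the
#' second Lyapunov coefficient at the refined point.  A regular Bautin
#' point has `l1 = 0`, `l2 != 0`.
#'
#' @param curve a `klepto_hopf_curve` from [hopf_curve()].
#' @param iter number of bisection iterations.
#' @return list of Bautin events: `par1`, `par2`, `state`, `omega`,
#'   `l1` (residual, near zero), `l2`.
#' @export
#' @examples
#' \donttest{
#' cv <- hopf_curve(baseline_params(), "A5", "A1", c(2, 0.95),
#'                  start2 = 0.02, Sref = 0.85, n = 40)
#' bp <- bautin_points(cv)
#' }
bautin_points <- function(curve, iter = 45) {
  par1 <- attr(curve, "par1"); par2 <- attr(curve, "par2")
  params <- attr(curve, "base")
  l1_at <- function(v1, guess2, Sref, order = 1) {
    base1 <- set_params(params, stats::setNames(v1, par1))
    f <- function(v2) liu_V(base1, par2, v2, Sref)
    vs <- seq(guess2 * 0.8, guess2 * 1.2, length.out = 81)
    Vv <- vapply(vs, f, 0)
    root <- NA_real_
    for (i in order(abs(vs - guess2))) {
      if (i >= length(vs)) next
      if (is.finite(Vv[i]) && is.finite(Vv[i + 1]) &&
          Vv[i] * Vv[i + 1] < 0) {
        root <- stats::uniroot(f, c(vs[i], vs[i + 1]), tol = 1e-13)$root
        break
      }
    }
    if (is.na(root)) return(NULL)
    p <- set_params(base1, stats::setNames(root, par2))
    e <- family_member(p, Sref)
    list(v2 = root, e = e,
         nf = hopf_normal_form(e, p, order = order, re_tol = 1e-5))
  }
  events <- list()
  for (i in seq_len(nrow(curve) - 1)) {
    a <- curve$l1[i]; b <- curve$l1[i + 1]
    if (!is.finite(a) || !is.finite(b) || a * b >= 0) next
    lo <- curve$par1[i]; hi <- curve$par1[i + 1]
    slo <- a; guess2 <- curve$par2[i]; Sref <- curve$S[i]
    for (k in seq_len(iter)) {
      mid <- (lo + hi) / 2
      r <- l1_at(mid, guess2, Sref)
      if (is.null(r)) break
      guess2 <- r$v2; Sref <- r$e$state[["S"]]
      if (sign(r$nf$l1) == sign(slo)) { lo <- mid; slo <- r$nf$l1 }
      else hi <- mid
    }
    fin <- l1_at((lo + hi) / 2, guess2, Sref, order = 2)
    if (is.null(fin)) next
    events[[length(events) + 1L]] <- list(
      kind = "bautin", par1 = (lo + hi) / 2, par2 = fin$v2,
      state = fin$e$state, omega = fin$nf$omega,
      l1 = fin$nf$l1, l2 = fin$nf$l2)
  }
  events
}

#' Export a branch or events to disk
#'
#' Branch samples are written as CSV (columns as in
#' [continue_branch()], floating values at 9 significant digits);
#' bifurcation events as a JSON array of records.
#'
#' @param branch a `klepto_branch`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  df <- branch$samples
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_branch_csv
#' @param events a list of event records (from [detect_fold()],
#'   [detect_hopf()], [detect_transcritical()] or [bautin_points()]).
#' @export
write_events_json <- function(events, path) {
  slim <- lapply(events, function(e) {
    e$normal_form <- if (!is.null(e$normal_form))
      list(omega = e$normal_form$omega, l1 = e$normal_form$l1,
           l2 = e$normal_form$l2) else NULL
    e$eigenvalues <- if (!is.null(e$eigenvalues))
      list(re = Re(e$eigenvalues), im = Im(e$eigenvalues)) else NULL
    e$sotomayor <- if (!is.null(e$sotomayor))
      e$sotomayor[c("q_Fmu", "q_DFmu_P", "q_D2F_PP", "transcritical")]
      else NULL
    e
  })
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
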