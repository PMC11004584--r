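#' Integrate the scaled system
#'
#' Adaptive, stiff-capable integration of the scaled vector field with
#' [deSolve::ode()] (`lsoda`, which switches between Adams and BDF as the
#' local stiffness demands -- the system is moderately stiff near folds).
#' Exact zeros on invariant hyperplanes are preserved: a component that
#' starts at zero is clamped to zero, and tiny negative excursions (within
#' integrator tolerance) are clamped and recorded as a positivity flag.
#'
#' @param params a [klepto_params] object.
#' @param init non-negative initial state `(S, P1, P2)`.
#' @param t_end time horizon (scaled time units).
#' @param n_out number of equally spaced output times.
#' @param rtol,atol integrator tolerances.
#' @param extinct_tol density below which a positive-started component is
#'   flagged as numerically extinct (`absorbed`); see Details.
#' @details Population trajectories of this model can pass exponentially
#' close to the coordinate planes (transients dip below `1e-30` at the
#' reference parameters), far beyond what double precision resolves.  The
#' integrator clamps the field evaluation at zero, so such a component is
#' *absorbed*: it behaves as extinct from then on, which is the ecological
#' reading of a density that small.  The `absorbed` flag records, per
#' component, whether this happened to a component that started positive;
#' attractors reached after absorption are attractors of the reduced
#' (boundary) dynamics.
#' @return a `klepto_trajectory`: list with `times`, `states`
#'   (`n_out` x 3 matrix), `params`, and `flags`
#'   (`positivity_violation`, `non_convergence`, `absorbed`).
#' @export
#' @examples
#' tr <- simulate_model(baseline_params(), c(0.8, 0.01, 0.2), t_end = 100)
#' tail(tr$states, 1)
simulate_model <- function(params, init, t_end = 1000, n_out = 2000,
                           rtol = 1e-9, atol = 1e-12,
                           extinct_tol = 1e-12) {
  check_state(init)
  zero <- init == 0
  times <- seq(0, t_end, length.out = n_out)
  fn <- function(t, y, parms) {
    y[zero] <- 0
    y <- pmax(y, 0)
    list(klepto_rhs(y, params))
  }
  sol <- try(suppressWarnings(
    deSolve::ode(y = stats::setNames(as.numeric(init), c("S", "P1", "P2")),
                 times = times, func = fn, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)),
    silent = TRUE)
  failed <- inherits(sol, "try-error")
  if (!failed) {
    states <- unname(as.matrix(sol[, 2:4]))
    keep <- stats::complete.cases(states)
    states <- states[keep, , drop = FALSE]
    completed <- nrow(states) == length(times)
  } else {
    states <- matrix(init, nrow = 1)
    completed <- FALSE
  }
  pos_flag <- min(states) < -1e-9
  absorbed <- !zero & apply(states <= extinct_tol, 2, any)
  states[, zero] <- 0
  states <- pmax(states, 0)
  structure(list(times = times[seq_len(nrow(states))],
                 states = states, params = params,
                 flags = list(positivity_violation = pos_flag,
                              non_convergence = !completed,
                              absorbed = stats::setNames(absorbed,
                                                         c("S", "P1", "P2")))),
            class = "klepto_trajectory")
}

#' @export
print.klepto_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples on [0, %g]; final state (%.5g, %.5g, %.5g)\n",
              nrow(x$states), max(x$times),
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2],
              x$states[nrow(x$states), 3]))
  if (x$flags$positivity_violation) cat("  ! positivity violation\n")
  if (x$flags$non_convergence) cat("  ! integration incomplete\n")
  invisible(x)
}

#' Classify the long-run attractor of a trajectory
#'
#' Discards the transient (first half by default) and inspects the tail:
#' a trajectory is at an `equilibrium` when the tail's maximum deviation
#' from its final state is below `eq_tol` over the last 10% of the
#' horizon; it is on a `limit_cycle` when the prey component shows at
#' least `min_peaks` inter-peak intervals over the final quarter with
#' period drift under 1%; otherwise `unresolved`.
#'
#' @param traj a `klepto_trajectory`.
#' @param eq_tol convergence tolerance for the equilibrium verdict.
#' @param min_peaks minimum number of prey-density peaks for the cycle
#'   verdict.
#' @return a list: `label` (`"equilibrium"`, `"limit_cycle"`,
#'   `"unresolved"`), `target` (equilibrium coordinates, when settled),
#'   `period` and `amplitude` (per component, for cycles), `diagnostics`.
#' @export
classify_attractor <- function(traj, eq_tol = 1e-6, min_peaks = 5) {
  st <- traj$states; tt <- traj$times
  n <- nrow(st)
  if (traj$flags$non_convergence || n < 20)
    return(list(label = "unresolved", diagnostics = list(reason = "integration incomplete")))
  tail10 <- st[tt >= 0.9 * max(tt), , drop = FALSE]
  dev <- max(abs(sweep(tail10, 2, st[n, ])))
  if (dev < eq_tol)
    return(list(label = "equilibrium",
                target = stats::setNames(st[n, ], c("S", "P1", "P2")),
                diagnostics = list(tail_deviation = dev)))
  sel <- tt >= 0.75 * max(tt)
  S <- st[sel, 1]; ts <- tt[sel]
  pk <- which(diff(sign(diff(S))) == -2) + 1L
  if (length(pk) >= min_peaks + 1) {
    gaps <- diff(ts[pk])
    k <- length(gaps)
    half1 <- mean(gaps[seq_len(floor(k / 2))])
    half2 <- mean(gaps[(floor(k / 2) + 1):k])
    drift <- abs(half1 - half2) / mean(gaps)
    if (drift < 0.01) {
      amp <- apply(st[sel, , drop = FALSE], 2, function(v) diff(range(v)))
      return(list(label = "limit_cycle", period = mean(gaps),
                  amplitude = stats::setNames(amp, c("S", "P1", "P2")),
                  diagnostics = list(n_peaks = length(pk),
                                     period_drift = drift)))
    }
  }
  list(label = "unresolved",
       diagnostics = list(tail_deviation = dev, n_peaks = length(pk)))
}

#' Probe basins of attraction
#'
#' Integrates the system from each initial condition and classifies the
#' attractor reached; reports bistability when at least two distinct
#' attractors are found.  Two equilibrium verdicts count as the same
#' attractor when their targets agree within `match_tol`.
#'
#' @param params a [klepto_params] object.
#' @param ics a list (or matrix, rows as states) of non-negative initial
#'   conditions.
#' @param t_end,n_out passed to [simulate_model()].
#' @param match_tol distance below which two equilibrium targets are the
#'   same attractor.
#' @return list with `verdicts` (one [classify_attractor()] result per
#'   initial condition), `n_attractors`, `bistable`.
#' @export
basin_probe <- function(params, ics, t_end = 2000, n_out = 4000,
                        match_tol = 1e-3) {
  if (is.matrix(ics)) ics <- asplit(ics, 1)
  verdicts <- lapply(ics, function(ic)
    classify_attractor(simulate_model(params, ic, t_end = t_end,
                                      n_out = n_out)))
  targets <- list()
  for (v in verdicts) {
    key <- if (v$label == "equilibrium") v$target else v$label
    dup <- FALSE
    for (tgt in targets) {
      if (is.character(key) && is.character(tgt) && key == tgt) dup <- TRUE
      if (is.numeric(key) && is.numeric(tgt) &&
          sqrt(sum((key - tgt)^2)) < match_tol) dup <- TRUE
    }
    if (!dup) targets[[length(targets) + 1]] <- key
  }
  list(verdicts = verdicts, n_attractors = length(targets),
       bistable = length(targets) >= 2)
}

#' Boundedness configuration
#'
#' The dissipativity argument uses the weighted total density
#' `D = S + P1/A9 + P2/A5` (with `A9 = A4/A1`) and a decay rate
#' `phi < min(A3, A7)`, yielding the asymptotic bound
#' `D(t) <= eta/phi` with `eta = (1 + phi)^2 / 4`.
#'
#' @param params a [klepto_params] object.
#' @param phi decay rate; default `0.9 * min(A3, A7)`.
#' @param margin slack `theta > 0` added to the bound.
#' @return list with `phi`, `eta`, `margin`, `bound = eta/phi + margin`.
#' @export
boundedness_config <- function(params, phi = NULL, margin = 1e-6) {
  p <- unclass(params)
  mx <- min(p[["A3"]], p[["A7"]])
  if (is.null(phi)) phi <- 0.9 * mx
  stopifnot(phi > 0, phi < mx, margin > 0)
  eta <- (1 + phi)^2 / 4
  list(phi = phi, eta = eta, margin = margin, bound = eta / phi + margin)
}

#' Empirical boundedness check along a trajectory
#'
#' Computes `D(t) = S + P1/A9 + P2/A5` along a trajectory and compares its
#' long-run supremum (after discarding the first half as transient) to the
#' dissipativity bound `eta/phi + margin`.  The bound's derivation assumes
#' the net predator-predator interaction loss `A10 = A6 - A8 >= 0`; when
#' `A10 < 0` (strong kleptoparasitic gain, as in the baseline parameter
#' set) the bound is not guaranteed and the report flags this.
#'
#' @param traj a `klepto_trajectory`.
#' @param params a [klepto_params] object.
#' @param cfg a [boundedness_config()].
#' @return list with `sup_D` (long-run supremum), `bound`, `held`,
#'   `assumption_met` (`A10 >= 0`).
#' @export
boundedness_check <- function(traj, params, cfg = boundedness_config(params)) {
  p <- unclass(params)
  A9 <- p[["A4"]] / p[["A1"]]
  D <- traj$states[, 1] + traj$states[, 2] / A9 + traj$states[, 3] / p[["A5"]]
  tail <- D[traj$times >= 0.5 * max(traj$times)]
  supD <- max(tail)
  list(sup_D = supD, bound = cfg$bound, held = supD <= cfg$bound,
       assumption_met = (p[["A6"]] - p[["A8"]]) >= 0)
}
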