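#' Baseline parameter set
#'
#' The reference nondimensional parameter set used throughout the
#' package's examples and tests: `A1 = 0.02`, `A2 = 0.05`, `A3 = 2`,
#' `A4 = 0.4`, `A5 = 4.536`, `A6 = 0.052`, `A7 = 4.546`, `A8 = 114.98`.
#' At these values the system has a single, locally stable coexistence
#' equilibrium near `(0.844, 0.0074, 0.148)`.
#'
#' @return a [klepto_params] object.
#' @export
baseline_params <- function() {
  klepto_params(A1 = 0.02, A2 = 0.05, A3 = 2, A4 = 0.4,
                A5 = 4.536, A6 = 0.052, A7 = 4.546, A8 = 114.98)
}

scenario_registry_list <- function() {
  list(
    `interior-stable` = list(
      overrides = c(),
      ics = list(c(0.8, 0.01, 0.2), c(0.9, 0.02, 0.1), c(0.7, 0.05, 0.25)),
      expected = "interior-stable"),
    `E1-stable` = list(
      overrides = c(A3 = 0.875, A4 = 0.0125, A5 = 4.536),
      ics = list(c(0.5, 0.5, 0.5), c(0.9, 0.2, 0.3), c(0.2, 0.8, 0.1)),
      expected = "E1-stable"),
    `E3-stable` = list(
      overrides = c(A3 = 2.723732, A4 = 0.516658, A5 = 9.3241),
      ics = list(c(0.5, 0.5, 0.5)),
      expected = "E3-stable"),
    `E2-stable` = list(
      overrides = c(A3 = 0.51558, A4 = 0.010528, A5 = 1.135458),
      ics = list(c(0.5, 0.5, 0.5)),
      expected = "E2-stable"),
    `subcritical-regime` = list(
      overrides = c(A4 = 1.2),
      ics = list(c(0.64, 0.025, 0.36), c(0.5, 0.5, 0.5)),
      expected = "interior-stable / unstable-cycle-basin-boundary"),
    `pre-supercritical` = list(
      overrides = c(A4 = 11),
      ics = list(c(0.11, 0.34, 0.57)),
      expected = "stable-limit-cycle"),
    `second-predator-extinct` = list(
      overrides = c(A4 = 3),
      ics = list(c(0.5, 0.5, 0.5)),
      expected = "E2-stable"),
    `first-predator-extinct` = list(
      overrides = c(A5 = 5.5),
      ics = list(c(0.5, 0.5, 0.5)),
      expected = "E3-stable"),
    `bistable-A8` = list(
      overrides = c(A8 = 20),
      ics = list(c(0.15, 0.85, 0.02), c(0.6, 0.2, 0.25)),
      expected = "bistable: E2 and interior"),
    `no-klepto` = list(
      overrides = c(A8 = 1e-12),
      ics = list(c(0.5, 0.5, 0.5)),
      expected = "E2-stable / second predator declines")
  )
}

#' Named study scenarios
#'
#' A registry of parameter scenarios covering the qualitatively distinct
#' regimes of the model: each of the four locally stable equilibrium
#' types, the sub- and supercritical oscillatory regimes in the host
#' growth rate `A4`, single-predator extinctions, kleptoparasitism-driven
#' bistability, and the no-kleptoparasitism limit (`A8 -> 0`; `A8` is set
#' to `1e-12` rather than exactly zero to stay within the validated
#' positive parameter domain -- dynamically indistinguishable from zero).
#' Expected-outcome tags are qualitative only.
#'
#' @param name a registry name; see [scenario_names()].
#' @return a `klepto_scenario`: list with `name`, `params`, `overrides`,
#'   `ics` (suggested initial conditions), `expected` (qualitative tag).
#' @export
#' @examples
#' scenario("E1-stable")$params
scenario <- function(name) {
  reg <- scenario_registry_list()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  sc <- reg[[name]]
  p <- if (length(sc$overrides) > 0)
    set_params(baseline_params(), sc$overrides) else baseline_params()
  structure(list(name = name, params = p, overrides = sc$overrides,
                 ics = sc$ics, expected = sc$expected),
            class = "klepto_scenario")
}

#' @rdname scenario
#' @export
scenario_names <- function() names(scenario_registry_list())

#' @export
print.klepto_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (expected: %s)\n", x$name, x$expected))
  if (length(x$overrides) > 0) {
    cat("  overrides:",
        paste(names(x$overrides), x$overrides, sep = " = ",
              collapse = ", "), "\n")
  } else cat("  baseline parameters\n")
  invisible(x)
}

#' Export / import the scenario registry as YAML
#'
#' @param path output (input) file path.
#' @return `write_scenarios()` returns the path invisibly;
#'   `read_scenarios()` the registry list.
#' @export
write_scenarios <- function(path) {
  reg <- scenario_registry_list()
  out <- lapply(reg, function(sc) list(
    overrides = as.list(sc$overrides),
    ics = lapply(sc$ics, as.list),
    expected = sc$expected))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) yaml::read_yaml(path)

#' Seeded random parameter / initial-condition ensembles
#'
#' Draws reproducible parameter sets and initial conditions uniformly
#' from positive boxes.  Default ranges span an order of magnitude around
#' the baseline values, which keeps most draws in the regime where the
#' model's scaling assumptions are sensible.
#'
#' @param n number of draws.
#' @param seed RNG seed (recorded in the output).
#' @param param_ranges named list of length-2 ranges for any of `A1..A8`;
#'   unlisted parameters use the defaults.
#' @param ic_box length-2 range for every state component.
#' @return list with `draws` (list of `list(params, ic)`), `seed`,
#'   `param_ranges`, `ic_box`.
#' @export
#' @examples
#' ens <- sample_ensemble(3, seed = 42)
#' ens$draws[[1]]$params
sample_ensemble <- function(n, seed = 1, param_ranges = list(),
                            ic_box = c(0.05, 1)) {
  defaults <- list(A1 = c(0.01, 0.1), A2 = c(0.01, 0.2),
                   A3 = c(0.2, 4), A4 = c(0.05, 5),
                   A5 = c(0.5, 10), A6 = c(0.01, 0.2),
                   A7 = c(0.5, 10), A8 = c(0.1, 150))
  bad <- setdiff(names(param_ranges), param_names())
  if (length(bad) > 0)
    stop("unknown parameter(s) in param_ranges: ",
         paste(bad, collapse = ", "))
  rng <- utils::modifyList(defaults, param_ranges)
  if (any(vapply(rng, function(r) r[1] <= 0 || r[2] <= r[1], TRUE)))
    stop("parameter ranges must be positive and increasing")
  set.seed(seed)
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- vapply(param_names(), function(nm)
      stats::runif(1, rng[[nm]][1], rng[[nm]][2]), 0)
    ic <- stats::runif(3, ic_box[1], ic_box[2])
    draws[[i]] <- list(params = as_klepto_params(vals),
                       ic = stats::setNames(ic, c("S", "P1", "P2")))
  }
  list(draws = draws, seed = seed, param_ranges = rng, ic_box = ic_box)
}
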