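#' Nondimensional model parameters
#'
#' Constructs and validates the eight dimensionless coefficients `A1..A8`
#' that drive the scaled two-predator-one-prey system (see
#' [klepto_rhs()]).  Two derived quantities are carried along: `A9 = A4/A1`
#' (the weight of the first predator in the boundedness function
#' `D = S + P1/A9 + P2/A5`) and `A10 = A6 - A8` (net loss rate of the
#' second predator in predator-predator encounters; it is negative whenever
#' the kleptoparasitic gain `A8` exceeds the competition loss `A6`).
#'
#' Interpretation of the coefficients:
#' * `A1` inverse kleptoparasitism intensity (scaled); the host's food share
#'   is `1/(A1 + P2)` up to the factor `A4`,
#' * `A2` interspecific competition loss of the first predator,
#' * `A3` first-predator death rate (scaled),
#' * `A4` first-predator growth (conversion) coefficient,
#' * `A5` second-predator growth from direct predation,
#' * `A6` interspecific competition loss of the second predator,
#' * `A7` second-predator death rate (scaled),
#' * `A8` second-predator growth from stolen food (kleptoparasitism).
#'
#' @param A1,A2,A3,A4,A5,A6,A7,A8 strictly positive numbers (`A8 >= 0` is
#'   accepted so the no-kleptoparasitism limit can be studied).
#' @return An object of class `klepto_params`: a named numeric vector
#'   `A1..A8` with attributes `A9` and `A10`.
#' @seealso [baseline_params()], [nondimensionalize()], [read_params()]
#' @export
#' @examples
#' p <- klepto_params(0.02, 0.05, 2, 0.4, 4.536, 0.052, 4.546, 114.98)
#' p
klepto_params <- function(A1, A2, A3, A4, A5, A6, A7, A8) {
  v <- c(A1 = A1, A2 = A2, A3 = A3, A4 = A4,
         A5 = A5, A6 = A6, A7 = A7, A8 = A8)
  validate_params(v)
}

#' @rdname klepto_params
#' @param x a named numeric vector or list with entries `A1..A8`.
#' @export
as_klepto_params <- function(x) {
  x <- unlist(x)
  miss <- setdiff(param_names(), names(x))
  if (length(miss) > 0)
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  validate_params(x[param_names()])
}

param_names <- function() paste0("A", 1:8)

validate_params <- function(v) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("parameters must be finite numbers")
  pos <- v[setdiff(param_names(), "A8")]
  if (any(pos <= 0))
    stop("parameters A1..A7 must be strictly positive")
  if (v[["A8"]] < 0)
    stop("A8 must be non-negative")
  structure(v, class = "klepto_params",
            A9 = v[["A4"]] / v[["A1"]], A10 = v[["A6"]] - v[["A8"]])
}

#' @export
print.klepto_params <- function(x, ...) {
  cat("Nondimensional kleptoparasitism-model parameters:\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  cat(sprintf("derived: A9 = A4/A1 = %g, A10 = A6 - A8 = %g\n",
              attr(x, "A9"), attr(x, "A10")))
  invisible(x)
}

#' Replace named entries of a parameter set
#'
#' @param params a `klepto_params` object.
#' @param ... named replacements among `A1..A8`, e.g. `A4 = 1.2`.
#' @return a validated `klepto_params` object.
#' @export
#' @examples
#' set_params(baseline_params(), A4 = 11)
set_params <- function(params, ...) {
  ov <- c(...)
  bad <- setdiff(names(ov), param_names())
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  v <- stats::setNames(as.numeric(params), names(unclass(params)))
  v[names(ov)] <- ov
  validate_params(v)
}

#' Dimensional (unscaled) model parameters
#'
#' The original model is written in terms of thirteen dimensional rates:
#' prey growth `r1` and carrying capacity `k`; predation rates `r2`, `r3`
#' and conversion efficiencies `r4`, `r5` of the two predators;
#' interspecific competition rates `k1`, `k2`; death rates `d2`, `d3`;
#' kleptoparasitism intensity `a`; and the proportionality constant
#' `r6_prime` of the size-dependent conversion `r7(p2) = r6_prime (1 + a p2)`
#' of stolen food (the counter-attack term).  The composite rate
#' `r6 = r6_prime * a * r2` multiplies the kleptoparasitic gain `r6 s p1 p2`.
#'
#' @param r1 prey intrinsic growth rate (1/time).
#' @param r2,r3 predation rates of the first and second predator
#'   (1/(density x time)).
#' @param r4,r5 conversion efficiencies (dimensionless).
#' @param r6_prime proportionality constant of the kleptoparasitic
#'   conversion rate.
#' @param a kleptoparasitism intensity (1/density).
#' @param k prey carrying capacity (density).
#' @param k1,k2 interspecific competition rates.
#' @param d2,d3 predator death rates (1/time).
#' @return An object of class `klepto_dparams` (named numeric vector).
#' @seealso [nondimensionalize()], [klepto_rhs_dimensional()]
#' @export
dimensional_params <- function(r1, r2, r3, r4, r5, r6_prime, a, k,
                               k1, k2, d2, d3) {
  v <- c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
         r6_prime = r6_prime, a = a, k = k, k1 = k1, k2 = k2,
         d2 = d2, d3 = d3)
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0))
    stop("all dimensional parameters must be strictly positive and finite")
  structure(v, class = "klepto_dparams")
}

#' @export
print.klepto_dparams <- function(x, ...) {
  cat("Dimensional kleptoparasitism-model parameters:\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Applies the scaling `s = S k`, `p1 = P1 r1/r2`, `p2 = P2 r1/r3`,
#' `T = r1 t`, which collapses the thirteen dimensional rates to the eight
#' coefficients of the scaled system:
#' `A1 = r3/(a r1)`, `A2 = k1/r3`, `A3 = d2/r1`,
#' `A4 = r2 r4 k r3 / (a r1^2)`, `A5 = r5 k r3 / r1`, `A6 = k2/r2`,
#' `A7 = d3/r1`, and `A8 = r6 k / r2` with `r6 = r6_prime a r2`.
#'
#' @param dp a `klepto_dparams` object.
#' @return a `klepto_params` object.
#' @export
#' @examples
#' dp <- dimensional_params(r1 = 0.25, r2 = 1, r3 = 1, r4 = 1, r5 = 1,
#'                          r6_prime = 1, a = 1, k = 1, k1 = 1, k2 = 1,
#'                          d2 = 0.5, d3 = 1)
#' nondimensionalize(dp)$A3 == 2  # d2/r1
nondimensionalize <- function(dp) {
  stopifnot(inherits(dp, "klepto_dparams"))
  d <- as.list(unclass(dp))
  r6 <- d$r6_prime * d$a * d$r2
  klepto_params(
    A1 = d$r3 / (d$a * d$r1),
    A2 = d$k1 / d$r3,
    A3 = d$d2 / d$r1,
    A4 = d$r2 * d$r4 * d$k * d$r3 / (d$a * d$r1^2),
    A5 = d$r5 * d$k * d$r3 / d$r1,
    A6 = d$k2 / d$r2,
    A7 = d$d3 / d$r1,
    A8 = r6 * d$k / d$r2
  )
}

#' @export
`$.klepto_params` <- function(x, name) {
  if (name %in% c("A9", "A10")) return(attr(x, name))
  unclass(x)[[name]]
}

#' Read / write parameter sets
#'
#' Parameter sets are stored as flat key-value mappings in YAML or JSON
#' (chosen by file extension).  Keys are either the nondimensional `A1..A8`
#' or the dimensional `r1..r6_prime, a, k, k1, k2, d2, d3`; strict
#' positivity is validated on load.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params()` returns a `klepto_params` or `klepto_dparams`
#'   object; `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter-file extension: ", ext))
  vals <- unlist(vals)
  if (all(param_names() %in% names(vals)))
    return(as_klepto_params(vals))
  dn <- c("r1", "r2", "r3", "r4", "r5", "r6_prime", "a", "k",
          "k1", "k2", "d2", "d3")
  if (all(dn %in% names(vals)))
    return(do.call(dimensional_params, as.list(vals[dn])))
  stop("file does not contain a complete A1..A8 or r1..d3 mapping")
}

#' @rdname read_params
#' @param params a `klepto_params` or `klepto_dparams` object.
#' @export
write_params <- function(params, path) {
  vals <- as.list(stats::setNames(as.numeric(params),
                                  names(unclass(params))))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter-file extension: ", ext))
  invisible(path)
}
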