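# shared fixtures and small oracles for the test suite

base_params <- function() baseline_params()

# reproducible positive random parameter draw (broad but plausible ranges)
random_params <- function() {
  as_klepto_params(c(
    A1 = runif(1, 0.01, 0.2), A2 = runif(1, 0.01, 0.2),
    A3 = runif(1, 0.2, 4),    A4 = runif(1, 0.05, 5),
    A5 = runif(1, 0.5, 10),   A6 = runif(1, 0.01, 0.2),
    A7 = runif(1, 0.5, 10),   A8 = runif(1, 0.1, 150)))
}

random_dimensional <- function() {
  dimensional_params(
    r1 = runif(1, 0.2, 2), r2 = runif(1, 0.2, 2), r3 = runif(1, 0.2, 2),
    r4 = runif(1, 0.1, 1), r5 = runif(1, 0.1, 1),
    r6_prime = runif(1, 0.1, 2), a = runif(1, 0.2, 3),
    k = runif(1, 0.5, 3), k1 = runif(1, 0.1, 1), k2 = runif(1, 0.1, 1),
    d2 = runif(1, 0.1, 1), d3 = runif(1, 0.1, 1))
}

random_state <- function(lo = 0.05, hi = 1.5) runif(3, lo, hi)

# central finite-difference Jacobian of the scaled vector field
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h * max(1, abs(state[j]))
    J[, j] <- (klepto_rhs(state + e, params) -
                 klepto_rhs(state - e, params)) / (2 * e[j])
  }
  J
}

# brute-force count of interior equilibria by dense sign scan of the
# reduced scalar nullcline equation
brute_force_interior_count <- function(params, n = 1e5) {
  S <- seq(1e-10, 1 - 1e-10, length.out = n)
  f <- kleptodyn:::interior_fS(S, params)
  p2 <- kleptodyn:::p2_of_s(S, params)
  p1 <- 1 - S - p2
  ok <- !is.na(f)
  sgn <- sign(f[ok])
  idx <- which(diff(sgn) != 0)
  # count only crossings that produce admissible states
  Sok <- S[ok]
  sum(vapply(idx, function(i) {
    s <- (Sok[i] + Sok[i + 1]) / 2
    q <- kleptodyn:::p2_of_s(s, params)
    !is.na(q) && q > 1e-6 && (1 - s - q) > 1e-6
  }, TRUE))
}

# map a dimensional state to scaled coordinates
to_scaled <- function(x, dp) {
  d <- unclass(dp)
  c(x[1] / d[["k"]], x[2] * d[["r2"]] / d[["r1"]], x[3] * d[["r3"]] / d[["r1"]])
}
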