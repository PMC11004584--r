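test_that("characteristic coefficients at the baseline coexistence state", {
  p <- base_params()
  eq <- interior_equilibria(p)[[1]]
  cc <- characteristic_coefficients(klepto_jacobian(eq$state, p))
  expect_equal(unname(cc), c(0.844371, 1.96046, 1.22722), tolerance = 1e-5)
  expect_equal(cc[["c1"]] * cc[["c2"]] - cc[["c3"]], 0.428135,
               tolerance = 1e-5)
  expect_equal(unname(characteristic_coefficients(matrix(0, 3, 3))),
               c(0, 0, 0))
})

test_that("characteristic polynomial roots equal the eigenvalues", {
  set.seed(31)
  for (i in 1:100) {
    J <- matrix(rnorm(9), 3, 3)
    cc <- characteristic_coefficients(J)
    roots <- polyroot(c(cc[3], cc[2], cc[1], 1))
    ev <- eigen(J, only.values = TRUE)$values
    # match as multisets
    d <- vapply(roots, function(r) min(Mod(r - ev)), 0)
    expect_lt(max(d), 1e-8)
  }
})

test_that("Routh-Hurwitz verdict agrees with eigenvalue classification", {
  expect_equal(routh_hurwitz(0.844371, 1.96046, 1.22722)$classification,
               "stable")
  expect_equal(routh_hurwitz(0.844371, 1.96046, 1.22722)$c1c2_minus_c3,
               0.428135, tolerance = 1e-5)
  expect_equal(routh_hurwitz(1, 1, 2)$classification, "unstable")
  set.seed(32)
  n_informative <- 0
  for (i in 1:1000) {
    p <- random_params()
    J <- klepto_jacobian(random_state(), p)
    cc <- characteristic_coefficients(J)
    rh <- routh_hurwitz(cc[1], cc[2], cc[3])
    re <- Re(eigen(J, only.values = TRUE)$values)
    if (max(abs(re)) < 1e-8 || min(abs(re)) < 1e-8) next   # marginal
    n_informative <- n_informative + 1
    expect_equal(rh$classification,
                 if (all(re < 0)) "stable" else "unstable")
  }
  expect_gt(n_informative, 900)
})

test_that("the trace identity c1 = S* holds at coexistence states", {
  # on the nullclines z22 = z33 = 0 and z11 = -S*, so the negative trace
  # equals the prey density exactly
  set.seed(33)
  for (i in 1:200) {
    p <- random_params()
    for (e in interior_equilibria(p)) {
      cc <- characteristic_coefficients(klepto_jacobian(e$state, p))
      expect_equal(cc[["c1"]], e$state[["S"]], tolerance = 1e-9)
    }
  }
})

test_that("parametric conditions reproduce the reference stable scenarios", {
  # predator-free scenario
  p1 <- set_params(base_params(), A3 = 0.875, A4 = 0.0125, A5 = 4.536)
  r1 <- stability_conditions(p1)$E1
  expect_true(all(r1$conditions))
  expect_equal(unname(r1$values["A1A3"]), 0.0175)
  expect_equal(r1$stability$classification, "stable")
  # host-free scenario
  p3 <- set_params(base_params(), A3 = 2.723732, A4 = 0.516658,
                   A5 = 9.3241)
  r3 <- stability_conditions(p3)$E3
  expect_true(all(r3$conditions))
  # the threshold expression, recomputed by direct arithmetic
  thr <- (0.05 * 9.3241^2 - 2 * 0.05 * 9.3241 * 4.546 + 0.05 * 4.546^2 +
            2.723732 * 9.3241^2 - 2.723732 * 9.3241 * 4.546) /
    (9.3241 * 4.546)
  expect_equal(unname(r3$values["A4_threshold"]), thr)
  expect_gt(thr, 0.516658)
  expect_equal(r3$stability$classification, "stable")
  # kleptoparasite-free scenario
  p2 <- set_params(base_params(), A3 = 0.51558, A4 = 0.010528,
                   A5 = 1.135458)
  r2 <- stability_conditions(p2)$E2
  expect_true(all(r2$conditions))
  expect_equal(unname(r2$values["A1A3"]), 0.0103116)
  # closed-form oracle for the kleptoparasitic-gain ceiling
  A1 <- 0.02; A3 <- 0.51558; A4 <- 0.010528; A5 <- 1.135458
  A6 <- 0.052; A7 <- 4.546
  thr8 <- (A1 * A3 * A4 * A5 + A1 * A3 * A4 * A6 - A4^2 * A6 - A4^2 * A7) /
    (A1^2 * A3^2 - A1 * A3 * A4)
  expect_equal(unname(r2$values["A8_threshold"]), thr8)
  expect_equal(unname(r2$values["A8_threshold"]), 170.022, tolerance = 5e-3)
  expect_equal(r2$stability$classification, "stable")
})

test_that("parametric verdicts match eigenvalues on random draws", {
  set.seed(34)
  for (i in 1:300) {
    p <- random_params()
    rep <- stability_conditions(p)
    # E1: conditions are exact iff (eigenvalues -1, (A4-A1A3)/A1, A5-A7)
    ev_stable <- rep$E1$stability$classification
    if (ev_stable != "marginal")
      expect_equal(all(rep$E1$conditions), ev_stable == "stable")
    # E2/E3: the closed-form conditions are sufficient
    for (lb in c("E2", "E3")) {
      r <- rep[[lb]]
      if (r$applicable && all(r$conditions) &&
          r$stability$classification != "marginal")
        expect_equal(r$stability$classification, "stable")
    }
  }
})

test_that("axial global-stability certificate can be found and verified", {
  p <- set_params(base_params(), A3 = 0.875, A4 = 0.0125, A5 = 4.536)
  cfg <- search_axial_certificate(p)
  expect_false(is.null(cfg))
  expect_true(global_stability_axial(p, cfg)$satisfied)
  samp <- lyapunov_derivative_sample(p, cfg, target = "axial",
                                     n = 10000, seed = 7)
  expect_true(samp$all_negative)
  # degenerate limit: the second inequality must fail as A3 -> 0
  p0 <- set_params(p, A3 = 1e-9)
  expect_false(global_stability_axial(p0, cfg)$ineq2)
})

test_that("interior certificate reports the full condition structure", {
  p <- base_params()
  eq <- interior_equilibria(p)[[1]]
  cfg <- global_stability_config(L = c(1, 1, 1),
                                 lower = eq$state * 0.5,
                                 upper = eq$state * 1.5)
  r <- global_stability_interior(p, eq, cfg)
  expect_named(r$thresholds, c("Y2", "Y3", "Y4"))
  expect_length(r$conditions, 5)
  expect_true(all(is.finite(r$margins)))
  # a box whose kleptoparasite ceiling excludes P2* violates the first
  # condition
  cfg2 <- global_stability_config(L = c(1, 1, 1),
                                  lower = eq$state * 0.1,
                                  upper = c(1, 1, eq$state[[3]] * 0.9))
  expect_false(global_stability_interior(p, eq, cfg2)$conditions[[1]])
})
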