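# one-parameter events at the reference parameter set; the located values
# are compared with an independent dense re-scan where cheap, and with
# closed-form values where those exist

test_that("folds of the coexistence family are located", {
  p <- base_params()
  br3 <- continue_branch(p, "A3", c(0.02, 0.1), n = 60)
  f3 <- detect_fold(br3)
  expect_length(f3, 1)
  expect_equal(f3[[1]]$value, 0.04267, tolerance = 1e-3)
  expect_lt(abs(f3[[1]]$det_jacobian), 1e-5)
  br4 <- continue_branch(p, "A4", c(11.5, 12.5), n = 50)
  f4 <- detect_fold(br4)
  expect_equal(f4[[1]]$value, 12.248, tolerance = 1e-3)
  br8 <- continue_branch(p, "A8", c(5, 15), n = 50)
  f8 <- detect_fold(br8)
  expect_equal(f8[[1]]$value, 10.2, tolerance = 1e-3)
  # independent coarse oracle: admissible-root count flips across the fold
  expect_length(interior_equilibria(set_params(p, A8 = f8[[1]]$value - 1e-3)), 0)
  expect_length(interior_equilibria(set_params(p, A8 = f8[[1]]$value + 1e-3)), 2)
})

test_that("Hopf points satisfy the Liu conditions at the known values", {
  p <- base_params()
  br <- continue_branch(p, "A4", c(0.5, 13), n = 260)
  hp <- detect_hopf(br)
  vals <- sort(vapply(hp, function(h) h$value, 0))
  expect_length(vals, 2)
  expect_equal(vals[1], 1.2252, tolerance = 1e-3)
  expect_equal(vals[2], 12.071019, tolerance = 1e-3)
  for (h in hp) {
    ev <- h$eigenvalues
    # spectrum is {-c1, +i omega, -i omega}
    expect_lt(min(abs(Re(ev[Im(ev) != 0]))), 1e-7)
    expect_equal(sort(abs(Im(ev)))[3], h$omega, tolerance = 1e-6)
    expect_false(h$degenerate)
  }
  br5 <- continue_branch(p, "A5", c(1.8, 2.2), n = 40)
  h5 <- detect_hopf(br5)
  expect_length(h5, 1)
  expect_equal(h5[[1]]$value, 2.007197, tolerance = 1e-3)
})

test_that("transversality sign predicts the observed eigenvalue crossing", {
  p <- base_params()
  cases <- list(list(param = "A4", range = c(1.1, 1.4), Sref = 0.62),
                list(param = "A4", range = c(11.9, 12.2), Sref = 0.086),
                list(param = "A5", range = c(1.8, 2.2), Sref = 0.85))
  for (cs in cases) {
    br <- continue_branch(p, cs$param, cs$range, n = 30)
    h <- detect_hopf(br)[[1]]
    tv <- h$transversality
    # direct differencing of the critical pair's real part
    re_at <- function(v) {
      q <- set_params(p, stats::setNames(v, cs$param))
      e <- kleptodyn:::family_member(q, cs$Sref)
      ev <- eigen(klepto_jacobian(e$state, q), only.values = TRUE)$values
      max(Re(ev[Im(ev) != 0]))
    }
    d <- 1e-3 * max(1, abs(h$value))
    slope <- (re_at(h$value + d) - re_at(h$value - d)) / (2 * d)
    expect_equal(sign(slope), sign(tv$d_re_lambda))
    expect_gt(abs(tv$numerator), 1e-3)
  }
})

test_that("no Hopf bifurcation occurs on the single-predator families", {
  p <- base_params()
  # scan wide ranges in several parameters; on the E2/E3 families the Liu
  # function must never vanish with positive characteristic coefficients
  scans <- list(c("A4", 0.05, 13), c("A5", 0.6, 10), c("A7", 0.5, 10),
                c("A8", 0.5, 150), c("A3", 0.1, 4))
  for (sc in scans) {
    br <- continue_branch(p, sc[1], as.numeric(sc[2:3]), n = 120)
    sm <- br$samples[br$samples$family %in% c("E2", "E3") & br$samples$exists, ]
    for (fam in unique(sm$family)) {
      fs <- sm[sm$family == fam, ]
      fs <- fs[order(fs$value), ]
      if (nrow(fs) < 2) next
      liu_zero <- diff(sign(fs$V)) != 0 &
        pmin(fs$c1[-nrow(fs)], fs$c1[-1]) > 0 &
        pmin(fs$c2[-nrow(fs)], fs$c2[-1]) > 0 &
        pmin(fs$c3[-nrow(fs)], fs$c3[-1]) > 0
      expect_false(any(liu_zero))
    }
  }
})

test_that("transcritical crossings are located with stability exchange", {
  p <- base_params()
  br5 <- continue_branch(p, "A5", c(4.2, 6), n = 60)
  tc <- detect_transcritical(br5)
  vals <- vapply(tc, function(e) e$value, 0)
  labs <- vapply(tc, function(e) e$boundary, "")
  # E1 loses transverse stability exactly at A5 = A7
  expect_true(any(labs == "E1" & abs(vals - 4.546) < 1e-9))
  # the coexistence family meets the host-free family
  i3 <- which(labs == "E3")
  expect_equal(vals[i3], 5.3449, tolerance = 1e-3)
  expect_equal(tc[[i3]]$vanishing, "P1")
  expect_setequal(unname(tc[[i3]]$exchange), c("unstable", "stable"))
  br7 <- continue_branch(p, "A7", c(3.5, 4.2), n = 40)
  tc7 <- detect_transcritical(br7)
  expect_equal(tc7[[1]]$value, 3.857, tolerance = 1e-3)
  # kleptoparasitic-gain crossing on the E2 family (the closed-form threshold
  # expression evaluates to 45.9911 at the reference values)
  br8 <- continue_branch(p, "A8", c(40, 50), n = 40)
  tc8 <- detect_transcritical(br8)
  expect_equal(tc8[[1]]$value, 45.9911, tolerance = 1e-3)
  expect_equal(tc8[[1]]$boundary, "E2")
})

test_that("Sotomayor quantities at the predator-free crossing", {
  p <- set_params(base_params(), A5 = 4.546)   # A5 = A7
  e1 <- boundary_equilibria(p)$E1
  sq <- sotomayor_quantities(e1, p, "A5", P = c(-1, 0, 1), Q = c(0, 0, 1))
  expect_equal(sq$q_Fmu, 0)
  expect_equal(sq$q_DFmu_P, 1)
  expect_equal(sq$q_D2F_PP, -2 * 4.546)  # full contraction; -A5 under the
                                         # symmetric 1/2 convention
  expect_true(sq$transcritical)
  # linearity: scaling P scales the quantities accordingly
  sq2 <- sotomayor_quantities(e1, p, "A5", P = c(-2, 0, 2), Q = c(0, 0, 1))
  expect_equal(sq2$q_Fmu, 0)
  expect_equal(sq2$q_DFmu_P, 2 * sq$q_DFmu_P)
  expect_equal(sq2$q_D2F_PP, 4 * sq$q_D2F_PP)
  # automatic null vectors give the same verdict
  sq3 <- sotomayor_quantities(e1, p, "A5")
  expect_true(sq3$transcritical)
  # error when the zero eigenvalue is absent
  expect_error(sotomayor_quantities(boundary_equilibria(base_params())$E1,
                                    base_params(), "A5"), "simple zero")
})

test_that("the kleptoparasite-free family crossing fits the Sotomayor pattern", {
  # locate the zero of the E2 transverse eigenvalue in A8 and verify the
  # transcritical pattern there
  p <- base_params()
  f <- function(a8) {
    q <- set_params(p, A8 = a8)
    e <- boundary_equilibria(q)$E2
    det(klepto_jacobian(e$state, q))
  }
  a8s <- uniroot(f, c(40, 50), tol = 1e-12)$root
  q <- set_params(p, A8 = a8s)
  sq <- sotomayor_quantities(boundary_equilibria(q)$E2, q, "A8")
  expect_lt(abs(sq$q_Fmu), 1e-9)
  expect_gt(abs(sq$q_DFmu_P), 1e-9)
  expect_gt(abs(sq$q_D2F_PP), 1e-9)
  # the crossing sits on the closed-form transcritical surface
  u <- unclass(q)
  surf <- u[["A1"]] * u[["A3"]] * u[["A4"]] *
    (u[["A5"]] + u[["A6"]] + u[["A8"]]) -
    u[["A4"]]^2 * (u[["A6"]] + u[["A7"]]) -
    u[["A1"]]^2 * u[["A3"]]^2 * u[["A8"]]
  expect_lt(abs(surf), 1e-8)
})

test_that("branch samples are genuine equilibria and export cleanly", {
  p <- base_params()
  br <- continue_branch(p, "A4", c(0.2, 2), n = 40)
  expect_true(all(br$samples$residual < 1e-9))
  # single-point branch: no events
  br0 <- continue_branch(p, "A4", c(0.4, 0.4), n = 2)
  expect_length(detect_fold(br0), 0)
  expect_length(detect_hopf(br0), 0)
  csv <- tempfile(fileext = ".csv")
  write_branch_csv(br, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(br$samples))
  js <- tempfile(fileext = ".json")
  write_events_json(detect_hopf(br), js)
  expect_true(jsonlite::validate(readChar(js, file.size(js))))
})

test_that("a short Hopf-curve segment tracks the locus and its l1", {
  p <- base_params()
  cv <- hopf_curve(p, "A5", "A1", c(2.0, 1.8), start2 = 0.0217,
                   Sref = 0.83, n = 6)
  expect_gte(nrow(cv), 6)
  expect_true(all(is.finite(cv$l1)))
  # every curve point satisfies the Liu condition
  for (i in seq_len(nrow(cv))) {
    q <- set_params(p, A5 = cv$par1[i], A1 = cv$par2[i])
    e <- kleptodyn:::family_member(q, cv$S[i])
    cc <- characteristic_coefficients(klepto_jacobian(e$state, q))
    expect_lt(abs(cc[1] * cc[2] - cc[3]), 1e-8)
    expect_gt(cc[1], 0); expect_gt(cc[2], 0)
  }
})
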