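test_that("ventilation rate matches hand evaluation and degenerate cases", {
  expect_equal(ventilation_rate(0.01, 0.005, Ti = 20, To = 0, u = 2, N = 1),
               0.01 * 20 + 0.005 * 4)
  # both driving terms vanish
  expect_equal(ventilation_rate(0.3, 0.9, Ti = 15, To = 15, u = 0, N = 5), 0)
  # works from a bundled input object too
  v <- ventilation_inputs(ft = 0.01, fw = 0.005, Ti = 20, To = 0, u = 2)
  expect_equal(ventilation_rate(v), 0.22)
})

test_that("ventilation rate is homogeneous in N and symmetric in Ti/To", {
  set.seed(42)
  for (i in 1:25) {
    ft <- runif(1, 0, 0.1); fw <- runif(1, 0, 0.02)
    Ti <- runif(1, -5, 30); To <- runif(1, -15, 35)
    u <- runif(1, 0, 8); N <- runif(1, 0, 3)
    base <- ventilation_rate(ft, fw, Ti, To, u, N)
    expect_equal(ventilation_rate(ft, fw, Ti, To, u, 2 * N), 2 * base)
    expect_equal(ventilation_rate(ft, fw, To, Ti, u, N), base)
    expect_gte(base, 0)
  }
})

test_that("ventilation rate rejects negative parameters", {
  expect_error(ventilation_rate(-0.01, 0.005, 20, 0, 2), "ft")
  expect_error(ventilation_rate(0.01, 0.005, 20, 0, u = -1), "u")
  expect_error(ventilation_rate(0.01, 0.005, 20, 0, 2, N = -2), "N")
})

test_that("steady-state concentration matches the closed form", {
  expect_equal(steady_state_ci(S = 10, Cs = 100, Cbm = 0, Co = 10,
                               lam = 7.56e-3, lam_v = 0.34),
               (10 + 0.34 * 10 - 7.56e-3 * 100) / (7.56e-3 + 0.34))
  expect_equal(steady_state_ci(S = 0, Cs = 0, Cbm = 0, Co = 0,
                               lam = 7.56e-3, lam_v = 0.3), 0)
  # ventilation-dominated limit approaches the outdoor concentration
  expect_equal(steady_state_ci(S = 10, Cs = 100, Co = 12, lam = 7.56e-3,
                               lam_v = 1e9), 12, tolerance = 1e-6)
  expect_error(steady_state_ci(S = 1, lam = 0, lam_v = 0.3), "lam")
})

test_that("steady state is monotone in S and Co, decreasing in lam_v above Co", {
  set.seed(7)
  for (i in 1:25) {
    S <- runif(1, 1, 50); Cs <- runif(1, 0, 300); Co <- runif(1, 0, 20)
    lam_v <- runif(1, 0.05, 1); h <- 1e-6
    ci <- steady_state_ci(S, Cs, 0, Co, lam_v = lam_v)
    expect_gt(steady_state_ci(S + 1, Cs, 0, Co, lam_v = lam_v), ci)
    expect_gt(steady_state_ci(S, Cs, 0, Co + 1, lam_v = lam_v), ci)
    if (ci > Co)
      expect_lt(steady_state_ci(S, Cs, 0, Co, lam_v = lam_v + 0.1), ci)
  }
})

test_that("inconsistent inputs give the algebraic value with a warning", {
  expect_warning(ci <- steady_state_ci(S = 0, Cs = 1000, Cbm = 0, Co = 0,
                                       lam_v = 0.3), "negative")
  expect_lt(ci, 0)
})

test_that("infiltration inversion is the exact inverse of the steady state", {
  # round-trip of the worked example
  ci <- steady_state_ci(S = 10, Cs = 100, Cbm = 0, Co = 10,
                        lam = 7.56e-3, lam_v = 0.34)
  expect_equal(infiltration_from_measurement(ci, 100, 0, 10,
                                             7.56e-3, 0.34), 10)
  expect_equal(infiltration_from_measurement(0, 0, 0, 0, lam_v = 0.2), 0)
  # property: identity in S over random valid draws
  set.seed(123)
  n <- 500
  S <- runif(n, 0, 100); Cs <- runif(n, 0, 500); Cbm <- runif(n, 0, 50)
  Co <- runif(n, 0, 30); lam_v <- runif(n, 0.01, 2)
  ci <- suppressWarnings(steady_state_ci(S, Cs, Cbm, Co, lam_v = lam_v))
  S_back <- infiltration_from_measurement(ci, Cs, Cbm, Co, lam_v = lam_v)
  expect_equal(S_back, S, tolerance = 1e-12)
})

test_that("dynamic model has the zero fixed point and converges to the linear solve", {
  p0 <- mass_balance_params(Es = 0, Ebm = 0, kd_s = 0.1, kd_bm = 0.05,
                            ka = 0.01, dP_si = 2, Sg = 80, Sbm = 200,
                            V = 240, Co = 0)
  traj <- simulate_dynamics(p0, v = 0.3, t_end = 100)
  expect_true(all(abs(as.matrix(traj[, c("Ci", "Cs", "Cbm")])) < 1e-10))

  set.seed(99)
  for (i in 1:5) {
    p <- random_mb_params()
    lam_v <- runif(1, 0.1, 0.8)
    fp <- steady_state_solution(p, lam_v)
    traj <- simulate_dynamics(p, lam_v, t_end = 1e4,
                              times = c(0, 1e4))
    end <- unlist(traj[nrow(traj), c("Ci", "Cs", "Cbm")])
    expect_equal(unname(end), unname(fp), tolerance = 1e-6)
    # converged indoor level equals the closed form driven by S = Es*Sg/V + Ebm*Sbm/V
    S <- p$Es * p$Sg / p$V + p$Ebm * p$Sbm / p$V
    expect_equal(fp[["Ci"]],
                 steady_state_ci(S, Cs = fp[["Cs"]], Cbm = fp[["Cbm"]],
                                 Co = p$Co, lam = p$lam, lam_v = lam_v),
                 tolerance = 1e-10)
  }
})

test_that("annual effective dose is the plain four-factor product", {
  expect_equal(annual_effective_dose(50, 0.4, 7000, 9e-9), 50 * 0.4 * 7000 * 9e-9)
  expect_equal(annual_effective_dose(0, 0.4, 7000, 9e-9), 0)
  expect_equal(annual_effective_dose(1, 1, 1, 1), 1)
  expect_error(annual_effective_dose(-1, 0.4, 7000, 9e-9), "Q")
})
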