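test_that("logistic solution matches the closed form, lag and asymptote", {
  p <- logistic_params(r = 1.85, K = 0.61, S0 = 0.005)
  # frozen value computed from the independent closed form
  expect_equal(oracle_logistic(1.85, 0.61, 0.005, 2), 0.1528230,
               tolerance = 1e-6)
  expect_equal(logistic_solution(p, 2), 0.1528230, tolerance = 1e-6)
  expect_equal(logistic_solution(p, seq(0, 10, by = 0.3)),
               oracle_logistic(1.85, 0.61, 0.005, seq(0, 10, by = 0.3)),
               tolerance = 1e-12)
  # initial condition, also under a lag
  lagged <- logistic_params(1.85, 0.61, 0.005, T_L = 2.35)
  expect_identical(logistic_solution(lagged, 2.35), 0.005)
  expect_identical(logistic_solution(lagged, 1.0), 0.005)
  # asymptote: r (t - T_L) >= 30 puts the density at K
  expect_equal(logistic_solution(p, 30 / 1.85), 0.61, tolerance = 1e-10)
  expect_error(logistic_solution(p, -1), "t")
})

test_that("logistic_params enforces its invariants", {
  expect_error(logistic_params(-0.1, 0.5, 0.005), "r")
  expect_error(logistic_params(1, 0, 0.005), "K")
  expect_error(logistic_params(1, 0.5, 0.6), "S0")
  expect_error(logistic_params(1, 0.5, 0.005, -1), "T_L")
})

test_that("interaction coefficients reproduce the published pair values", {
  expect_equal(round(interaction_coefficient(0.17, 0.61, 0.35), 2), -1.26)
  expect_equal(round(interaction_coefficient(0.03, 0.35, 0.61), 2), -0.52)
  expect_identical(interaction_coefficient(0.61, 0.61, 0.35), 0)
  expect_error(interaction_coefficient(0.17, 0.61, 0), "K_j")
})

test_that("LV rate coefficient a_ij = c_ij r_i / K_i", {
  expect_identical(lv_interaction_strength(0, 1.85, 0.61), 0)
  expect_equal(lv_interaction_strength(-1.26, 1.85, 0.61), -3.8213,
               tolerance = 1e-4)
  # sign is inherited from c for any positive kinetics
  set.seed(11)
  c_ij <- runif(50, -2, 2)
  a <- lv_interaction_strength(c_ij, runif(50, 0.1, 3), runif(50, 0.05, 1))
  expect_identical(sign(a), sign(c_ij))
  expect_error(lv_interaction_strength(-1, 1.85, 0), "K_i")
})

test_that("CFSM parameter prediction obeys the r/K ratio identity", {
  p1 <- logistic_params(1.85, 0.61, 0.005)
  rec <- predict_cfsm_params(p1, c_ij = -1.26, K_j = 0.35)
  expect_equal(rec$K, 0.169, tolerance = 1e-12)
  expect_equal(rec$r, 0.5125, tolerance = 1e-3)
  expect_false(rec$suppressed)
  # no modulation leaves the baseline untouched
  null <- predict_cfsm_params(p1, 0, 0.35)
  expect_identical(c(null$r, null$K), c(p1$r, p1$K))
  # strong inhibition is flagged, not an error
  sup <- predict_cfsm_params(p1, -2, 0.35)
  expect_true(sup$suppressed)
  expect_identical(sup$K, 0)
  # round trip: capacity back to coefficient
  expect_equal(interaction_coefficient(rec$K, 0.61, 0.35), -1.26,
               tolerance = 1e-12)
})

test_that("the r/K identity and coefficient round trip hold across parameter space", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:300) {
    r_i <- runif(1, 0.1, 3); K_i <- runif(1, 0.05, 1)
    K_j <- runif(1, 0.05, 1); c_ij <- runif(1, -2, 2)
    p <- logistic_params(r_i, K_i, K_i / 100)
    rec <- predict_cfsm_params(p, c_ij, K_j)
    if (rec$suppressed) next
    n_checked <- n_checked + 1
    expect_equal(rec$r / rec$K, r_i / K_i, tolerance = 1e-12)
    expect_equal(interaction_coefficient(rec$K, K_i, K_j), c_ij,
                 tolerance = 1e-12)
  }
  expect_gt(n_checked, 150)
})

test_that("decoupled LV dynamics reduce to the logistic solution", {
  p1 <- logistic_params(1.85, 0.61, 0.005, 2.35)
  p2 <- logistic_params(1.56, 0.35, 0.005, 2.25)
  sys <- lv_system(list(a = p1, b = p2), matrix(0, 2, 2))
  times <- seq(0, 48, by = 1/6)
  traj <- simulate_lv(sys, times = times)
  for (k in 1:2) {
    truth <- logistic_solution(list(p1, p2)[[k]], times)
    expect_lt(max(abs(traj[[k + 1]] - truth) / pmax(truth, 1e-12)), 1e-6)
  }
})

test_that("identical isolates with symmetric interactions stay identical", {
  p <- logistic_params(1.5, 0.5, 0.005, 2)
  sys <- lv_system(list(a = p, b = p), matrix(c(0, -0.6, -0.6, 0), 2))
  traj <- simulate_lv(sys, times = seq(0, 24, by = 0.25))
  expect_equal(traj[[2]], traj[[3]], tolerance = 1e-9)
})

test_that("the published pair ends with S. aureus dominant at 24 h", {
  traj <- simulate_lv(staph_pair_system(), times = seq(0, 24, by = 1/6))
  final <- traj[nrow(traj), ]
  expect_gt(final$S_aureus, final$Staph_KPL1850)
  expect_true(all(as.matrix(traj[, -1]) >= 0))
  expect_true(all(is.finite(as.matrix(traj[, -1]))))
})

test_that("adaptive solver agrees with an independent fixed-step integrator", {
  sys <- staph_pair_system()
  traj <- simulate_lv(sys, times = c(0, 12, 24))
  ref <- oracle_rk4_lv(r = c(table2$r1, table2$r2),
                       K = c(table2$K1, table2$K2),
                       lag = c(table2$T1L, table2$T2L),
                       cmat = coef(sys), init = c(0.005, 0.005), t_end = 24)
  expect_equal(as.numeric(traj[3, -1]), ref, tolerance = 1e-3)
})

test_that("all-inhibitory cocultures stay below their monoculture envelopes", {
  p1 <- logistic_params(1.85, 0.61, 0.005, 2.35)
  p2 <- logistic_params(1.56, 0.35, 0.005, 2.25)
  sys <- lv_system(list(a = p1, b = p2),
                   matrix(c(0, -1.26, -0.52, 0), 2, byrow = TRUE))
  times <- seq(0, 36, by = 0.25)
  traj <- simulate_lv(sys, times = times)
  expect_true(all(traj[[2]] <= logistic_solution(p1, times) + 1e-8))
  expect_true(all(traj[[3]] <= logistic_solution(p2, times) + 1e-8))
})

test_that("simulate() on an lv_system is seed-deterministic under noise", {
  sys <- staph_pair_system()
  a <- simulate(sys, seed = 9, noise = noise_model())
  b <- simulate(sys, seed = 9, noise = noise_model())
  expect_identical(a, b)
})
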