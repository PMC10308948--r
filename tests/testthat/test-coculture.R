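test_that("deconvolution clamps and flags impossible readings", {
  t <- seq(0, 2, by = 0.5)
  total <- rep(0.05, 5)
  # middle reading converts above the total
  F <- as.numeric(invert_gfp_calibration(c(0.02, 0.02, 0.08, 0.02, 0.02)))
  tr <- deconvolve_coculture(coculture_trace(t, total, F))
  expect_true(tr$flags$clamped[3])
  expect_identical(tr$od2[3], 0)
  expect_identical(tr$od1[3], 0.05)
  expect_equal(tr$flags$fraction_flagged, 0.2)
  # absent reporter: the partner carries the whole total
  F0 <- rep(as.numeric(invert_gfp_calibration(0, extrapolate = TRUE)), 5)
  tr0 <- deconvolve_coculture(coculture_trace(t, total, F0))
  expect_equal(tr0$od1, rep(0, 5), tolerance = 1e-12)
  expect_equal(tr0$od2, total)
})

test_that("initial densities are read off the pre-lag plateau", {
  sys <- staph_pair_system("1:10")
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  init <- estimate_initial_densities(tr, sys)
  expect_equal(init, c(0.0005, 0.005), tolerance = 1e-6)
})

test_that("the empirical interaction trace recovers the generating c", {
  sys <- staph_pair_system()
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  truth <- c(coef(sys)[1, 2], coef(sys)[2, 1])
  for (f in 1:2) {
    it <- empirical_interaction_trace(tr, sys$isolates[[f]],
                                      sys$isolates[[3 - f]], focal = f)
    est <- it$c_hat[it$valid]
    expect_equal(median(est), truth[f], tolerance = 0.05 * abs(truth[f]))
    # constancy: the LV inversion of LV data is flat over the window
    expect_lt(sd(est), 0.05 * abs(truth[f]))
  }
})

test_that("a non-interacting coculture yields an empirical c near zero", {
  p1 <- logistic_params(1.85, 0.61, 0.005, 2.35)
  p2 <- logistic_params(1.56, 0.35, 0.005, 2.25)
  sys <- lv_system(list(a = p1, b = p2), matrix(0, 2, 2))
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  it <- empirical_interaction_trace(tr, p1, p2, focal = 1)
  expect_lt(max(abs(it$c_hat[it$valid])), 0.05)
})

test_that("an everywhere-sparse partner is an estimation error", {
  sys <- staph_pair_system()
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  expect_error(
    empirical_interaction_trace(tr, sys$isolates[[1]], sys$isolates[[2]],
                                focal = 1, partner_floor = 10),
    "valid points")
})

test_that("LV coefficients are recovered from noise-free cocultures", {
  sys <- staph_pair_system()
  traces <- lapply(c("1:1", "1:10"), function(rt)
    deconvolve_coculture(simulate_coculture_trace(
      staph_pair_system(rt), noise = noise_free, ratio = rt)))
  fit <- fit_lv_to_coculture(traces, baselines = sys$isolates,
                             start = c(-1, -0.4))
  truth <- c(coef(sys)[1, 2], coef(sys)[2, 1])
  expect_equal(unname(coef(fit)), truth, tolerance = 0.01)
  expect_lt(max(fit$rmse), 1e-4)
})

test_that("null interactions fit to coefficients near zero", {
  p1 <- logistic_params(1.85, 0.61, 0.005, 2.35)
  p2 <- logistic_params(1.56, 0.35, 0.005, 2.25)
  sys <- lv_system(list(a = p1, b = p2), matrix(0, 2, 2))
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  fit <- fit_lv_to_coculture(tr, baselines = list(p1, p2),
                             start = c(-0.3, -0.3))
  expect_lt(max(abs(coef(fit))), 0.05)
})

test_that("fitted coefficients converge to truth as noise vanishes", {
  sys <- staph_pair_system()
  truth <- c(coef(sys)[1, 2], coef(sys)[2, 1])
  err <- vapply(c(0, 0.01, 0.02), function(sd_mult) {
    traces <- lapply(1:3, function(k)
      deconvolve_coculture(simulate_coculture_trace(
        sys, noise = noise_model(sd_mult, 0, 0, 0.001), seed = 600 + k,
        ratio = "1:1", replicate = k)))
    fit <- fit_lv_to_coculture(traces, baselines = sys$isolates,
                               start = truth)
    max(abs(coef(fit) - truth) / abs(truth))
  }, numeric(1))
  expect_lt(err[1], 0.01)
  expect_lt(err[2], 0.15)
  expect_lt(err[3], 0.15)
})

test_that("model-experiment comparison separates the generating system", {
  sys <- staph_pair_system()
  tr <- deconvolve_coculture(simulate_coculture_trace(sys, noise = noise_free))
  self <- compare_model_experiment(tr, sys)
  expect_lt(max(self$rmse), 1e-5)
  expect_true(all(self$sign_agreement))
  expect_true(all(self$c_model < 0) && all(self$c_empirical < 0))
  # a mis-specified model fits visibly worse
  wrong <- lv_system(sys$isolates,
                     matrix(c(0, 1.5 * coef(sys)[1, 2],
                              coef(sys)[2, 1], 0), 2, byrow = TRUE))
  expect_gt(compare_model_experiment(tr, wrong)$rmse[1], self$rmse[1])
})
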