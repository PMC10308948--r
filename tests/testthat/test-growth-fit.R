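test_that("smoothing is the identity on window 1 and on constants", {
  cv <- growth_curve(1:10, c(rep(0.01, 5), 0.1, 0.2, 0.3, 0.35, 0.35))
  expect_identical(smooth_curve(cv, 1)$od, cv$od)
  flat <- growth_curve(1:10, rep(0.2, 10))
  expect_equal(smooth_curve(flat, 5)$od, flat$od)
  expect_error(smooth_curve(cv, 4), "odd")
  expect_error(smooth_curve(cv, 11), "odd")
})

test_that("smoothing suppresses a single-read spike by at least 80%", {
  t <- seq(0, 10, by = 0.25)
  base <- 0.2 + 0.01 * t
  od <- base
  od[20] <- od[20] + 0.1
  sm <- smooth_curve(growth_curve(t, od), 5)
  expect_lt(abs(sm$od[20] - base[20]), 0.1 * 0.2)
})

test_that("carrying capacity is recovered from a noiseless logistic", {
  p <- logistic_params(1.56, 0.35, 0.005)
  cv <- simulate_monoculture_curve(p, noise_free)
  est <- estimate_carrying_capacity(cv)
  expect_equal(est$K, 0.35, tolerance = 1e-3)
  expect_false(est$diagnostics$truncated_plateau)
  expect_false(est$diagnostics$no_growth)
})

test_that("a truncated exponential is flagged as plateau-not-reached", {
  t <- seq(0, 8, by = 1/6)
  cv <- growth_curve(t, 0.005 * exp(0.5 * t))
  est <- estimate_carrying_capacity(cv)
  expect_true(est$diagnostics$truncated_plateau)
})

test_that("a flat curve yields its level with the no-growth flag", {
  cv <- growth_curve(seq(0, 10, by = 0.5), rep(0.005, 21))
  est <- estimate_carrying_capacity(cv)
  expect_equal(est$K, 0.005)
  expect_true(est$diagnostics$no_growth)
  fit <- fit_growth(cv)
  expect_identical(unname(coef(fit)["r"]), 0)
})

test_that("growth rate is exact on exponential data", {
  t <- seq(0, 3, by = 1/6)
  cv <- growth_curve(t, 0.005 * exp(1.85 * t))
  # far from capacity the transform reduces to log(S); slope is exact
  est <- estimate_growth_rate(cv, K = 1e6)
  expect_equal(est$r, 1.85, tolerance = 1e-6)
})

test_that("growth rate is recovered from a noiseless lagged logistic", {
  p <- logistic_params(1.56, 0.35, 0.005, T_L = 2.25)
  cv <- simulate_monoculture_curve(p, noise_free)
  K <- estimate_carrying_capacity(cv)$K
  est <- estimate_growth_rate(cv, K)
  expect_equal(est$r, 1.56, tolerance = 0.03)
  expect_gt(est$diagnostics$r_squared, 0.999)
})

test_that("growth-rate estimation is scale-equivariant", {
  p <- logistic_params(1.2, 0.4, 0.004, 1)
  cv <- simulate_monoculture_curve(p, noise_model(0.02, 0, 0, 0), seed = 8)
  r1 <- estimate_growth_rate(cv, 0.4)$r
  scaled <- growth_curve(cv$time, cv$od * 10)
  r2 <- estimate_growth_rate(scaled, 4, floor = 0.01)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("too few usable points raise an informative error", {
  t <- seq(0, 2, by = 0.5)
  cv <- growth_curve(t, c(0.005, 0.005, 0.005, 0.005, 0.0051),
                     isolate = "x", context = "fresh")
  expect_error(estimate_growth_rate(cv, K = 0.005), "x")
})

test_that("lag time is recovered and degenerate cases are handled", {
  p <- logistic_params(1.85, 0.61, 0.005, T_L = 2.35)
  cv <- simulate_monoculture_curve(p, noise_free)
  fit <- fit_growth(cv)
  expect_equal(unname(coef(fit)["T_L"]), 2.35, tolerance = 0.17)
  # noisy recovery stays within about one sampling interval (median)
  lags <- vapply(1:50, function(s) {
    cvn <- simulate_monoculture_curve(p, noise_model(0.02, 0.003, 0, 0.001),
                                      seed = 400 + s)
    unname(coef(fit_growth(cvn))["T_L"])
  }, numeric(1))
  expect_lt(median(abs(lags - 2.35)), 0.2)
  # an unlagged exponential extrapolates back to its start
  t <- seq(0, 3, by = 1/6)
  exp_cv <- growth_curve(t, 0.005 * exp(1.85 * t))
  expect_equal(estimate_lag_time(exp_cv, 1.85, 0.005, K = 1e3), 0,
               tolerance = 0.02)
  expect_true(is.na(estimate_lag_time(exp_cv, -1, 0.005)))
})

test_that("noisy parameter recovery meets the stated accuracy", {
  # 200 seeded replicates at the published parameter values
  p <- logistic_params(1.85, 0.61, 0.005, T_L = 2.35)
  noise <- noise_model(0.02, 0.003, 0, 0.001)
  err <- vapply(1:200, function(s) {
    co <- coef(fit_growth(simulate_monoculture_curve(p, noise, seed = s)))
    c(abs(co[["r"]] - 1.85) / 1.85, abs(co[["K"]] - 0.61) / 0.61)
  }, numeric(2))
  expect_lte(median(err[1, ]), 0.05)
  expect_lte(median(err[2, ]), 0.03)
})

test_that("estimates are invariant to appended post-plateau readings", {
  p <- logistic_params(1.56, 0.35, 0.005, T_L = 2)
  cv <- simulate_monoculture_curve(p, noise_free, duration = 30)
  co1 <- coef(fit_growth(cv))
  extra_t <- seq(max(cv$time) + 1/6, 48, by = 1/6)
  ext <- growth_curve(c(cv$time, extra_t),
                      c(cv$od, rep(cv$od[length(cv$od)], length(extra_t))))
  co2 <- coef(fit_growth(ext))
  expect_equal(co1, co2, tolerance = 1e-8)
})

test_that("panel fitting tabulates wells and aggregates into records", {
  spec <- example_panel_spec(3, seed = 31, replicates = 2)
  panel <- generate_cfsm_panel(spec, noise_model(0.02, 0.003, 0, 0.001))
  tab <- fit_growth_table(panel)
  expect_identical(nrow(tab), length(panel$curves))
  recs <- cfsm_records(tab)
  expect_true(all(c("focal", "context", "r", "K", "n") %in% names(recs)))
  expect_identical(sort(unique(recs$context)),
                   sort(c("fresh", names(spec$isolates))))
  # aggregated estimates track the generating truth
  truth <- panel$truth
  m <- merge(recs, truth, by.x = c("focal", "context"),
             by.y = c("focal", "context"))
  usable <- !m$suppressed.y & m$K_true > 0.05 & is.finite(m$r)
  expect_gt(sum(usable), 5)
  expect_lt(median(abs(m$K[usable] - m$K_true[usable]) / m$K_true[usable]),
            0.05)
})
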