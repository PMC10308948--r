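test_that("noise-free monoculture curves follow the closed form", {
  p <- logistic_params(1.85, 0.61, 0.005)
  cv <- simulate_monoculture_curve(p, noise_free, duration = 24)
  truth <- oracle_logistic(1.85, 0.61, 0.005, cv$time)
  expect_lt(max(abs(cv$od - truth) / truth), 1e-8)
  expect_identical(cv$od[1], 0.005)  # t = 0 is the inoculum
  # the frozen 2-h value
  expect_equal(cv$od[cv$time == 2], 0.1528230, tolerance = 1e-6)
})

test_that("generators are seed-deterministic", {
  p <- logistic_params(1.5, 0.5, 0.005, 2)
  a <- simulate_monoculture_curve(p, noise_model(), seed = 7)
  b <- simulate_monoculture_curve(p, noise_model(), seed = 7)
  expect_identical(a$od, b$od)
  spec <- example_panel_spec(3, seed = 5, replicates = 2, duration = 12)
  pa <- generate_cfsm_panel(spec)
  pb <- generate_cfsm_panel(spec)
  expect_identical(lapply(pa$curves, `[[`, "od"),
                   lapply(pb$curves, `[[`, "od"))
  sys <- staph_pair_system()
  ta <- simulate_coculture_trace(sys, seed = 3)
  tb <- simulate_coculture_trace(sys, seed = 3)
  expect_identical(ta$total_od, tb$total_od)
  expect_identical(ta$fluorescence, tb$fluorescence)
})

test_that("generator rejects invalid parameters", {
  p <- logistic_params(1.5, 0.5, 0.005, 2)
  expect_error(simulate_monoculture_curve(p, sampling_interval = 0), "interval")
  expect_error(simulate_monoculture_curve(p, duration = 1), "lag")
  expect_error(
    simulate_monoculture_curve(logistic_params(0, 0.5, 0.005)), "r")
  expect_error(noise_model(-0.1), "noise")
})

test_that("observed OD respects the detection floor and stays finite", {
  p <- logistic_params(1.2, 0.4, 0.005, 1)
  for (s in 1:20) {
    cv <- simulate_monoculture_curve(
      p, noise_model(0.1, 0.01, 0.002, 0.001), duration = 24, seed = s)
    expect_true(all(is.finite(cv$od)))
    expect_true(all(cv$od >= 0.001))
  }
})

test_that("LV-consistent panels satisfy the ratio identity by construction", {
  spec <- example_panel_spec(5, seed = 21)
  panel <- generate_cfsm_panel(spec, noise_free)
  truth <- panel$truth
  for (iso in names(spec$isolates)) {
    p <- spec$isolates[[iso]]
    rows <- truth[truth$focal == iso & truth$context != "fresh" &
                    !truth$suppressed, ]
    expect_equal(rows$r_true / rows$K_true, rep(p$r / p$K, nrow(rows)),
                 tolerance = 1e-14)
  }
})

test_that("noise-free LV panels regress to the baseline slope exactly", {
  spec <- example_panel_spec(4, seed = 13)
  truth <- generate_cfsm_panel(spec, noise_free)$truth
  for (iso in names(spec$isolates)) {
    rows <- truth[truth$focal == iso & truth$context != "fresh" &
                    !truth$suppressed, ]
    if (nrow(rows) < 3 || length(unique(rows$K_true)) < 2) next
    reg <- fit_rk_regression(data.frame(r = rows$r_true, K = rows$K_true))
    ratio <- spec$isolates[[iso]]$r / spec$isolates[[iso]]$K
    expect_equal(reg$slope, ratio, tolerance = 1e-10)
    expect_equal(reg$intercept, 0, tolerance = 1e-10)
    # subset invariance: any 3-record subset gives the same slope
    sub <- fit_rk_regression(data.frame(r = rows$r_true[1:3],
                                        K = rows$K_true[1:3]))
    expect_equal(sub$slope, ratio, tolerance = 1e-10)
  }
})

test_that("rate-yield-tradeoff panels regress with a negative slope", {
  spec <- example_panel_spec(4, seed = 13,
                             violation_mode = "rate_yield_tradeoff")
  truth <- generate_cfsm_panel(spec, noise_free)$truth
  for (iso in names(spec$isolates)) {
    rows <- truth[truth$focal == iso & truth$context != "fresh" &
                    !truth$suppressed, ]
    reg <- fit_rk_regression(data.frame(r = rows$r_true, K = rows$K_true))
    expect_lt(reg$slope, 0)
  }
})

test_that("a null interaction matrix reproduces the fresh-medium curve", {
  iso <- list(a = logistic_params(1.4, 0.45, 0.005, 2),
              b = logistic_params(1.0, 0.3, 0.005, 1.5))
  spec <- panel_spec(iso, matrix(0, 2, 2), replicates = 1, duration = 24)
  panel <- generate_cfsm_panel(spec, noise_free)
  for (iso_id in c("a", "b")) {
    curves <- Filter(function(cv) cv$meta$isolate == iso_id, panel$curves)
    fresh <- Filter(function(cv) cv$meta$context == "fresh", curves)[[1]]
    for (cv in curves) expect_identical(cv$od, fresh$od)
  }
})

test_that("noise-free coculture channels deconvolve back to the truth", {
  sys <- staph_pair_system()
  tr <- simulate_coculture_trace(sys, noise = noise_free)
  # the stated invariant: gfp_to_od(F) + S2 equals the total exactly
  ok <- !tr$truth$gap
  expect_equal(gfp_to_od(tr$fluorescence[ok]) + tr$truth$S2[ok],
               tr$total_od[ok], tolerance = 1e-12)
  dec <- deconvolve_coculture(tr)
  expect_lt(max(abs(dec$od1[ok] - tr$truth$S1[ok]) /
                  pmax(tr$truth$S1[ok], 1e-12)), 1e-6)
  expect_lt(max(abs(dec$od2[ok] - tr$truth$S2[ok]) /
                  pmax(tr$truth$S2[ok], 1e-12)), 1e-6)
})

test_that("an absent reporter species yields a constant fluorescence channel", {
  sys <- staph_pair_system()
  tr <- simulate_coculture_trace(sys, init = c(0, 0.005), noise = noise_free)
  expect_equal(tr$fluorescence,
               rep(as.numeric(invert_gfp_calibration(0, extrapolate = TRUE)),
                   length(tr$time)))
})

test_that("saturating (non-LV) dynamics produce a valid bounded trace", {
  tr <- simulate_coculture_trace(staph_pair_system(), noise = noise_free,
                                 dynamics = "saturating")
  expect_true(all(is.finite(tr$total_od)))
  expect_true(all(tr$truth$S1 <= table2$K1 + 1e-9))
  expect_true(all(tr$truth$S2 <= table2$K2 + 1e-9))
})
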