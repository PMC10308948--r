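test_that("collinear records give the exact line and guards fire", {
  K <- c(0.1, 0.25, 0.4, 0.55)
  recs <- data.frame(r = 3.2 * K, K = K)
  reg <- fit_rk_regression(recs)
  expect_equal(reg$slope, 3.2, tolerance = 1e-12)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_identical(reg$n, 4L)
  expect_error(fit_rk_regression(recs[1:2, ]), "at least 3")
  expect_error(fit_rk_regression(data.frame(r = c(1, 2, 3),
                                            K = rep(0.2, 3))), "spread")
  multi <- data.frame(focal = c("a", "a", "a", "b"), r = 3.2 * K, K = K)
  expect_error(fit_rk_regression(multi), "multiple focal")
  expect_equal(fit_rk_regression(multi, focal = "a")$n, 3L)
})

test_that("a perfect LV panel passes and violations fail with reasons", {
  baseline <- list(r = 1.85, K = 0.61)
  K <- c(0.1, 0.2, 0.35, 0.5, 0.61)
  perfect <- fit_rk_regression(data.frame(r = (1.85 / 0.61) * K, K = K))
  v <- lv_consistency_test(perfect, baseline)
  expect_true(v$lv_consistent)
  expect_length(v$reasons, 0)
  # rate-yield tradeoff: negative slope named in the reasons
  neg <- fit_rk_regression(data.frame(r = 2 - 2 * K, K = K))
  vn <- lv_consistency_test(neg, baseline)
  expect_false(vn$lv_consistent)
  expect_true(any(grepl("negative slope", vn$reasons)))
  # significant positive slope that misses the baseline ratio
  off <- fit_rk_regression(data.frame(r = 1.2 * K, K = K))
  vo <- lv_consistency_test(off, baseline)
  expect_false(vo$lv_consistent)
  expect_true(any(grepl("deviates", vo$reasons)))
})

test_that("shuffled-capacity panels are rejected with high probability", {
  verdicts <- unlist(lapply(1:15, function(s)
    panel_verdicts(example_panel_spec(6, seed = s,
                                      violation_mode = "shuffled_K"))))
  expect_lte(mean(verdicts, na.rm = TRUE), 0.25)
})

test_that("habitat quality is the capacity ratio and is monotone", {
  baseline <- list(K = 0.61)
  expect_identical(habitat_quality(0.61, baseline), 1)
  expect_identical(habitat_quality(0, baseline), 0)
  expect_equal(habitat_quality(0.17, baseline), 0.2787, tolerance = 1e-4)
  q <- habitat_quality(seq(0, 1, by = 0.05), baseline)
  expect_true(all(diff(q) > 0))
  rec <- cfsm_record(0.5, 0.17, "a", "b")
  expect_equal(habitat_quality(rec, baseline), 0.17 / 0.61)
})

test_that("combined-CFSM additivity detects matches and separations", {
  set.seed(77)
  resp_j <- rnorm(6, 0.40, 0.01)
  resp_k <- rnorm(6, 0.20, 0.01)
  mixed <- (resp_j + resp_k) / 2
  expect_true(combined_cfsm_additivity(resp_j, resp_k, mixed)$additive)
  shifted <- mixed + 10 * sd(mixed)
  expect_false(combined_cfsm_additivity(resp_j, resp_k, shifted)$additive)
  expect_error(combined_cfsm_additivity(resp_j[1:3], resp_k, mixed), "equal")
  expect_error(combined_cfsm_additivity(resp_j[1:2], resp_k[1:2],
                                        mixed[1:2]), "3 replicates")
})

test_that("the additivity test holds its nominal size under the null", {
  set.seed(123)
  rejections <- vapply(1:1000, function(i) {
    j <- rnorm(6, 0.3, 0.02); k <- rnorm(6, 0.3, 0.02)
    m <- rnorm(6, 0.3, 0.02)
    combined_cfsm_additivity(j, k, m)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
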