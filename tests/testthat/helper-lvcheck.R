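# Shared fixtures and independent oracles for the test suite.

noise_free <- noise_model(0, 0, 0, 0)

# the published two-isolate parameter set used throughout
table2 <- staph_pair_params()

# independent closed-form logistic oracle (textbook form, written without
# reference to the package implementation)
oracle_logistic <- function(r, K, S0, t, T_L = 0) {
  tt <- pmax(t - T_L, 0)
  K * S0 * exp(r * tt) / (K + S0 * (exp(r * tt) - 1))
}

# independent fixed-step RK4 integrator for the two-species LV system,
# used as a dual-route check on the adaptive solver
oracle_rk4_lv <- function(r, K, lag, cmat, init, t_end, dt = 5e-4) {
  cmat0 <- cmat; diag(cmat0) <- 0
  f <- function(t, S) {
    active <- as.numeric(t >= lag)
    active * r * S * (1 - (S - as.numeric(cmat0 %*% S)) / K)
  }
  S <- init
  t <- 0
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- f(t, S)
    k2 <- f(t + h / 2, S + h / 2 * k1)
    k3 <- f(t + h / 2, S + h / 2 * k2)
    k4 <- f(t + h, S + h * k3)
    S <- pmax(S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    t <- t + h
  }
  S
}

# verdicts for every isolate of a synthetic panel, via the full
# fit -> aggregate -> regress -> test chain (regression on CFSM contexts;
# fresh medium supplies the baseline)
panel_verdicts <- function(spec, noise = noise_model(0.02, 0.003, 0, 0.001)) {
  panel <- generate_cfsm_panel(spec, noise)
  recs <- cfsm_records(fit_growth_table(panel))
  vapply(names(spec$isolates), function(iso) {
    fresh <- recs[recs$focal == iso & recs$context == "fresh", ]
    cf <- recs[recs$focal == iso & recs$context != "fresh", ]
    reg <- tryCatch(fit_rk_regression(cf, focal = iso),
                    error = function(e) NULL)
    if (is.null(reg) || !nrow(fresh)) return(NA)
    lv_consistency_test(reg, list(r = fresh$r, K = fresh$K))$lv_consistent
  }, logical(1))
}
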