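# Coculture analysis: fluorescence-based deconvolution of species
# densities, time-resolved empirical interaction coefficients, and
# least-squares LV fitting to measured dynamics.

# Local-quadratic (Savitzky-Golay) smoothing of log-density: a moving
# median removes single-read spikes, then a centered least-squares
# quadratic replaces each point. Working on the log scale with a quadratic
# kernel is exact for exponential growth, so the smoother does not bias the
# growing phase the way a flat moving mean would (a flat mean inflates an
# exponential by ~ (r dt)^2 per window point).
sg_center_weights <- function(window) {
  j <- -(window %/% 2L):(window %/% 2L)
  X <- cbind(1, j, j^2)
  as.numeric((solve(crossprod(X)) %*% t(X))[1L, ])
}

smooth_log_density <- function(x, window, eps = 1e-9) {
  lx <- log(pmax(x, eps))
  if (window <= 1L) return(lx)
  lx <- as.numeric(stats::runmed(lx, window, endrule = "median"))
  sm <- as.numeric(stats::filter(lx, sg_center_weights(window), sides = 2L))
  sm[is.na(sm)] <- lx[is.na(sm)]  # keep raw values at the record edges
  sm
}

#' Deconvolve a coculture trace into per-species densities
#'
#' Converts the fluorescence channel to the reporter strain's OD600 via the
#' [gfp_calibration] (\code{od1 = gfp_to_od(F)}) and obtains the partner by
#' subtraction (\code{od2 = max(0, total - od1)}). Points where the
#' converted reporter OD exceeds the total are clamped and flagged; points
#' whose reporter OD sits at the calibration's branch boundary (the
#' unreachable gap maps there) are flagged as \code{boundary} since their
#' conversion is biased by up to the gap width (~3%).
#'
#' @param trace a [coculture_trace] with total-OD and fluorescence
#'   channels.
#' @param cal a [gfp_calibration].
#'
#' @return The trace with \code{od1}, \code{od2} and a \code{flags} list
#'   (\code{clamped}, \code{boundary}, and the flagged fraction) filled in.
#' @export
deconvolve_coculture <- function(trace, cal = gfp_calibration()) {
  stopifnot(inherits(trace, "coculture_trace"))
  od1 <- gfp_to_od(trace$fluorescence, cal)
  clamped <- od1 > trace$total_od
  od2 <- pmax(trace$total_od - od1, 0)
  od1 <- pmin(od1, trace$total_od)
  # reporter ODs emitted exactly at the upper-branch edge are gap-mapped
  boundary <- abs(od1 - cal$od_sqrt_min) < 1e-12
  trace$od1 <- od1
  trace$od2 <- od2
  trace$flags <- list(clamped = clamped, boundary = boundary,
                      fraction_flagged = mean(clamped | boundary))
  trace
}

#' Initial densities of a coculture from its pre-growth readings
#'
#' Per species, the median of the deconvolved density over the points
#' before that species' lag ends (at least the first three readings). This
#' absorbs inoculation error instead of trusting the nominal inoculum.
#'
#' @param trace a deconvolved [coculture_trace].
#' @param lags numeric vector of the two lag times (hours), or an
#'   [lv_system] to take them from.
#'
#' @return Numeric vector of two initial densities (OD600).
#' @export
estimate_initial_densities <- function(trace, lags) {
  stopifnot(inherits(trace, "coculture_trace"))
  if (is.null(trace$od1)) stop("trace must be deconvolved first")
  if (inherits(lags, "lv_system"))
    lags <- vapply(lags$isolates, `[[`, numeric(1), "T_L")
  vapply(1:2, function(i) {
    ch <- if (i == 1L) trace$od1 else trace$od2
    idx <- which(trace$time <= lags[i])
    if (length(idx) < 3L) idx <- 1:3
    max(stats::median(ch[idx]), 1e-6)
  }, numeric(1))
}

#' Time-resolved empirical interaction coefficient
#'
#' Inverts the coculture LV equation point by point: with smoothed
#' species channels and the focal isolate's monoculture baseline
#' (\code{r_i}, \code{K_i}),
#' \deqn{\hat c_{ij}(t) = \frac{S_i - K_i + K_i \, \dot S_i/(r_i S_i)}{S_j}.}
#' If the dynamics truly are LV, this trace is constant and equal to
#' \code{c_ij}. Derivatives are geometric centered differences
#' (\eqn{\dot S = S \cdot d\log S/dt}), exact for exponential growth, on
#' median-then-mean smoothed channels. Estimates are restricted to the
#' exponential window -- by default from just after the focal lag to 4.5 h
#' later -- and to points where the partner density exceeds
#' \code{partner_floor} and no deconvolution flag is set.
#'
#' @param trace a deconvolved [coculture_trace].
#' @param baseline_i focal isolate's fresh-medium [logistic_params].
#' @param baseline_j partner's fresh-medium [logistic_params] (used for its
#'   lag when positioning the window).
#' @param focal which trace channel is the focal species (1 or 2).
#' @param window numeric \code{c(start, end)} in hours, or \code{NULL} for
#'   the default exponential window.
#' @param window_span length of the default window in hours (the stated
#'   "first 4 to 5 h of growth"; 4.5 h by default).
#' @param smooth_window smoothing window in points.
#' @param partner_floor smallest partner density (OD600) at which a point
#'   is used (division guard).
#'
#' @return An object of class \code{"interaction_trace"}: \code{time},
#'   \code{c_hat}, a \code{valid} mask, and the window used.
#' @export
empirical_interaction_trace <- function(trace, baseline_i, baseline_j,
                                        focal = 1L, window = NULL,
                                        window_span = 4.5,
                                        smooth_window = 5L,
                                        partner_floor = 0.005) {
  stopifnot(inherits(trace, "coculture_trace"),
            inherits(baseline_i, "logistic_params"),
            inherits(baseline_j, "logistic_params"))
  if (is.null(trace$od1)) stop("trace must be deconvolved first")
  focal <- as.integer(focal)
  if (!focal %in% 1:2) stop("'focal' must be 1 or 2")
  t <- trace$time
  dt <- stats::median(diff(t))
  raw_i <- if (focal == 1L) trace$od1 else trace$od2
  raw_j <- if (focal == 1L) trace$od2 else trace$od1
  L_i <- smooth_log_density(raw_i, smooth_window)
  L_j <- smooth_log_density(raw_j, smooth_window)
  S_i <- exp(L_i)
  S_j <- exp(L_j)
  if (is.null(window)) {
    # start after the focal lag, clear of the smoothing half-width so the
    # lag kink does not leak into the derivative
    margin <- (smooth_window %/% 2L + 2L) * dt
    window <- c(baseline_i$T_L + margin, baseline_i$T_L + window_span)
  }
  n <- length(t)
  dlog <- rep(NA_real_, n)
  inner <- 2:(n - 1L)
  dlog[inner] <- (L_i[inner + 1L] - L_i[inner - 1L]) /
    (t[inner + 1L] - t[inner - 1L])
  c_hat <- (S_i - baseline_i$K + baseline_i$K * dlog / baseline_i$r) / S_j
  flagged <- if (is.null(trace$flags)) rep(FALSE, n)
             else (trace$flags$clamped | trace$flags$boundary)
  # a flagged reading contaminates every smoothed value within the window
  half <- smooth_window %/% 2L
  if (any(flagged) && half > 0L) {
    idx <- which(flagged)
    spread <- unique(pmin(pmax(rep(idx, each = 2L * half + 1L) +
                                 (-half):half, 1L), n))
    flagged[spread] <- TRUE
  }
  valid <- is.finite(c_hat) & t >= window[1] & t <= window[2] &
    S_j > partner_floor & !flagged
  if (!any(valid))
    stop("no valid points in the exponential window; cannot estimate c")
  structure(list(time = t, c_hat = c_hat, valid = valid, focal = focal,
                 window = window), class = "interaction_trace")
}

#' @export
print.interaction_trace <- function(x, ...) {
  est <- x$c_hat[x$valid]
  cat(sprintf(
    "Empirical interaction trace (focal channel %d): median c = %.4g over %d valid points (window %.2f-%.2f h)\n",
    x$focal, stats::median(est), length(est), x$window[1], x$window[2]))
  invisible(x)
}

#' @export
median.interaction_trace <- function(x, na.rm = FALSE, ...) {
  stats::median(x$c_hat[x$valid], na.rm = na.rm)
}

#' @export
plot.interaction_trace <- function(x, ...) {
  graphics::plot(x$time[x$valid], x$c_hat[x$valid], pch = 1,
                 xlab = "time (h)", ylab = expression(hat(c)[ij](t)), ...)
  graphics::abline(h = stats::median(x$c_hat[x$valid]), lty = 3)
  invisible(x)
}

#' Fit LV interaction coefficients to coculture dynamics
#'
#' Least-squares fit of the two interaction coefficients (c12, c21) of a
#' two-species LV system to one or more deconvolved coculture traces,
#' keeping the monoculture baselines (r, K, lag) fixed. Traces are grouped
#' by their initial-ratio metadata; per group, initial densities are taken
#' from the traces' pre-lag deconvolved readings (averaged across
#' replicates) and a single trajectory is integrated per objective
#' evaluation, so replicates share predictions. The objective is the
#' summed squared residual over both species channels of every trace
#' (deconvolution-flagged points excluded); it is minimized by Nelder-Mead
#' from \code{start} -- by default the CFSM-derived coefficients, the
#' natural prior -- with coefficients softly confined to \code{bounds}.
#'
#' @param traces a [coculture_trace] or list of them (deconvolved; raw
#'   traces are deconvolved with \code{cal}).
#' @param baselines list of two fresh-medium [logistic_params]
#'   (focal = channel 1, partner = channel 2).
#' @param start numeric \code{c(c12, c21)} starting values; default the
#'   median empirical interaction coefficients of the first trace.
#' @param bounds admissible coefficient range.
#' @param cal a [gfp_calibration] used if traces are not yet deconvolved.
#' @param control passed to [stats::optim()].
#'
#' @return An object of class \code{"lv_fit"}: fitted coefficients,
#'   per-channel RMSE, the fitted [lv_system], start values, optimizer
#'   diagnostics. Supports \code{coef}, \code{print}, \code{predict}.
#' @examples
#' \donttest{
#' sys <- staph_pair_system()
#' tr <- deconvolve_coculture(simulate_coculture_trace(
#'   sys, noise = noise_model(0, 0, 0, 0), ratio = "1:1"))
#' fit <- fit_lv_to_coculture(tr, baselines = sys$isolates,
#'                            start = c(-1, -0.4))
#' coef(fit)
#' }
#' @export
fit_lv_to_coculture <- function(traces, baselines, start = NULL,
                                bounds = c(-5, 5), cal = gfp_calibration(),
                                control = list(reltol = 1e-8, maxit = 1000)) {
  if (inherits(traces, "coculture_trace")) traces <- list(traces)
  stopifnot(is.list(traces), length(traces) >= 1L,
            is.list(baselines), length(baselines) == 2L)
  lapply(baselines, function(p)
    if (!inherits(p, "logistic_params")) stop("baselines must be 'logistic_params'"))
  traces <- lapply(traces, function(tr) {
    if (is.null(tr$od1)) deconvolve_coculture(tr, cal) else tr
  })
  lags <- vapply(baselines, `[[`, numeric(1), "T_L")

  make_system <- function(c12, c21)
    lv_system(baselines, matrix(c(0, c12, c21, 0), 2, byrow = TRUE),
              names = c("sp1", "sp2"))

  if (is.null(start)) {
    start <- vapply(1:2, function(f) {
      est <- tryCatch(
        median(empirical_interaction_trace(
          traces[[1]], baselines[[f]], baselines[[3 - f]], focal = f)),
        error = function(e) 0)
      min(max(est, bounds[1]), bounds[2])
    }, numeric(1))
  }

  ratio_key <- vapply(traces, function(tr) {
    if (!is.null(tr$meta$ratio) && !is.na(tr$meta$ratio))
      as.character(tr$meta$ratio)
    else paste0("trace", format(round(tr$total_od[1], 5)))
  }, character(1))
  groups <- split(seq_along(traces), ratio_key)
  group_init <- lapply(groups, function(ix) {
    inits <- vapply(traces[ix], estimate_initial_densities, numeric(2),
                    lags = lags)
    rowMeans(matrix(inits, nrow = 2L))
  })
  group_times <- lapply(groups, function(ix) traces[[ix[1]]]$time)
  use_mask <- lapply(traces, function(tr) {
    if (is.null(tr$flags)) rep(TRUE, length(tr$time))
    else !(tr$flags$clamped | tr$flags$boundary)
  })

  objective <- function(par) {
    pen <- sum(pmax(par - bounds[2], 0)^2 + pmax(bounds[1] - par, 0)^2)
    par <- pmin(pmax(par, bounds[1]), bounds[2])
    sys <- make_system(par[1], par[2])
    ssr <- 0
    for (g in seq_along(groups)) {
      traj <- tryCatch(
        simulate_lv(sys, init = group_init[[g]], times = group_times[[g]]),
        error = function(e) NULL)
      if (is.null(traj)) return(1e6)
      for (ix in groups[[g]]) {
        m <- use_mask[[ix]]
        ssr <- ssr + sum((traces[[ix]]$od1[m] - traj[[2]][m])^2) +
          sum((traces[[ix]]$od2[m] - traj[[3]][m])^2)
      }
    }
    ssr + 1e3 * pen
  }

  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = control)
  if (opt$convergence != 0)
    warning(sprintf("LV fit did not fully converge (code %d, objective %.4g)",
                    opt$convergence, opt$value))
  c_hat <- pmin(pmax(opt$par, bounds[1]), bounds[2])
  sys <- make_system(c_hat[1], c_hat[2])
  res1 <- res2 <- numeric(0)
  for (g in seq_along(groups)) {
    traj <- simulate_lv(sys, init = group_init[[g]], times = group_times[[g]])
    for (ix in groups[[g]]) {
      m <- use_mask[[ix]]
      res1 <- c(res1, traces[[ix]]$od1[m] - traj[[2]][m])
      res2 <- c(res2, traces[[ix]]$od2[m] - traj[[3]][m])
    }
  }
  structure(list(coefficients = c(c12 = c_hat[1], c21 = c_hat[2]),
                 start = c(c12 = start[1], c21 = start[2]),
                 system = sys,
                 rmse = c(od1 = sqrt(mean(res1^2)), od2 = sqrt(mean(res2^2))),
                 value = opt$value, convergence = opt$convergence,
                 n_traces = length(traces),
                 groups = lapply(group_init, identity)),
            class = "lv_fit")
}

#' @export
print.lv_fit <- function(x, ...) {
  cat(sprintf("LV fit to %d coculture trace%s\n", x$n_traces,
              if (x$n_traces == 1L) "" else "s"))
  cat(sprintf("  c12 = %.4g, c21 = %.4g (started from %.4g, %.4g)\n",
              x$coefficients[1], x$coefficients[2], x$start[1], x$start[2]))
  cat(sprintf("  RMSE: %.4g OD600 (reporter channel), %.4g OD600 (partner channel)\n",
              x$rmse[1], x$rmse[2]))
  invisible(x)
}

#' @export
coef.lv_fit <- function(object, ...) object$coefficients

#' @export
predict.lv_fit <- function(object, times, init = NULL, ...) {
  simulate_lv(object$system, init = init, times = times)
}

#' Compare a coculture trace against an LV model
#'
#' Simulates the given [lv_system] from the trace's own (estimated) initial
#' densities and reports per-channel RMSE together with the sign agreement
#' between the model's interaction coefficients and the median empirical
#' coefficients inferred from the trace.
#'
#' @param trace a deconvolved [coculture_trace].
#' @param system a fully specified two-isolate [lv_system] (CFSM-derived or
#'   fitted).
#' @param cal a [gfp_calibration] used if the trace is not yet
#'   deconvolved.
#'
#' @return An object of class \code{"lv_comparison"}: per-channel RMSE, the
#'   model and empirical coefficients, and per-pair sign agreement.
#' @export
compare_model_experiment <- function(trace, system, cal = gfp_calibration()) {
  stopifnot(inherits(trace, "coculture_trace"), inherits(system, "lv_system"))
  if (length(system$isolates) != 2L) stop("a two-isolate system is required")
  if (is.null(trace$od1)) trace <- deconvolve_coculture(trace, cal)
  init <- estimate_initial_densities(trace, system)
  traj <- simulate_lv(system, init = init, times = trace$time)
  m <- if (is.null(trace$flags)) rep(TRUE, length(trace$time))
       else !(trace$flags$clamped | trace$flags$boundary)
  rmse <- c(od1 = sqrt(mean((trace$od1[m] - traj[[2]][m])^2)),
            od2 = sqrt(mean((trace$od2[m] - traj[[3]][m])^2)))
  c_model <- c(c12 = system$c[1, 2], c21 = system$c[2, 1])
  c_emp <- vapply(1:2, function(f) {
    tryCatch(median(empirical_interaction_trace(
      trace, system$isolates[[f]], system$isolates[[3 - f]], focal = f)),
      error = function(e) NA_real_)
  }, numeric(1))
  names(c_emp) <- c("c12", "c21")
  structure(list(rmse = rmse, c_model = c_model, c_empirical = c_emp,
                 sign_agreement = sign(c_emp) == sign(c_model)),
            class = "lv_comparison")
}

#' @export
print.lv_comparison <- function(x, ...) {
  cat("Model-experiment comparison\n")
  cat(sprintf("  RMSE: %.4g OD600 (reporter), %.4g OD600 (partner)\n",
              x$rmse[1], x$rmse[2]))
  cat(sprintf("  c12: model %.4g vs empirical %.4g (%s)\n",
              x$c_model[1], x$c_empirical[1],
              if (isTRUE(x$sign_agreement[1])) "signs agree" else "signs differ"))
  cat(sprintf("  c21: model %.4g vs empirical %.4g (%s)\n",
              x$c_model[2], x$c_empirical[2],
              if (isTRUE(x$sign_agreement[2])) "signs agree" else "signs differ"))
  invisible(x)
}
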