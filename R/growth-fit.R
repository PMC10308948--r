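# Growth-curve parameter estimation: smoothing, carrying capacity from the
# curve maximum, growth rate from a log-linear fit over early growth, lag
# time from the fit line's intercept with the inoculum density.

# centered moving mean with shrinking windows at the edges
moving_mean <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# smoothed od vector (median filter then moving mean)
smooth_od <- function(od, window) {
  if (window == 1L) return(od)
  moving_mean(as.numeric(stats::runmed(od, window, endrule = "median")),
              window)
}

#' Smooth a growth curve
#'
#' Centered moving-median followed by a centered moving-mean of the OD
#' channel (time unchanged). The median stage removes single-read spikes;
#' the mean stage suppresses read noise. \code{window = 1} is the identity.
#'
#' @param curve a [growth_curve].
#' @param window odd window size in points, \code{1 <= window <= length}.
#'
#' @return A smoothed [growth_curve].
#' @export
smooth_curve <- function(curve, window = 5L) {
  stopifnot(inherits(curve, "growth_curve"))
  window <- as.integer(window)
  if (window < 1L || window > length(curve$od) || window %% 2L == 0L)
    stop("'window' must be odd, >= 1 and <= the number of readings")
  out <- curve
  out$od <- smooth_od(curve$od, window)
  out
}

fit_diagnostics <- function(window_start = NA_real_, window_end = NA_real_,
                            n_points = NA_integer_, r_squared = NA_real_,
                            truncated_plateau = FALSE, no_growth = FALSE,
                            widened = FALSE, intercept = NA_real_) {
  structure(list(window_start = window_start, window_end = window_end,
                 n_points = n_points, r_squared = r_squared,
                 truncated_plateau = truncated_plateau, no_growth = no_growth,
                 widened = widened, intercept = intercept),
            class = "fit_diagnostics")
}

# cheap OLS of y on x: slope, intercept, R^2
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  slope <- sum(dx * (y - my)) / sxx
  res <- y - my - slope * dx
  ss_tot <- sum((y - my)^2)
  list(slope = slope, intercept = my - slope * mx,
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_)
}

#' Estimate carrying capacity from a growth curve
#'
#' The carrying capacity is taken as the maximum of the smoothed OD over
#' the record (maximum OD600 as a proxy for K). Two guard flags are
#' reported: \code{no_growth} when the curve never rises to twice its
#' pre-peak minimum, and \code{truncated_plateau} when the final smoothed
#' value is within 5% of the maximum while the last-quarter slope still
#' exceeds 2% of K per hour (the plateau was not reached within the assay).
#'
#' @param curve a [growth_curve].
#' @param window smoothing window (points, odd) used before taking the
#'   maximum.
#' @param floor detection floor (OD600) for the no-growth guard.
#'
#' @return A list with elements \code{K} (OD600) and \code{diagnostics}.
#' @export
estimate_carrying_capacity <- function(curve, window = 5L, floor = 0.001) {
  stopifnot(inherits(curve, "growth_curve"))
  window <- min(as.integer(window), length(curve$od))
  if (window %% 2L == 0L) window <- window - 1L
  sm <- smooth_od(curve$od, window)
  K <- max(sm)
  peak <- which.max(sm)
  pre_min <- min(sm[seq_len(peak)])
  no_growth <- K < 2 * max(pre_min, floor)
  n <- length(sm)
  q <- seq.int(max(1L, n - (n %/% 4L) + 1L), n)
  tail_slope <- if (length(q) >= 3L) ols_line(curve$time[q], sm[q])$slope else 0
  truncated <- (sm[n] >= 0.95 * K) && (tail_slope > 0.02 * K)
  list(K = K,
       diagnostics = fit_diagnostics(
         window_start = curve$time[1], window_end = curve$time[n],
         n_points = n, truncated_plateau = truncated, no_growth = no_growth))
}

# select the early-exponential fitting window; returns indices.
# The lag plateau level is estimated as the median of the smoothed pre-peak
# readings below 15% of K; growth is taken to start once the smoothed curve
# clears twice that level, so a plateau fluctuating with read noise cannot
# leak flat points into the log-linear fit.
exp_window_idx <- function(curve, K, upper_fraction, floor, window) {
  sm <- smooth_od(curve$od, window)
  peak <- which.max(sm)
  pre <- seq_len(peak)
  cand <- pre[sm[pre] <= 0.15 * K]
  if (length(cand) < 3L) cand <- seq_len(min(3L, peak))
  plateau <- stats::median(sm[cand])
  which(seq_along(sm) <= peak &
          curve$od > floor &
          curve$od < 0.99 * K &
          sm >= 2 * plateau &
          sm <= upper_fraction * K)
}

# capacity-corrected log transform: log(S K/(K - S)) is exactly linear in
# time for logistic growth, so the early-window fit is unbiased by the
# onset of saturation (it reduces to log(S) as K -> Inf)
logit_density <- function(od, K) log(od) - log1p(-od / K)

#' Estimate growth rate from the early-exponential window
#'
#' Ordinary least squares of the log-transformed readings on time over the
#' early stage of growth: readings above the detection floor, clear of the
#' lag plateau (after the last pre-peak point within 20% of the pre-growth
#' minimum) and at or below \code{upper_fraction} of the carrying capacity
#' (30% by default). The log transform is capacity-corrected,
#' \code{log(S K/(K - S))}, which is exactly linear in time for logistic
#' growth, so the estimate is not biased by the onset of saturation inside
#' the window; for readings far below K it coincides with \code{log(S)}.
#' If fewer than 4 points qualify, the window is widened once to 50% of K
#' and the fit is flagged; fewer than 4 points after widening is an error.
#'
#' @param curve a [growth_curve].
#' @param K carrying capacity (OD600, > 0), e.g. from
#'   [estimate_carrying_capacity()].
#' @param upper_fraction upper edge of the fitting window as a fraction of
#'   K (0 < upper_fraction < 1).
#' @param floor detection floor (OD600); readings at or below it are
#'   excluded from the log fit.
#' @param window smoothing window used to locate the fitting region (the
#'   fit itself uses the raw readings).
#'
#' @return A list with elements \code{r} (per hour) and \code{diagnostics}
#'   (fitting window, number of points, R-squared, intercept of the
#'   log-linear line, widening flag).
#' @export
estimate_growth_rate <- function(curve, K, upper_fraction = 0.3,
                                 floor = 0.001, window = 5L) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(K) || K <= 0) stop("'K' must be > 0")
  if (upper_fraction <= 0 || upper_fraction >= 1)
    stop("'upper_fraction' must be in (0, 1)")
  idx <- exp_window_idx(curve, K, upper_fraction, floor, window)
  widened <- FALSE
  if (length(idx) < 4L) {
    idx <- exp_window_idx(curve, K, 0.5, floor, window)
    widened <- TRUE
  }
  if (length(idx) < 4L)
    stop(sprintf(
      "too few usable points (%d) for a growth-rate fit on isolate %s / %s rep %s",
      length(idx), curve$meta$isolate, curve$meta$context,
      as.character(curve$meta$replicate)))
  fit <- ols_line(curve$time[idx], logit_density(curve$od[idx], K))
  list(r = fit$slope,
       diagnostics = fit_diagnostics(
         window_start = curve$time[idx[1]],
         window_end = curve$time[idx[length(idx)]],
         n_points = length(idx), r_squared = fit$r_squared,
         widened = widened, intercept = fit$intercept))
}

#' Estimate lag time from the log-linear fit
#'
#' The lag time is the time at which the early-growth log-linear line
#' extrapolates back to the inoculum density: \code{T_L = (log(S0) -
#' intercept)/slope}, clipped at zero. The line is refitted on the curve's
#' early-exponential window; a non-positive growth rate yields \code{NA}.
#'
#' @param curve a [growth_curve].
#' @param r estimated growth rate (per hour); only its sign is used as a
#'   guard, the refitted slope determines the crossing.
#' @param S0 inoculum density (OD600).
#' @param K carrying capacity; if \code{NULL}, estimated from the curve.
#' @param upper_fraction,floor,window as in [estimate_growth_rate()].
#'
#' @return Lag time in hours (>= 0), or \code{NA} when growth is absent.
#' @export
estimate_lag_time <- function(curve, r, S0, K = NULL, upper_fraction = 0.3,
                              floor = 0.001, window = 5L) {
  if (!is.numeric(r) || is.na(r) || r <= 0) return(NA_real_)
  if (S0 <= 0) stop("'S0' must be > 0")
  if (is.null(K)) K <- estimate_carrying_capacity(curve, window, floor)$K
  gr <- estimate_growth_rate(curve, K, upper_fraction, floor, window)
  max(0, (logit_density(min(S0, 0.99 * K), K) - gr$diagnostics$intercept) / gr$r)
}

#' Fit the lagged logistic model to a growth curve
#'
#' The package's one-stop growth-curve fit: estimates the carrying capacity
#' from the smoothed maximum, the growth rate from a log-linear fit over
#' early growth, the inoculum density from the pre-growth plateau, and the
#' lag time from the fit line's crossing of the inoculum density. Wells
#' without measurable growth are returned with \code{r = 0} and flagged
#' rather than raising an error.
#'
#' If \code{blank} readings are supplied (a vector of blank-well OD at the
#' same time points, or a single value), their per-time median is
#' subtracted from the curve before fitting.
#'
#' @param curve a [growth_curve].
#' @param window smoothing window in points (odd).
#' @param upper_fraction upper edge of the growth-rate window as a fraction
#'   of K.
#' @param floor detection floor (OD600).
#' @param blank optional blank-well readings to subtract.
#'
#' @return An object of class \code{"growth_fit"} with components
#'   \code{params} ([logistic_params]), \code{diagnostics}, and the fitted
#'   \code{curve}; supports \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{plot}, \code{summary}.
#' @examples
#' p <- logistic_params(1.56, 0.35, 0.005, T_L = 2.25)
#' curve <- simulate_monoculture_curve(p, noise_model(0, 0, 0, 0))
#' fit <- fit_growth(curve)
#' coef(fit)
#' @export
fit_growth <- function(curve, window = 5L, upper_fraction = 0.3,
                       floor = 0.001, blank = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.null(blank)) {
    # per-time median across blank wells (matrix: time x wells), or a
    # per-time vector / single value
    b <- if (is.matrix(blank)) apply(blank, 1L, stats::median) else blank
    curve$od <- pmax(curve$od - b, floor)
  }
  cap <- estimate_carrying_capacity(curve, window, floor)
  K <- cap$K
  sm <- smooth_od(curve$od, min(window, length(curve$od)))
  peak <- which.max(sm)
  S0 <- max(min(sm[seq_len(peak)]), floor)
  if (cap$diagnostics$no_growth) {
    params <- logistic_params(0, K, min(S0, K), 0)
    return(structure(list(params = params, curve = curve, rate_failed = FALSE,
                          diagnostics = list(capacity = cap$diagnostics,
                                             rate = fit_diagnostics(no_growth = TRUE))),
                     class = "growth_fit"))
  }
  # a failed rate fit (e.g. capacity barely above the inoculum) still
  # leaves the capacity estimate usable: flag instead of erroring
  gr <- tryCatch(estimate_growth_rate(curve, K, upper_fraction, floor, window),
                 error = function(e) NULL)
  if (is.null(gr)) {
    params <- logistic_params(0, K, min(S0, K), 0)
    return(structure(list(params = params, curve = curve, rate_failed = TRUE,
                          diagnostics = list(capacity = cap$diagnostics,
                                             rate = fit_diagnostics())),
                     class = "growth_fit"))
  }
  r <- max(gr$r, 0)
  T_L <- if (r > 0)
    max(0, (logit_density(min(S0, 0.99 * K), K) - gr$diagnostics$intercept) / gr$r)
  else 0
  params <- logistic_params(r, K, min(S0, K), T_L)
  structure(list(params = params, curve = curve, rate_failed = FALSE,
                 diagnostics = list(capacity = cap$diagnostics, rate = gr$diagnostics)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  p <- x$params
  flags <- c(if (x$diagnostics$capacity$no_growth) "no growth",
             if (x$diagnostics$capacity$truncated_plateau) "plateau not reached",
             if (isTRUE(x$diagnostics$rate$widened)) "widened rate window",
             if (isTRUE(x$rate_failed)) "rate fit failed")
  cat(sprintf("Logistic growth fit (%s / %s rep %s):\n",
              x$curve$meta$isolate, x$curve$meta$context,
              as.character(x$curve$meta$replicate)))
  cat(sprintf("  r = %.4g /h, K = %.4g OD600, S0 = %.4g OD600, lag = %.3g h\n",
              p$r, p$K, p$S0, p$T_L))
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  p <- object$params
  c(r = p$r, K = p$K, S0 = p$S0, T_L = p$T_L)
}

#' @export
predict.growth_fit <- function(object, times = object$curve$time, ...) {
  logistic_solution(object$params, times)
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) object$curve$od - fitted(object)

#' @export
summary.growth_fit <- function(object, ...) {
  out <- list(coefficients = coef(object),
              rate_window = c(object$diagnostics$rate$window_start,
                              object$diagnostics$rate$window_end),
              rate_r_squared = object$diagnostics$rate$r_squared,
              n_points = object$diagnostics$rate$n_points,
              flags = list(no_growth = object$diagnostics$capacity$no_growth,
                           truncated_plateau = object$diagnostics$capacity$truncated_plateau,
                           widened = isTRUE(object$diagnostics$rate$widened)),
              rmse = sqrt(mean(residuals(object)^2)))
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Logistic growth fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("rate window: %.2f-%.2f h (%d points, R^2 = %.4f)\n",
              x$rate_window[1], x$rate_window[2], x$n_points,
              x$rate_r_squared))
  cat(sprintf("RMSE vs fitted logistic: %.4g OD600\n", x$rmse))
  flg <- names(Filter(isTRUE, x$flags))
  if (length(flg)) cat("flags:", paste(flg, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.growth_fit <- function(x, log = FALSE, ...) {
  t <- x$curve$time
  graphics::plot(t, x$curve$od, pch = 16, cex = 0.4,
                 log = if (log) "y" else "",
                 xlab = "time (h)", ylab = "OD600",
                 main = sprintf("%s / %s", x$curve$meta$isolate,
                                x$curve$meta$context), ...)
  graphics::lines(t, predict(x), col = "red3", lwd = 2)
  invisible(x)
}

#' Fit every curve of a panel and tabulate the parameters
#'
#' Applies [fit_growth()] to a list of growth curves (or a
#' \code{cfsm_panel}) and returns one row per well with the fitted
#' parameters and quality flags. Wells whose rate fit fails are kept with
#' \code{NA} entries and flagged.
#'
#' @param curves a list of [growth_curve] objects or a \code{cfsm_panel}.
#' @param ... passed to [fit_growth()].
#'
#' @return A data frame with columns \code{isolate}, \code{context},
#'   \code{replicate}, \code{r}, \code{K}, \code{S0}, \code{T_L},
#'   \code{r_squared}, \code{no_growth}, \code{truncated_plateau},
#'   \code{widened}, \code{fit_failed}.
#' @export
fit_growth_table <- function(curves, ...) {
  if (inherits(curves, "cfsm_panel")) curves <- curves$curves
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- lapply(curves, function(cv) {
    fit <- tryCatch(fit_growth(cv, ...), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(isolate = cv$meta$isolate, context = cv$meta$context,
                        replicate = cv$meta$replicate, r = NA_real_,
                        K = NA_real_, S0 = NA_real_, T_L = NA_real_,
                        r_squared = NA_real_, no_growth = FALSE,
                        truncated_plateau = FALSE, widened = FALSE,
                        fit_failed = TRUE, stringsAsFactors = FALSE))
    p <- fit$params
    data.frame(isolate = cv$meta$isolate, context = cv$meta$context,
               replicate = cv$meta$replicate,
               r = if (fit$rate_failed) NA_real_ else p$r,
               K = p$K, S0 = p$S0,
               T_L = if (fit$rate_failed) NA_real_ else p$T_L,
               r_squared = fit$diagnostics$rate$r_squared,
               no_growth = fit$diagnostics$capacity$no_growth,
               truncated_plateau = fit$diagnostics$capacity$truncated_plateau,
               widened = isTRUE(fit$diagnostics$rate$widened),
               fit_failed = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate per-well fits into per-condition CFSM records
#'
#' Averages the per-replicate growth-rate and capacity estimates within
#' each (isolate, context) condition, excluding failed fits. No-growth
#' wells contribute \code{r = 0} and their measured floor-level K, so
#' suppressed conditions remain in the record set.
#'
#' @param table a per-well parameter table from [fit_growth_table()].
#'
#' @return A data frame with columns \code{focal}, \code{context},
#'   \code{r}, \code{K}, \code{n} (replicates used), \code{suppressed}.
#' @export
cfsm_records <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("isolate", "context", "r", "K") %in% names(table)))
  ok <- !table$fit_failed & !is.na(table$K)
  tab <- table[ok, , drop = FALSE]
  if (!nrow(tab)) stop("no usable fits to aggregate")
  key <- interaction(tab$isolate, tab$context, drop = TRUE)
  rows <- lapply(split(tab, key), function(g) {
    data.frame(focal = g$isolate[1], context = g$context[1],
               r = mean(g$r, na.rm = TRUE), K = mean(g$K), n = nrow(g),
               suppressed = all(g$no_growth), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$focal, out$context), , drop = FALSE]
}
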