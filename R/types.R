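#' Baseline logistic growth parameters of an isolate
#'
#' Container for the per-isolate kinetic parameters used throughout the
#' package: exponential growth rate \code{r} (per hour), carrying capacity
#' \code{K} (OD600), initial density \code{S0} (OD600) and lag time
#' \code{T_L} (hours). Growth is assumed logistic after the lag, with the
#' density held at \code{S0} for \code{t < T_L}.
#'
#' @param r growth rate, per hour (>= 0).
#' @param K carrying capacity, OD600 (> 0).
#' @param S0 initial density, OD600 (0 < S0 <= K).
#' @param T_L lag time, hours (>= 0).
#'
#' @return An object of class \code{"logistic_params"}.
#' @examples
#' logistic_params(r = 1.85, K = 0.61, S0 = 0.005, T_L = 2.35)
#' @export
logistic_params <- function(r, K, S0, T_L = 0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(S0), length(S0) == 1L, is.finite(S0),
            is.numeric(T_L), length(T_L) == 1L, is.finite(T_L))
  if (r < 0) stop("growth rate 'r' must be >= 0")
  if (K <= 0) stop("carrying capacity 'K' must be > 0")
  if (S0 <= 0 || S0 > K) stop("'S0' must satisfy 0 < S0 <= K")
  if (T_L < 0) stop("lag time 'T_L' must be >= 0")
  structure(list(r = r, K = K, S0 = S0, T_L = T_L),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf(
    "Logistic growth parameters: r = %.4g /h, K = %.4g OD600, S0 = %.4g OD600, lag = %.4g h\n",
    x$r, x$K, x$S0, x$T_L))
  invisible(x)
}

#' A single well's growth curve
#'
#' One plate-reader time series: strictly increasing time (hours), OD600
#' readings, an optional fluorescence channel, and well metadata (isolate,
#' growth context, replicate). The context records the environment the well
#' was grown in: \code{"fresh"} for plain medium or the donor isolate id for
#' a cell-free spent medium (CFSM).
#'
#' @param time time in hours, strictly increasing, length >= 3.
#' @param od OD600 readings, same length as \code{time}, finite and >= 0.
#' @param fluorescence optional fluorescence channel (arbitrary units).
#' @param isolate,context,replicate well metadata.
#'
#' @return An object of class \code{"growth_curve"}.
#' @export
growth_curve <- function(time, od, fluorescence = NULL,
                         isolate = NA_character_, context = "fresh",
                         replicate = 1L) {
  time <- as.numeric(time); od <- as.numeric(od)
  n <- length(time)
  if (n < 3L || length(od) != n)
    stop("'time' and 'od' must have equal length >= 3")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("'time' must be finite and strictly increasing")
  if (any(!is.finite(od)) || any(od < 0))
    stop("'od' must be finite and >= 0")
  if (!is.null(fluorescence)) {
    fluorescence <- as.numeric(fluorescence)
    if (length(fluorescence) != n)
      stop("'fluorescence' must match the length of 'time'")
  }
  structure(list(time = time, od = od, fluorescence = fluorescence,
                 meta = list(isolate = as.character(isolate),
                             context = as.character(context),
                             replicate = replicate)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "Growth curve: isolate %s in %s (rep %s), %d readings over %.1f h%s\n",
    m$isolate, if (identical(m$context, "fresh")) "fresh medium"
               else paste0("CFSM of ", m$context),
    as.character(m$replicate), length(x$time), max(x$time) - min(x$time),
    if (is.null(x$fluorescence)) "" else ", with fluorescence channel"))
  invisible(x)
}

#' @export
as.data.frame.growth_curve <- function(x, ...) {
  data.frame(time_h = x$time,
             isolate = x$meta$isolate,
             context = x$meta$context,
             replicate = x$meta$replicate,
             od600 = x$od,
             gfp = if (is.null(x$fluorescence)) NA_real_ else x$fluorescence,
             stringsAsFactors = FALSE)
}

#' Plate-reader measurement noise model
#'
#' Observation model applied by the synthetic-data generators: the true
#' density is perturbed by multiplicative lognormal noise (pipetting and
#' well-to-well variation), then additive Gaussian read noise and a constant
#' blank offset are added, and the result is clamped at the instrument's
#' detection floor.
#'
#' @param multiplicative_sd sd of the lognormal factor (dimensionless).
#' @param additive_sd sd of additive read noise, OD600 units.
#' @param blank_offset constant blank offset, OD600 units.
#' @param detection_floor smallest reportable OD600 (> 0 recommended for
#'   log-scale fitting).
#'
#' @return An object of class \code{"noise_model"}.
#' @examples
#' noise_model()                      # package defaults
#' noise_model(0, 0, 0, 0)           # noise-free observation
#' @export
noise_model <- function(multiplicative_sd = 0.02, additive_sd = 0.003,
                        blank_offset = 0, detection_floor = 0.001) {
  vals <- c(multiplicative_sd, additive_sd, blank_offset, detection_floor)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise model fields must be finite and >= 0")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd,
                 blank_offset = blank_offset,
                 detection_floor = detection_floor),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Plate-reader noise model: mult sd %.3g, add sd %.3g OD, blank %.3g OD, floor %.3g OD\n",
    x$multiplicative_sd, x$additive_sd, x$blank_offset, x$detection_floor))
  invisible(x)
}

#' A CFSM conditioned-growth record
#'
#' The kinetic summary of one spent-medium assay: growth rate \code{r} and
#' carrying capacity \code{K} of a focal isolate grown in the cell-free
#' spent medium of a context isolate. When the predicted or measured
#' capacity is not positive the record is flagged as growth-suppressed.
#'
#' @param r growth rate in the CFSM, per hour (>= 0).
#' @param K carrying capacity in the CFSM, OD600 (>= 0).
#' @param focal,context isolate identifiers.
#' @param suppressed logical flag; growth suppressed to the detection floor.
#'
#' @return An object of class \code{"cfsm_record"}.
#' @export
cfsm_record <- function(r, K, focal = NA_character_, context = NA_character_,
                        suppressed = FALSE) {
  stopifnot(is.numeric(r), is.numeric(K), length(r) == 1L, length(K) == 1L)
  if (!suppressed && (r < 0 || K < 0))
    stop("'r' and 'K' must be >= 0 in a CFSM record")
  structure(list(focal = as.character(focal), context = as.character(context),
                 r = r, K = K, suppressed = isTRUE(suppressed)),
            class = "cfsm_record")
}

#' @export
print.cfsm_record <- function(x, ...) {
  cat(sprintf("CFSM record: %s in CFSM of %s: r = %.4g /h, K = %.4g OD600%s\n",
              x$focal, x$context, x$r, x$K,
              if (x$suppressed) " [growth suppressed]" else ""))
  invisible(x)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
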