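# Synthetic plate-reader data: monoculture curves, CFSM panels and
# two-species coculture traces with the observation model of noise_model().

# Apply the plate-reader observation model to a vector of true densities.
observe_od <- function(true, noise) {
  n <- length(true)
  obs <- true
  if (noise$multiplicative_sd > 0)
    obs <- obs * exp(stats::rnorm(n, 0, noise$multiplicative_sd))
  if (noise$additive_sd > 0)
    obs <- obs + stats::rnorm(n, 0, noise$additive_sd)
  pmax(obs + noise$blank_offset, noise$detection_floor)
}

#' Simulate a monoculture growth curve
#'
#' Generates one well's time series from the lagged logistic model
#' ([logistic_solution()]) observed through a plate-reader [noise_model]:
#' multiplicative lognormal noise, additive read noise, a constant blank
#' offset, and clamping at the detection floor. Sampling every 10 minutes
#' for 48 h mirrors the standard monoculture assay.
#'
#' @param params a [logistic_params] with \code{r > 0}.
#' @param noise a [noise_model]; use \code{noise_model(0, 0, 0, 0)} for a
#'   noise-free curve.
#' @param sampling_interval sampling interval in hours (default 10 min).
#' @param duration assay duration in hours; must cover the lag.
#' @param seed RNG seed; identical seeds give identical curves.
#' @param isolate,context,replicate metadata for the generated well.
#'
#' @return A [growth_curve].
#' @examples
#' p <- logistic_params(1.85, 0.61, 0.005, T_L = 2)
#' curve <- simulate_monoculture_curve(p, seed = 1)
#' @export
simulate_monoculture_curve <- function(params, noise = noise_model(),
                                       sampling_interval = 1/6, duration = 48,
                                       seed = NULL, isolate = NA_character_,
                                       context = "fresh", replicate = 1L) {
  stopifnot(inherits(params, "logistic_params"), inherits(noise, "noise_model"))
  if (params$r <= 0) stop("'r' must be > 0 to simulate growth")
  if (sampling_interval <= 0) stop("'sampling_interval' must be > 0")
  if (duration < sampling_interval) stop("'duration' must cover at least one interval")
  if (duration < params$T_L) stop("'duration' must be >= the lag time")
  time <- seq(0, duration, by = sampling_interval)
  true <- logistic_solution(params, time)
  od <- with_preserved_seed(seed, observe_od(true, noise))
  growth_curve(time, od, isolate = isolate, context = context,
               replicate = replicate)
}

#' Specification of a synthetic CFSM assay panel
#'
#' Describes a full spent-medium experiment: a set of isolates with
#' baseline kinetics, the interaction matrix \code{c[i, j]} generating
#' their conditioned-growth parameters, and the assay layout (sampling,
#' duration, replicates). \code{violation_mode} selects the generative
#' regime: \code{"none"} produces exactly LV-consistent panels
#' (\eqn{K_{ij} = K_i + c_{ij} K_j}, \eqn{r_{ij} = r_i K_{ij}/K_i});
#' \code{"rate_yield_tradeoff"} makes growth rate anticorrelated with
#' capacity (\eqn{r_{ij} = r_i (1 + \beta (1 - K_{ij}/K_i))}); and
#' \code{"shuffled_K"} permutes the capacities across contexts within each
#' focal isolate, destroying the r-K pairing while preserving the marginal
#' distributions.
#'
#' @param isolates named list of [logistic_params].
#' @param interactions square matrix of interaction coefficients
#'   \code{c[i, j]}; diagonal = response to the isolate's own spent medium.
#' @param violation_mode one of \code{"none"}, \code{"rate_yield_tradeoff"},
#'   \code{"shuffled_K"}.
#' @param sampling_interval hours between readings (> 0).
#' @param duration assay length in hours (>= sampling_interval).
#' @param replicates wells per isolate-context combination (>= 1).
#' @param seed integer seed controlling noise and any permutation.
#' @param tradeoff_strength \eqn{\beta} of the rate-yield-tradeoff regime.
#'
#' @return An object of class \code{"panel_spec"}.
#' @seealso [generate_cfsm_panel()], [example_panel_spec()]
#' @export
panel_spec <- function(isolates, interactions,
                       violation_mode = c("none", "rate_yield_tradeoff",
                                          "shuffled_K"),
                       sampling_interval = 1/6, duration = 48,
                       replicates = 4L, seed = 1L, tradeoff_strength = 1) {
  violation_mode <- match.arg(violation_mode)
  stopifnot(is.list(isolates), length(isolates) >= 1L)
  lapply(isolates, function(p)
    if (!inherits(p, "logistic_params")) stop("each isolate must be a 'logistic_params'"))
  interactions <- as.matrix(interactions)
  n <- length(isolates)
  if (nrow(interactions) != n || ncol(interactions) != n)
    stop("'interactions' must be square with side = number of isolates")
  if (sampling_interval <= 0) stop("'sampling_interval' must be > 0")
  if (duration < sampling_interval) stop("'duration' must be >= 'sampling_interval'")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  nms <- names(isolates)
  if (is.null(nms)) nms <- paste0("isolate", seq_len(n))
  names(isolates) <- nms
  dimnames(interactions) <- list(nms, nms)
  structure(list(isolates = isolates, interactions = interactions,
                 violation_mode = violation_mode,
                 sampling_interval = sampling_interval, duration = duration,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 tradeoff_strength = tradeoff_strength),
            class = "panel_spec")
}

#' Default synthetic community for validation studies
#'
#' Draws a reproducible panel of isolates with kinetics in the range
#' typical of nasal bacteria grown in dilute rich medium (r in 0.8-2 /h,
#' K in 0.2-0.6 OD600, lag 1.5-2.5 h, inoculum 0.005 OD600) and a mostly
#' inhibitory interaction matrix (off-diagonal c in [-0.9, 0.3], self-spent
#' medium strongly depleted, c clipped so every conditioned capacity stays
#' above 0.02 OD600).
#'
#' @param n_isolates number of community members.
#' @param seed integer seed; fixes both the drawn parameters and the panel
#'   noise stream.
#' @param ... further arguments passed to [panel_spec()] (e.g.
#'   \code{violation_mode}, \code{replicates}).
#'
#' @return A [panel_spec].
#' @examples
#' spec <- example_panel_spec(n_isolates = 3, seed = 7)
#' @export
example_panel_spec <- function(n_isolates = 6L, seed = 1L, ...) {
  stopifnot(n_isolates >= 2L)
  with_preserved_seed(seed, {
    r <- stats::runif(n_isolates, 0.8, 2.0)
    K <- stats::runif(n_isolates, 0.2, 0.6)
    lag <- stats::runif(n_isolates, 1.5, 2.5)
    isolates <- lapply(seq_len(n_isolates), function(i)
      logistic_params(r[i], K[i], 0.005, lag[i]))
    names(isolates) <- paste0("isolate", seq_len(n_isolates))
    cmat <- matrix(stats::runif(n_isolates^2, -0.9, 0.3), n_isolates)
    diag(cmat) <- stats::runif(n_isolates, -0.9, -0.4)
    # keep every conditioned capacity measurable (>= 0.02 OD600)
    for (i in seq_len(n_isolates))
      cmat[i, ] <- pmax(cmat[i, ], (0.02 - K[i]) / K)
    panel_spec(isolates, cmat, seed = seed, ...)
  })
}

# True (r_ij, K_ij) for every focal/context pair of a panel, per regime.
panel_truth <- function(spec, floor) {
  nms <- names(spec$isolates)
  n <- length(nms)
  r0 <- vapply(spec$isolates, `[[`, numeric(1), "r")
  K0 <- vapply(spec$isolates, `[[`, numeric(1), "K")
  rows <- list()
  for (i in seq_len(n)) {
    K_ij <- K0[i] + spec$interactions[i, ] * K0
    suppressed <- K_ij <= floor
    K_ij <- pmax(K_ij, floor)
    r_ij <- switch(spec$violation_mode,
      none = ,
      shuffled_K = r0[i] * K_ij / K0[i],
      rate_yield_tradeoff =
        r0[i] * (1 + spec$tradeoff_strength * (1 - K_ij / K0[i])))
    r_ij <- pmax(r_ij, 0)
    r_ij[suppressed] <- 0
    if (spec$violation_mode == "shuffled_K") {
      perm <- sample.int(n)
      K_ij <- K_ij[perm]
      suppressed <- suppressed[perm]
    }
    rows[[i]] <- data.frame(
      focal = nms[i], context = c("fresh", nms),
      r_true = c(r0[i], unname(r_ij)), K_true = c(K0[i], unname(K_ij)),
      suppressed = c(FALSE, unname(suppressed)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic CFSM assay panel
#'
#' Simulates the full spent-medium experiment described by a [panel_spec]:
#' for every focal isolate, one fresh-medium baseline condition plus one
#' condition per CFSM donor (including its own), each with the requested
#' number of replicate wells observed through the [noise_model]. Records
#' whose conditioned capacity falls at or below the detection floor are
#' generated as growth-suppressed wells (flat at the floor) and flagged in
#' the truth table rather than raising an error.
#'
#' @param spec a [panel_spec].
#' @param noise a [noise_model].
#'
#' @return An object of class \code{"cfsm_panel"}: a list with
#'   \code{curves} (list of [growth_curve]), \code{truth} (data frame of
#'   generating parameters per focal/context) and \code{spec}.
#' @examples
#' panel <- generate_cfsm_panel(example_panel_spec(3, seed = 2,
#'                                                 replicates = 2))
#' panel$truth
#' @export
generate_cfsm_panel <- function(spec, noise = noise_model()) {
  stopifnot(inherits(spec, "panel_spec"), inherits(noise, "noise_model"))
  floor <- noise$detection_floor
  with_preserved_seed(spec$seed, {
    truth <- panel_truth(spec, floor)
    time <- seq(0, spec$duration, by = spec$sampling_interval)
    curves <- vector("list", nrow(truth) * spec$replicates)
    k <- 0L
    for (row in seq_len(nrow(truth))) {
      tr <- truth[row, ]
      p0 <- spec$isolates[[tr$focal]]
      if (tr$suppressed || tr$K_true <= floor || tr$r_true <= 0) {
        true <- rep(max(floor, min(p0$S0, tr$K_true)), length(time))
      } else {
        S0 <- min(p0$S0, tr$K_true)  # inoculum cannot exceed capacity
        pp <- logistic_params(tr$r_true, tr$K_true, S0, p0$T_L)
        true <- logistic_solution(pp, time)
      }
      for (rep in seq_len(spec$replicates)) {
        k <- k + 1L
        curves[[k]] <- growth_curve(time, observe_od(true, noise),
                                    isolate = tr$focal, context = tr$context,
                                    replicate = rep)
      }
    }
    structure(list(curves = curves, truth = truth, spec = spec),
              class = "cfsm_panel")
  })
}

#' @export
print.cfsm_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic CFSM panel: %d isolates x %d contexts x %d replicates (%d wells), regime '%s'\n",
    length(x$spec$isolates), length(x$spec$isolates) + 1L,
    x$spec$replicates, length(x$curves), x$spec$violation_mode))
  invisible(x)
}

#' A two-species coculture observation
#'
#' One coculture well as the plate reader sees it: a total-OD600 channel
#' (both species together) and a fluorescence channel tied to species 1 via
#' the GFP calibration. Species-resolved channels \code{od1}/\code{od2} are
#' filled in by [deconvolve_coculture()].
#'
#' @param time time in hours, strictly increasing.
#' @param total_od total OD600 channel.
#' @param fluorescence fluorescence channel (species 1 reporter).
#' @param meta list of metadata (pair ids, initial ratio, replicate).
#' @param truth optional list with true per-species densities \code{S1},
#'   \code{S2} (kept by the simulator for recovery studies).
#'
#' @return An object of class \code{"coculture_trace"}.
#' @export
coculture_trace <- function(time, total_od, fluorescence, meta = list(),
                            truth = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 3L || any(diff(time) <= 0))
    stop("'time' must be strictly increasing with length >= 3")
  if (length(total_od) != n || length(fluorescence) != n)
    stop("channel lengths must match 'time'")
  structure(list(time = time, total_od = as.numeric(total_od),
                 fluorescence = as.numeric(fluorescence),
                 od1 = NULL, od2 = NULL, flags = NULL,
                 meta = meta, truth = truth),
            class = "coculture_trace")
}

#' @export
print.coculture_trace <- function(x, ...) {
  cat(sprintf("Coculture trace: %d readings over %.1f h%s%s\n",
              length(x$time), max(x$time) - min(x$time),
              if (!is.null(x$meta$ratio)) paste0(", ratio ", x$meta$ratio) else "",
              if (is.null(x$od1)) "" else ", deconvolved"))
  invisible(x)
}

# Non-LV reference dynamics for adequacy demonstrations: logistic growth
# inhibited by a saturating (Monod-like) function of the partner density,
#   dSi/dt = ri Si (1 - Si/Ki) / (1 + Sj/h).
# Unlike LV, the partner's effect saturates, so an LV fit to these dynamics
# depends on the inoculation ratio.
simulate_saturating <- function(system, init, times, h = 0.05) {
  r <- vapply(system$isolates, `[[`, numeric(1), "r")
  K <- vapply(system$isolates, `[[`, numeric(1), "K")
  lag <- vapply(system$isolates, `[[`, numeric(1), "T_L")
  rhs <- function(t, S, parms) {
    S <- pmax(S, 0)
    active <- as.numeric(t >= lag - 1e-12)
    partner <- rev(S)
    list(active * r * S * (1 - S / K) / (1 + partner / h))
  }
  breaks <- sort(unique(lag[lag > times[1] & lag < max(times)]))
  bounds <- c(times[1], breaks, max(times))
  y <- init
  out <- matrix(NA_real_, length(times), 2L)
  out[1, ] <- y
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- unique(c(bounds[s], times[times > bounds[s] & times < bounds[s + 1L]],
                    bounds[s + 1L]))
    sol <- deSolve::ode(y, seg, rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    keep <- sol[, 1] %in% times
    out[match(sol[keep, 1], times), ] <- pmax(sol[keep, -1, drop = FALSE], 0)
  }
  out
}

#' Simulate a two-species coculture trace
#'
#' Integrates the two-species dynamics and emits the channels a plate
#' reader would record: total OD600 (sum of both species, observed through
#' the [noise_model]) and a fluorescence channel obtained by inverting the
#' [gfp_calibration] on the (noisy) species-1 density. Noise-free channels
#' satisfy \code{gfp_to_od(F) + S2 == total} exactly, except at time points
#' whose species-1 OD falls in the calibration's unreachable gap (flagged
#' in \code{truth$gap}).
#'
#' \code{dynamics = "saturating"} substitutes a non-LV generative process
#' (logistic growth inhibited by a saturating function of the partner
#' density) used to demonstrate how LV fits misbehave when the true
#' dynamics are not LV.
#'
#' @param system a two-isolate [lv_system].
#' @param init initial densities (OD600); defaults to the isolates'
#'   \code{S0}. Zero entries allowed.
#' @param calibration a [gfp_calibration] for the species-1 reporter.
#' @param noise a [noise_model].
#' @param sampling_interval,duration assay layout in hours (defaults:
#'   10-min sampling over 24 h).
#' @param seed RNG seed; identical seeds give identical traces.
#' @param dynamics generative model, \code{"lv"} or \code{"saturating"}.
#' @param saturation_od half-saturation partner density (OD600) of the
#'   saturating regime.
#' @param ratio,replicate metadata stored on the trace.
#'
#' @return A [coculture_trace] with the generating truth attached.
#' @examples
#' tr <- simulate_coculture_trace(staph_pair_system(),
#'                                noise = noise_model(0, 0, 0, 0))
#' @export
simulate_coculture_trace <- function(system, init = NULL,
                                     calibration = gfp_calibration(),
                                     noise = noise_model(),
                                     sampling_interval = 1/6, duration = 24,
                                     seed = NULL,
                                     dynamics = c("lv", "saturating"),
                                     saturation_od = 0.05,
                                     ratio = NA_character_, replicate = 1L) {
  stopifnot(inherits(system, "lv_system"), inherits(noise, "noise_model"))
  dynamics <- match.arg(dynamics)
  if (length(system$isolates) != 2L)
    stop("coculture simulation requires a two-isolate system")
  if (sampling_interval <= 0 || duration < sampling_interval)
    stop("invalid sampling layout")
  if (is.null(init)) init <- vapply(system$isolates, `[[`, numeric(1), "S0")
  if (any(init < 0)) stop("initial densities must be >= 0")
  times <- seq(0, duration, by = sampling_interval)
  S <- if (dynamics == "lv") {
    traj <- simulate_lv(system, init = init, times = times)
    as.matrix(traj[, -1])
  } else {
    simulate_saturating(system, init, times, h = saturation_od)
  }
  S1 <- unname(S[, 1]); S2 <- unname(S[, 2])
  with_preserved_seed(seed, {
    n <- length(times)
    od1_obs <- S1
    if (noise$multiplicative_sd > 0)
      od1_obs <- od1_obs * exp(stats::rnorm(n, 0, noise$multiplicative_sd))
    if (noise$additive_sd > 0)
      od1_obs <- pmax(od1_obs + stats::rnorm(n, 0, noise$additive_sd), 0)
    F <- invert_gfp_calibration(od1_obs, calibration, extrapolate = TRUE)
    total <- observe_od(S1 + S2, noise)
    coculture_trace(times, total, as.numeric(F),
                    meta = list(pair = system$names, ratio = ratio,
                                replicate = replicate, dynamics = dynamics),
                    truth = list(S1 = S1, S2 = S2, init = init,
                                 gap = attr(F, "gap")))
  })
}
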