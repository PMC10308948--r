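#' Closed-form logistic growth with lag
#'
#' Evaluates the lagged logistic solution
#' \deqn{S(t) = K / (1 + (K/S_0 - 1) e^{-r (t - T_L)})}{
#'       S(t) = K / (1 + (K/S0 - 1) exp(-r (t - T_L)))}
#' for \code{t >= T_L}, and \code{S0} for \code{t < T_L}. This is the
#' monoculture model underlying all growth-curve fitting in the package.
#'
#' @param params a [logistic_params] object.
#' @param t time(s) in hours, >= 0; vectorized.
#'
#' @return Numeric vector of densities (OD600).
#' @examples
#' p <- logistic_params(r = 1.85, K = 0.61, S0 = 0.005)
#' logistic_solution(p, 2)   # 0.15283
#' @export
logistic_solution <- function(params, t) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  tt <- pmax(t - params$T_L, 0)
  # numerically stable form: no overflow for large r * t
  params$K / (1 + (params$K / params$S0 - 1) * exp(-params$r * tt))
}

#' A Lotka-Volterra interaction system
#'
#' Bundles per-isolate baseline kinetics with a square matrix of
#' dimensionless interaction coefficients \code{c[i, j]} (effect of isolate
#' \code{j} on isolate \code{i}; negative = inhibition, positive =
#' facilitation). The diagonal is stored (it is the self-spent-medium
#' record) but excluded from the dynamics: self-limitation already lives in
#' each \code{K_i}.
#'
#' The coupled dynamics are
#' \deqn{dS_i/dt = r_i S_i (1 - (S_i - \sum_{j \ne i} c_{ij} S_j)/K_i)}
#' with the growth term zeroed for \code{t < T_iL} (lag).
#'
#' @param isolates list of [logistic_params], one per isolate.
#' @param c square numeric matrix of interaction coefficients, side equal to
#'   the number of isolates.
#' @param names optional isolate names (defaults to names of
#'   \code{isolates}, else \code{"isolate1"}, ...).
#'
#' @return An object of class \code{"lv_system"}.
#' @seealso [simulate_lv()], [interaction_coefficient()],
#'   [staph_pair_system()]
#' @export
lv_system <- function(isolates, c, names = NULL) {
  stopifnot(is.list(isolates), length(isolates) >= 1L)
  lapply(isolates, function(p)
    if (!inherits(p, "logistic_params")) stop("each isolate must be a 'logistic_params'"))
  c <- as.matrix(c)
  n <- length(isolates)
  if (nrow(c) != n || ncol(c) != n)
    stop("interaction matrix 'c' must be square with side = number of isolates")
  if (any(!is.finite(c))) stop("interaction coefficients must be finite")
  if (is.null(names)) names <- base::names(isolates)
  if (is.null(names)) names <- paste0("isolate", seq_len(n))
  base::names(isolates) <- names
  dimnames(c) <- list(names, names)
  structure(list(isolates = isolates, c = c, names = names),
            class = "lv_system")
}

#' @export
print.lv_system <- function(x, ...) {
  n <- length(x$isolates)
  cat(sprintf("Lotka-Volterra system with %d isolate%s\n", n,
              if (n == 1L) "" else "s"))
  pars <- t(vapply(x$isolates, function(p) c(r = p$r, K = p$K, S0 = p$S0,
                                             lag_h = p$T_L), numeric(4)))
  print(round(pars, 4))
  cat("Interaction coefficients c[i, j] (effect of j on i):\n")
  print(round(x$c, 4))
  invisible(x)
}

#' @export
coef.lv_system <- function(object, ...) object$c

# interaction matrix with diagonal removed, as used by the dynamics
off_diagonal <- function(c) { diag(c) <- 0; c }

#' Simulate Lotka-Volterra coculture dynamics
#'
#' Integrates the coupled LV equations of an [lv_system] with an adaptive
#' Runge-Kutta/Adams solver (deSolve's \code{lsoda}, rtol 1e-8, atol 1e-10).
#' Each isolate's growth term is zero before its lag time; the integration
#' is split at the lag breakpoints so the discontinuities do not degrade
#' solver accuracy. Densities are clamped at zero on output.
#'
#' @param system an [lv_system].
#' @param init initial densities (OD600), one per isolate; defaults to the
#'   isolates' \code{S0}. Zero entries are allowed (absent species).
#' @param times increasing time grid in hours starting at >= 0.
#' @param rtol,atol solver tolerances.
#'
#' @return A data frame with column \code{time} and one density column per
#'   isolate.
#' @examples
#' sys <- staph_pair_system()
#' traj <- simulate_lv(sys, times = seq(0, 24, by = 1/6))
#' tail(traj, 1)
#' @export
simulate_lv <- function(system, init = NULL, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "lv_system"))
  n <- length(system$isolates)
  if (is.null(init)) init <- vapply(system$isolates, `[[`, numeric(1), "S0")
  init <- as.numeric(init)
  if (length(init) != n) stop("'init' must have one density per isolate")
  if (any(!is.finite(init)) || any(init < 0))
    stop("initial densities must be finite and >= 0")
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] < 0)
    stop("'times' must be increasing and start at >= 0")

  r <- vapply(system$isolates, `[[`, numeric(1), "r")
  K <- vapply(system$isolates, `[[`, numeric(1), "K")
  lag <- vapply(system$isolates, `[[`, numeric(1), "T_L")
  C0 <- off_diagonal(system$c)

  rhs <- function(t, S, parms) {
    S <- pmax(S, 0)
    active <- as.numeric(t >= parms$lag - 1e-12)
    dS <- active * parms$r * S * (1 - (S - drop(parms$C0 %*% S)) / parms$K)
    list(dS)
  }
  parms <- list(r = r, K = K, lag = lag, C0 = C0)

  t0 <- times[1]
  grid <- if (t0 > 0) c(0, times) else times
  breaks <- sort(unique(lag[lag > grid[1] & lag < max(grid)]))
  seg_bounds <- c(grid[1], breaks, max(grid))
  y <- init
  out <- matrix(NA_real_, nrow = length(grid), ncol = n)
  out[1, ] <- y
  for (s in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[s]; b <- seg_bounds[s + 1L]
    inner <- grid[grid > a & grid < b]
    seg_times <- unique(c(a, inner, b))
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs, parms = parms,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("LV integration failed on [%.3g, %.3g] h (r = %s, K = %s)",
                   a, b, paste(signif(r, 4), collapse = ", "),
                   paste(signif(K, 4), collapse = ", ")))
    y <- pmax(as.numeric(sol[nrow(sol), -1, drop = FALSE]), 0)
    keep <- sol[, 1] %in% grid
    out[match(sol[keep, 1], grid), ] <- pmax(sol[keep, -1, drop = FALSE], 0)
  }
  res <- data.frame(time = grid, out)
  base::names(res) <- c("time", system$names)
  res[res$time %in% times, , drop = FALSE]
}

#' @describeIn lv_system \code{simulate()} method: deterministic
#'   trajectories, optionally replicated with plate-reader observation
#'   noise applied to each density channel.
#' @param object an [lv_system].
#' @param nsim number of replicate simulations (only meaningful with noise).
#' @param seed RNG seed for the observation noise.
#' @param times time grid (hours); default 10-min sampling over 24 h.
#' @param init initial densities.
#' @param noise optional [noise_model] applied to the density channels.
#' @param ... unused.
#' @export
simulate.lv_system <- function(object, nsim = 1, seed = NULL,
                               times = seq(0, 24, by = 1/6), init = NULL,
                               noise = NULL, ...) {
  traj <- simulate_lv(object, init = init, times = times)
  if (is.null(noise)) return(traj)
  stopifnot(inherits(noise, "noise_model"))
  with_preserved_seed(seed, {
    reps <- lapply(seq_len(nsim), function(i) {
      obs <- traj
      for (nm in object$names)
        obs[[nm]] <- observe_od(traj[[nm]], noise)
      obs
    })
    if (nsim == 1L) reps[[1L]] else reps
  })
}

#' Interaction coefficient from spent-medium carrying capacities
#'
#' The dimensionless effect of isolate \code{j} on isolate \code{i},
#' estimated from CFSM assays as
#' \deqn{c_{ij} = (K_{ij} - K_i) / K_j}
#' where \code{K_ij} is the capacity of \code{i} in the spent medium of
#' \code{j} and \code{K_i}, \code{K_j} are the fresh-medium capacities.
#' Negative values indicate inhibition, positive facilitation.
#'
#' @param K_ij capacity of the focal isolate in the partner's CFSM (OD600).
#' @param K_i fresh-medium capacity of the focal isolate (OD600).
#' @param K_j fresh-medium capacity of the CFSM donor (OD600, > 0).
#'
#' @return Dimensionless interaction coefficient(s); vectorized.
#' @examples
#' interaction_coefficient(0.17, 0.61, 0.35)  # -1.26
#' interaction_coefficient(0.03, 0.35, 0.61)  # -0.52
#' @export
interaction_coefficient <- function(K_ij, K_i, K_j) {
  if (any(!is.finite(K_j)) || any(K_j <= 0))
    stop("donor capacity 'K_j' must be > 0")
  (K_ij - K_i) / K_j
}

#' Classical LV rate coefficient
#'
#' Converts a dimensionless interaction coefficient into the classical
#' Lotka-Volterra rate coefficient \eqn{a_{ij} = c_{ij} r_i / K_i}
#' (per hour per OD600).
#'
#' @param c_ij dimensionless interaction coefficient.
#' @param r_i focal growth rate (per hour).
#' @param K_i focal carrying capacity (OD600, > 0).
#'
#' @return \code{a_ij}, per hour per OD600; vectorized.
#' @export
lv_interaction_strength <- function(c_ij, r_i, K_i) {
  if (any(!is.finite(K_i)) || any(K_i <= 0)) stop("'K_i' must be > 0")
  c_ij * r_i / K_i
}

#' Predicted spent-medium growth parameters under LV
#'
#' Under an LV representation, growth of isolate \code{i} in the spent
#' medium of isolate \code{j} is again logistic with
#' \deqn{K_{ij} = K_i + c_{ij} K_j, \qquad r_{ij} = r_i K_{ij} / K_i,}
#' so that \eqn{r_{ij}/K_{ij} = r_i/K_i} identically. This ratio invariance
#' is the basis of the r-K consistency criterion. A non-positive predicted
#' capacity is returned as a growth-suppressed record (K = 0, r = 0) rather
#' than an error.
#'
#' @param params_i baseline [logistic_params] of the focal isolate.
#' @param c_ij dimensionless interaction coefficient (effect of j on i).
#' @param K_j donor fresh-medium capacity (OD600, > 0).
#' @param focal,context optional isolate identifiers for the record.
#'
#' @return A [cfsm_record].
#' @examples
#' p1 <- logistic_params(r = 1.85, K = 0.61, S0 = 0.005)
#' predict_cfsm_params(p1, c_ij = -1.26, K_j = 0.35)  # K = 0.169, r = 0.5125
#' @export
predict_cfsm_params <- function(params_i, c_ij, K_j,
                                focal = NA_character_, context = NA_character_) {
  stopifnot(inherits(params_i, "logistic_params"),
            is.numeric(c_ij), length(c_ij) == 1L,
            is.numeric(K_j), length(K_j) == 1L)
  if (!is.finite(K_j) || K_j <= 0) stop("'K_j' must be > 0")
  K_ij <- params_i$K + c_ij * K_j
  if (K_ij <= 0)
    return(cfsm_record(0, 0, focal = focal, context = context,
                       suppressed = TRUE))
  r_ij <- params_i$r * K_ij / params_i$K
  cfsm_record(r_ij, K_ij, focal = focal, context = context)
}

#' Published parameters of the S. aureus / non-aureus Staphylococcus pair
#'
#' The fully characterized two-isolate parameter set used for coculture
#' validation: \emph{S. aureus} (isolate 1) and the non-aureus
#' \emph{Staphylococcus} sp. KPL1850 (isolate 2) grown in 10% THY medium.
#' \code{staph_pair_params()} returns the printed kinetic quantities;
#' \code{staph_pair_system()} assembles them into an [lv_system], deriving
#' the interaction coefficients from the spent-medium capacities via
#' [interaction_coefficient()].
#'
#' @param initial_ratio inoculation ratio of isolate 1 to isolate 2; one of
#'   \code{"1:1"} (both at 0.005 OD600), \code{"1:10"} (0.0005 vs 0.005) or
#'   \code{"1:100"} (0.00005 vs 0.005).
#'
#' @return \code{staph_pair_params()}: a named list of kinetic parameters.
#'   \code{staph_pair_system()}: an [lv_system] of the pair.
#' @examples
#' staph_pair_system()
#' coef(staph_pair_system())
#' @export
staph_pair_params <- function() {
  list(r1 = 1.85, r2 = 1.56,       # growth rates, 1/h
       K1 = 0.61, K2 = 0.35,       # fresh-medium capacities, OD600
       K12 = 0.17, K21 = 0.03,     # capacities in the partner's CFSM, OD600
       S10 = 0.005, S20 = 0.005,   # inoculum densities at 1:1, OD600
       T1L = 2.35, T2L = 2.25)     # lag times, h
}

#' @rdname staph_pair_params
#' @export
staph_pair_system <- function(initial_ratio = c("1:1", "1:10", "1:100")) {
  initial_ratio <- match.arg(initial_ratio)
  p <- staph_pair_params()
  S10 <- switch(initial_ratio, "1:1" = 0.005, "1:10" = 0.0005,
                "1:100" = 0.00005)
  c12 <- interaction_coefficient(p$K12, p$K1, p$K2)
  c21 <- interaction_coefficient(p$K21, p$K2, p$K1)
  lv_system(
    isolates = list(
      S_aureus = logistic_params(p$r1, p$K1, S10, p$T1L),
      Staph_KPL1850 = logistic_params(p$r2, p$K2, p$S20, p$T2L)),
    c = matrix(c(0, c12, c21, 0), nrow = 2, byrow = TRUE))
}
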