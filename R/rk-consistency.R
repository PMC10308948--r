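# The r-K linear-consistency criterion: per-isolate regression of growth
# rate on carrying capacity across spent-medium contexts, the LV adequacy
# verdict, habitat quality, and the combined-CFSM additivity test.

#' Regress growth rate on carrying capacity across CFSM contexts
#'
#' For one focal isolate, ordinary least squares of the conditioned growth
#' rate \code{r_ij} (response) on the conditioned carrying capacity
#' \code{K_ij} (predictor) across spent-medium contexts, matching the
#' orientation in which the LV prediction makes \code{r_i/K_i} the slope.
#' Requires at least 3 records with non-degenerate K spread.
#'
#' @param records a data frame with numeric columns \code{r} and \code{K}
#'   (one row per context; e.g. from [cfsm_records()]), or a list of
#'   [cfsm_record] objects.
#' @param focal optional focal isolate id; if \code{records} has a
#'   \code{focal} column the rows are filtered to it.
#'
#' @return An object of class \code{"rk_regression"}: slope, intercept,
#'   R-squared, slope p-value (two-sided t test, equivalent to the F test
#'   for a single predictor), number of points, and the underlying
#'   \code{lm} fit. Supports \code{coef}, \code{summary}, \code{plot},
#'   \code{predict}.
#' @examples
#' recs <- data.frame(K = c(0.1, 0.3, 0.5, 0.6),
#'                    r = 3 * c(0.1, 0.3, 0.5, 0.6))
#' fit_rk_regression(recs)  # slope 3, R^2 = 1
#' @export
fit_rk_regression <- function(records, focal = NULL) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "cfsm_record"))) {
    records <- do.call(rbind, lapply(records, function(x)
      data.frame(focal = x$focal, context = x$context, r = x$r, K = x$K,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(records), all(c("r", "K") %in% names(records)))
  if (!is.null(focal) && "focal" %in% names(records))
    records <- records[records$focal == focal, , drop = FALSE]
  else if (is.null(focal) && "focal" %in% names(records)) {
    focal <- unique(records$focal)
    if (length(focal) > 1L)
      stop("records span multiple focal isolates; supply 'focal'")
  }
  records <- records[is.finite(records$r) & is.finite(records$K), , drop = FALSE]
  n <- nrow(records)
  if (n < 3L)
    stop("at least 3 CFSM records are required for the r-K regression")
  if (length(unique(records$K)) < 2L || stats::var(records$K) == 0)
    stop("CFSM records have no carrying-capacity spread; regression undefined")
  fit <- stats::lm(r ~ K, data = records)
  # collinear synthetic panels are legitimate input; silence the
  # "essentially perfect fit" note summary.lm emits for them
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  p_value <- sm$coefficients["K", "Pr(>|t|)"]
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(p_value), n = n,
                 focal = if (is.null(focal)) NA_character_ else as.character(focal),
                 lm = fit, records = records),
            class = "rk_regression")
}

#' @export
print.rk_regression <- function(x, ...) {
  cat(sprintf("r-K regression%s: r = %.4g %+.4g * K  (n = %d)\n",
              if (is.na(x$focal)) "" else paste0(" for ", x$focal),
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4f, slope p-value = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @export
coef.rk_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.rk_regression <- function(object, ...) summary(object$lm, ...)

#' @export
predict.rk_regression <- function(object, K, ...) {
  object$intercept + object$slope * K
}

#' @export
plot.rk_regression <- function(x, ...) {
  graphics::plot(x$records$K, x$records$r, pch = 16,
                 xlab = "carrying capacity K (OD600)",
                 ylab = "growth rate r (1/h)",
                 main = if (is.na(x$focal)) "r-K regression" else x$focal, ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' LV-consistency verdict from the r-K regression
#'
#' Under an LV representation, a focal isolate's conditioned (r, K) pairs
#' across spent-medium contexts fall on a line through the origin with
#' slope \code{r_i/K_i}. The verdict requires three clauses: the slope is
#' statistically significant (p below \code{alpha}), positive, and within
#' \code{slope_tolerance} (relative) of the baseline ratio \code{r_i/K_i}.
#' A failed verdict lists the violated clauses; a negative or mismatched
#' slope indicates that an LV model is inappropriate for the system (a
#' passing verdict is necessary but not sufficient for LV adequacy).
#'
#' @param result an [fit_rk_regression()] result.
#' @param baseline the focal isolate's fresh-medium [logistic_params] (or a
#'   list with elements \code{r} and \code{K}).
#' @param alpha significance level for the slope test.
#' @param slope_tolerance allowed relative deviation of the slope from
#'   \code{r_i/K_i}.
#'
#' @return An object of class \code{"lv_verdict"}: \code{lv_consistent},
#'   the individual clause flags, a 95% slope confidence interval, the
#'   baseline ratio, and failure reasons.
#' @export
lv_consistency_test <- function(result, baseline, alpha = 0.05,
                                slope_tolerance = 0.25) {
  stopifnot(inherits(result, "rk_regression"))
  if (!is.list(baseline) || is.null(baseline$r) || is.null(baseline$K))
    stop("'baseline' must provide elements 'r' and 'K'")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (slope_tolerance <= 0) stop("'slope_tolerance' must be > 0")
  ratio <- baseline$r / baseline$K
  significant <- result$p_value < alpha
  positive <- result$slope > 0
  matches <- abs(result$slope - ratio) <= slope_tolerance * abs(ratio)
  reasons <- c(
    if (!significant)
      sprintf("slope not significant (p = %.3g >= %.3g)", result$p_value, alpha),
    if (!positive) sprintf("negative slope (%.4g)", result$slope),
    if (!matches)
      sprintf("slope %.4g deviates from baseline r/K = %.4g by more than %.0f%%",
              result$slope, ratio, 100 * slope_tolerance))
  ci <- tryCatch(
    suppressWarnings(stats::confint(result$lm, "K", level = 0.95)[1, ]),
    error = function(e) c(NA_real_, NA_real_))
  structure(list(lv_consistent = significant && positive && matches,
                 significant = significant, positive = positive,
                 slope_matches_baseline = matches,
                 slope = result$slope, slope_ci = unname(ci),
                 baseline_ratio = ratio, p_value = result$p_value,
                 alpha = alpha, slope_tolerance = slope_tolerance,
                 focal = result$focal, reasons = reasons),
            class = "lv_verdict")
}

#' @export
print.lv_verdict <- function(x, ...) {
  cat(sprintf("LV consistency%s: %s\n",
              if (is.na(x$focal)) "" else paste0(" for ", x$focal),
              if (x$lv_consistent) "CONSISTENT with an LV model"
              else "NOT consistent with an LV model"))
  cat(sprintf("  slope %.4g (95%% CI %.4g to %.4g), baseline r/K = %.4g, p = %.3g\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$baseline_ratio,
              x$p_value))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Habitat quality of a spent-medium environment
#'
#' A scalar position along the r-K correlation line summarizing how well an
#' environment supports a focal isolate: \code{q = K_ij / K_i} (equal to
#' \code{r_ij / r_i} under exact LV). \code{q = 1} is a fresh-medium-
#' equivalent habitat, \code{q = 0} supports no growth, and \code{q > 1}
#' indicates facilitation.
#'
#' @param record a [cfsm_record], or the conditioned capacity
#'   \code{K_ij} as a numeric vector.
#' @param baseline the focal isolate's fresh-medium [logistic_params] (or
#'   a list with element \code{K > 0}).
#'
#' @return Dimensionless habitat quality (vectorized over \code{record}
#'   when numeric).
#' @examples
#' habitat_quality(0.17, list(K = 0.61))  # 0.2787
#' @export
habitat_quality <- function(record, baseline) {
  K_ij <- if (inherits(record, "cfsm_record")) record$K else as.numeric(record)
  if (!is.list(baseline) || is.null(baseline$K)) stop("'baseline' must provide 'K'")
  if (baseline$K <= 0) stop("baseline 'K' must be > 0")
  if (any(K_ij < 0)) stop("'K_ij' must be >= 0")
  K_ij / baseline$K
}

#' Additivity test for combined spent media
#'
#' For the LV picture to extend beyond pairs, the growth response to a 1:1
#' mixture of two isolates' spent media should equal the average of the
#' responses to each medium alone. The test compares the mixed-CFSM
#' response replicates against the per-replicate pairwise means of the two
#' single-CFSM responses with a Welch two-sample t test, and declares
#' additivity when the test fails to reject at \code{alpha} \emph{and} the
#' mean difference is within \code{band} (relative) of the pairwise-mean
#' magnitude (a pure hypothesis test would declare everything additive at
#' small n and nothing at large n).
#'
#' @param resp_j,resp_k replicate growth summaries (K or r) in each single
#'   CFSM; equal lengths >= 3 (replicates are paired positionally).
#' @param resp_mixed replicate growth summaries in the 1:1 mixed CFSM
#'   (>= 3).
#' @param alpha significance level of the Welch test.
#' @param band relative effect-size band for the additivity call.
#'
#' @return An object of class \code{"additivity_verdict"}: \code{additive},
#'   the Welch p-value, group means and the relative difference.
#' @export
combined_cfsm_additivity <- function(resp_j, resp_k, resp_mixed,
                                     alpha = 0.05, band = 0.15) {
  if (length(resp_j) != length(resp_k))
    stop("'resp_j' and 'resp_k' must have equal length (paired replicates)")
  if (length(resp_j) < 3L || length(resp_mixed) < 3L)
    stop("at least 3 replicates per group are required")
  if (any(!is.finite(c(resp_j, resp_k, resp_mixed))))
    stop("responses must be finite")
  pairwise <- (resp_j + resp_k) / 2
  test <- stats::t.test(resp_mixed, pairwise, var.equal = FALSE)
  diff_rel <- abs(mean(resp_mixed) - mean(pairwise)) /
    max(abs(mean(pairwise)), .Machine$double.eps)
  structure(list(additive = test$p.value >= alpha && diff_rel <= band,
                 p_value = unname(test$p.value),
                 mean_mixed = mean(resp_mixed),
                 mean_pairwise = mean(pairwise),
                 relative_difference = diff_rel,
                 alpha = alpha, band = band),
            class = "additivity_verdict")
}

#' @export
print.additivity_verdict <- function(x, ...) {
  cat(sprintf("Combined-CFSM additivity: %s\n",
              if (x$additive) "ADDITIVE" else "NOT additive"))
  cat(sprintf("  mixed mean %.4g vs pairwise mean %.4g (%.1f%% apart), Welch p = %.3g\n",
              x$mean_mixed, x$mean_pairwise, 100 * x$relative_difference,
              x$p_value))
  invisible(x)
}
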