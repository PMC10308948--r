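# Plate-reader file handling and the end-to-end analysis pipeline.
# Long-format CSV schema: time_h, well, isolate, context, replicate,
# od600, gfp (empty when absent). Coculture CSV: time_h, pair, ratio,
# replicate, od600 (total), gfp.

#' Write growth curves to a long-format CSV
#'
#' @param curves list of [growth_curve] objects or a \code{cfsm_panel}.
#' @param path output file path.
#'
#' @return The path, invisibly.
#' @export
write_plate_csv <- function(curves, path) {
  if (inherits(curves, "cfsm_panel")) curves <- curves$curves
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- lapply(seq_along(curves), function(i) {
    df <- as.data.frame(curves[[i]])
    df$well <- sprintf("W%03d", i)
    df[, c("time_h", "well", "isolate", "context", "replicate", "od600",
           "gfp")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

check_numeric_column <- function(x, name, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad))
    stop(sprintf("non-numeric '%s' value in %s at data row %d: '%s'",
                 name, path, bad[1], x[bad[1]]))
  v
}

#' Read a long-format plate-reader CSV
#'
#' Reads the long-format schema written by [write_plate_csv()] (columns
#' \code{time_h}, \code{od600}, \code{isolate}, \code{context},
#' \code{replicate}; optional \code{gfp}, \code{well}) and returns one
#' [growth_curve] per (isolate, context, replicate) group, time-sorted.
#' Row order in the file is irrelevant; duplicated time stamps within a
#' well are an error.
#'
#' @param path path to the CSV file.
#'
#' @return A list of [growth_curve] objects.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_h", "od600", "isolate", "context", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")))
  if (!nrow(df)) stop(sprintf("input file '%s' contains no data rows", path))
  df$time_h <- check_numeric_column(df$time_h, "time_h", path)
  df$od600 <- check_numeric_column(df$od600, "od600", path)
  has_gfp <- "gfp" %in% names(df) && any(!is.na(df$gfp))
  key <- interaction(df$isolate, df$context, df$replicate, drop = TRUE)
  curves <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (anyDuplicated(g$time_h))
      stop(sprintf("duplicated time stamps for isolate %s / %s rep %s in %s",
                   g$isolate[1], g$context[1], g$replicate[1], path))
    growth_curve(g$time_h, g$od600,
                 fluorescence = if (has_gfp && any(!is.na(g$gfp))) g$gfp,
                 isolate = g$isolate[1], context = g$context[1],
                 replicate = g$replicate[1])
  })
  names(curves) <- NULL
  curves
}

#' Write coculture traces to CSV
#'
#' @param traces list of [coculture_trace] objects (or one).
#' @param path output file path.
#'
#' @return The path, invisibly.
#' @export
write_coculture_csv <- function(traces, path) {
  if (inherits(traces, "coculture_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(time_h = tr$time,
               pair = paste(tr$meta$pair, collapse = "+"),
               ratio = if (is.null(tr$meta$ratio)) NA_character_ else tr$meta$ratio,
               replicate = if (is.null(tr$meta$replicate)) 1L else tr$meta$replicate,
               od600 = tr$total_od, gfp = tr$fluorescence,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read coculture traces from CSV
#'
#' Expects columns \code{time_h}, \code{od600} (total), \code{gfp};
#' optional \code{pair}, \code{ratio}, \code{replicate} for grouping.
#'
#' @param path path to the CSV file.
#'
#' @return A list of raw [coculture_trace] objects (not yet deconvolved).
#' @export
read_coculture_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_h", "od600", "gfp")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")))
  for (nm in required) df[[nm]] <- check_numeric_column(df[[nm]], nm, path)
  if (!"pair" %in% names(df)) df$pair <- "pair1"
  if (!"ratio" %in% names(df)) df$ratio <- NA_character_
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  key <- interaction(df$pair, df$ratio, df$replicate, drop = TRUE)
  traces <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (anyDuplicated(g$time_h))
      stop(sprintf("duplicated time stamps for %s in %s", g$pair[1], path))
    coculture_trace(g$time_h, g$od600, g$gfp,
                    meta = list(pair = strsplit(g$pair[1], "+", fixed = TRUE)[[1]],
                                ratio = g$ratio[1], replicate = g$replicate[1]))
  })
  names(traces) <- NULL
  traces
}

#' Convert a wide plate-reader matrix export to long format
#'
#' Many plate readers export a matrix with one row per time point and one
#' column per well. Given such a data frame and a well map (well id to
#' isolate/context/replicate), returns the long-format data frame used by
#' [read_plate_csv()].
#'
#' @param wide data frame: first column time, remaining columns one per
#'   well.
#' @param well_info data frame with columns \code{well}, \code{isolate},
#'   \code{context}, \code{replicate}; wells absent from it are dropped.
#' @param time_unit \code{"hours"} or \code{"minutes"} (minutes are
#'   converted to hours).
#'
#' @return A long-format data frame (\code{time_h}, \code{well},
#'   \code{isolate}, \code{context}, \code{replicate}, \code{od600},
#'   \code{gfp}).
#' @export
wide_to_long <- function(wide, well_info, time_unit = c("hours", "minutes")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.data.frame(wide), ncol(wide) >= 2L,
            is.data.frame(well_info),
            all(c("well", "isolate", "context", "replicate") %in% names(well_info)))
  time_h <- as.numeric(wide[[1]])
  if (time_unit == "minutes") time_h <- time_h / 60
  wells <- intersect(names(wide)[-1], well_info$well)
  if (!length(wells)) stop("no columns of 'wide' match 'well_info$well'")
  rows <- lapply(wells, function(w) {
    info <- well_info[well_info$well == w, , drop = FALSE][1, ]
    data.frame(time_h = time_h, well = w, isolate = info$isolate,
               context = info$context, replicate = info$replicate,
               od600 = as.numeric(wide[[w]]), gfp = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a panel metadata sidecar
#'
#' Records the generating parameters of a synthetic panel (baseline
#' kinetics, interaction matrix, regime, seed) in a YAML sidecar so that
#' parameter-recovery studies can compare estimates against the truth.
#'
#' @param panel a \code{cfsm_panel} from [generate_cfsm_panel()].
#' @param path sidecar file path.
#'
#' @return \code{write_panel_metadata}: the path, invisibly;
#'   \code{read_panel_metadata}: the metadata list.
#' @export
write_panel_metadata <- function(panel, path) {
  stopifnot(inherits(panel, "cfsm_panel"))
  spec <- panel$spec
  meta <- list(
    isolates = lapply(spec$isolates, function(p)
      list(r = p$r, K = p$K, S0 = p$S0, T_L = p$T_L)),
    interactions = apply(spec$interactions, 1L, as.list, simplify = FALSE),
    violation_mode = spec$violation_mode,
    sampling_interval_h = spec$sampling_interval,
    duration_h = spec$duration,
    replicates = spec$replicates,
    seed = spec$seed)
  yaml::write_yaml(meta, path, precision = 15)
  invisible(path)
}

#' @rdname write_panel_metadata
#' @export
read_panel_metadata <- function(path) yaml::read_yaml(path)

# short deterministic hash of a configuration (polynomial rolling hash over
# the serialized object), stamped onto every output table for provenance
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles the paths and analysis options of the end-to-end pipeline.
#'
#' @param input_csv long-format growth CSV (see [read_plate_csv()]).
#' @param output_dir directory for result tables (created if absent).
#' @param coculture_csv optional coculture CSV (see
#'   [read_coculture_csv()]).
#' @param upper_fraction growth-rate window edge as a fraction of K.
#' @param smoothing_window smoothing window in points (odd).
#' @param alpha significance level of the consistency test.
#' @param slope_tolerance relative slope tolerance of the consistency
#'   test.
#' @param detection_floor detection floor (OD600).
#' @param partner_floor partner-density floor for empirical interaction
#'   estimates (OD600).
#' @param seed integer seed stamped on the run (the pipeline itself is
#'   deterministic).
#'
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input_csv, output_dir, coculture_csv = NULL,
                            upper_fraction = 0.3, smoothing_window = 5L,
                            alpha = 0.05, slope_tolerance = 0.25,
                            detection_floor = 0.001, partner_floor = 0.005,
                            seed = 1L) {
  stopifnot(upper_fraction > 0, upper_fraction < 1, smoothing_window >= 1L,
            alpha > 0, alpha < 1, slope_tolerance > 0, detection_floor >= 0,
            partner_floor > 0)
  structure(list(input_csv = input_csv, output_dir = output_dir,
                 coculture_csv = coculture_csv,
                 upper_fraction = upper_fraction,
                 smoothing_window = as.integer(smoothing_window),
                 alpha = alpha, slope_tolerance = slope_tolerance,
                 detection_floor = detection_floor,
                 partner_floor = partner_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full spent-medium LV-adequacy pipeline
#'
#' Executes the analysis end to end: growth-curve fitting on every well of
#' the input CSV, aggregation into per-condition CFSM records, the
#' per-isolate r-K regression and LV-consistency verdict (baselines taken
#' from the \code{"fresh"} context, which must be present), and -- when a
#' coculture CSV is supplied -- deconvolution and LV coefficient fitting
#' for each coculture pair using the CFSM-derived coefficients as the
#' starting point. All tables are written to \code{output_dir}, stamped
#' with a hash of the configuration; reruns with the same configuration
#' and inputs produce byte-identical tables.
#'
#' @param config a [pipeline_config].
#'
#' @return Invisibly, a list with \code{parameters} (per-well fits),
#'   \code{records} (per-condition CFSM records), \code{regressions},
#'   \code{verdicts}, optional \code{coculture_fits}, and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  curves <- read_plate_csv(config$input_csv)  # fails before any output
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)

  params <- fit_growth_table(curves, window = config$smoothing_window,
                             upper_fraction = config$upper_fraction,
                             floor = config$detection_floor)
  records <- cfsm_records(params)

  fresh <- records[records$context == "fresh", , drop = FALSE]
  if (!nrow(fresh))
    stop("no 'fresh' context in the input; baselines cannot be estimated")
  verdict_rows <- list()
  regressions <- list()
  for (focal in sort(unique(records$focal))) {
    base_row <- fresh[fresh$focal == focal, , drop = FALSE]
    # the regression runs on spent-medium contexts (incl. the isolate's
    # own); the fresh-medium condition only supplies the baseline ratio
    recs <- records[records$focal == focal & records$context != "fresh", ,
                    drop = FALSE]
    if (!nrow(base_row) || nrow(recs) < 3L) next
    baseline <- list(r = base_row$r[1], K = base_row$K[1])
    reg <- tryCatch(fit_rk_regression(recs, focal = focal),
                    error = function(e)
                      stop(sprintf("consistency stage failed for %s: %s",
                                   focal, conditionMessage(e))))
    v <- lv_consistency_test(reg, baseline, alpha = config$alpha,
                             slope_tolerance = config$slope_tolerance)
    regressions[[focal]] <- reg
    verdict_rows[[focal]] <- data.frame(
      focal = focal, slope = reg$slope, intercept = reg$intercept,
      r_squared = reg$r_squared, p_value = reg$p_value, n = reg$n,
      baseline_ratio = v$baseline_ratio, lv_consistent = v$lv_consistent,
      reasons = paste(v$reasons, collapse = "; "), stringsAsFactors = FALSE)
  }
  verdicts <- do.call(rbind, verdict_rows)
  rownames(verdicts) <- NULL

  out <- list(parameters = params, records = records,
              regressions = regressions, verdicts = verdicts)

  if (!is.null(config$coculture_csv)) {
    traces <- read_coculture_csv(config$coculture_csv)
    fit_rows <- list()
    by_pair <- split(traces, vapply(traces, function(tr)
      paste(tr$meta$pair, collapse = "+"), character(1)))
    for (pair_id in names(by_pair)) {
      trs <- lapply(by_pair[[pair_id]], deconvolve_coculture)
      ids <- trs[[1]]$meta$pair
      base1 <- fresh[fresh$focal == ids[1], , drop = FALSE]
      base2 <- fresh[fresh$focal == ids[2], , drop = FALSE]
      if (!nrow(base1) || !nrow(base2))
        stop(sprintf("coculture stage: no fresh-medium baseline for pair %s",
                     pair_id))
      lag1 <- params$T_L[params$isolate == ids[1] & params$context == "fresh"]
      lag2 <- params$T_L[params$isolate == ids[2] & params$context == "fresh"]
      baselines <- list(
        logistic_params(base1$r[1], base1$K[1],
                        min(0.005, base1$K[1]), mean(lag1, na.rm = TRUE)),
        logistic_params(base2$r[1], base2$K[1],
                        min(0.005, base2$K[1]), mean(lag2, na.rm = TRUE)))
      # CFSM-derived coefficients as the starting point when available
      K12 <- records$K[records$focal == ids[1] & records$context == ids[2]]
      K21 <- records$K[records$focal == ids[2] & records$context == ids[1]]
      start <- if (length(K12) && length(K21))
        c(interaction_coefficient(K12[1], base1$K[1], base2$K[1]),
          interaction_coefficient(K21[1], base2$K[1], base1$K[1]))
      else NULL
      fit <- fit_lv_to_coculture(trs, baselines, start = start)
      fit_rows[[pair_id]] <- data.frame(
        pair = pair_id, c12_fit = fit$coefficients[1],
        c21_fit = fit$coefficients[2],
        c12_cfsm = if (is.null(start)) NA_real_ else start[1],
        c21_cfsm = if (is.null(start)) NA_real_ else start[2],
        rmse_od1 = fit$rmse[1], rmse_od2 = fit$rmse[2],
        n_traces = fit$n_traces, stringsAsFactors = FALSE)
    }
    out$coculture_fits <- do.call(rbind, fit_rows)
    rownames(out$coculture_fits) <- NULL
  }

  paths <- list(
    parameters = file.path(config$output_dir, "growth_parameters.csv"),
    records = file.path(config$output_dir, "cfsm_records.csv"),
    verdicts = file.path(config$output_dir, "consistency_verdicts.csv"),
    report = file.path(config$output_dir, "report.yaml"))
  write_stamped_csv(params, paths$parameters, hash)
  write_stamped_csv(records, paths$records, hash)
  write_stamped_csv(verdicts, paths$verdicts, hash)
  if (!is.null(out$coculture_fits)) {
    paths$coculture <- file.path(config$output_dir, "coculture_fits.csv")
    write_stamped_csv(out$coculture_fits, paths$coculture, hash)
  }
  report <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("lvcheck")),
    n_wells = nrow(params), n_conditions = nrow(records),
    lv_consistent = stats::setNames(as.list(verdicts$lv_consistent),
                                    verdicts$focal),
    options = unclass(config))
  yaml::write_yaml(report, paths$report)
  out$paths <- paths
  out$config_hash <- hash
  invisible(out)
}
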