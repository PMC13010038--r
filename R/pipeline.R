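#' Run configuration for the end-to-end analysis
#'
#' Exactly one input source must be given: either `input` (a directory of
#' trace CSVs, or a character vector of file paths) or `synthetic = TRUE`
#' (generate the default-calibrated cohort, using `seed`).
#'
#' @param input Directory or file paths of trace CSVs (or `NULL`).
#' @param synthetic Generate a synthetic cohort instead of reading files.
#' @param out Output directory (created if needed).
#' @param seed Integer seed for synthetic generation.
#' @param n_neonates Cohort size when `synthetic = TRUE`.
#' @param gap_s Segmentation gap rule in seconds.
#' @param grid Optional list of [alarm_settings()] for a what-if sweep.
#' @param dialect Trace CSV dialect.
#' @param verbose Log progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = FALSE, out = "neoalarm-out",
                       seed = 20211, n_neonates = 49, gap_s = 30,
                       grid = NULL, dialect = trace_dialect(),
                       verbose = TRUE) {
  if (is.null(input) == !isTRUE(synthetic)) {
    stop("exactly one input source required: `input` or `synthetic = TRUE`")
  }
  structure(list(input = input, synthetic = isTRUE(synthetic), out = out,
                 seed = as.integer(seed), n_neonates = as.integer(n_neonates),
                 gap_s = gap_s, grid = grid, dialect = dialect,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `input`, `synthetic`, `out`, `seed`, `n_neonates`,
#' `gap_s`, and `grid` (a mapping of vectors over `spo2_low`, `spo2_high`,
#' `pr_low`, `pr_high`, `delay_s`, `averaging_s`, `rapid_desat_pct`; the
#' cross-product is expanded, `.na` entries disable an upper threshold).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- NULL
  if (!is.null(y$grid)) {
    grid <- do.call(settings_grid, y$grid)
  }
  run_config(
    input = y$input, synthetic = y$synthetic %||% FALSE,
    out = y$out %||% "neoalarm-out", seed = y$seed %||% 20211,
    n_neonates = y$n_neonates %||% 49, gap_s = y$gap_s %||% 30,
    grid = grid, verbose = y$verbose %||% TRUE
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or synthesis), quality filtering, event
#' segmentation, burden summarization, and (when a settings grid is
#' present) the what-if sweep. Writes four artifact families to the output
#' directory: `quality_report.txt`/`.json` (pooled), `events.csv`,
#' `burden_summary*.{csv,json,txt}`, and `sweep.csv`. Inputs are never
#' mutated; the run is deterministic for fixed inputs and seed.
#'
#' @param config A [run_config()] or path to a YAML config file.
#' @return Invisibly, a list with the written paths and an exit status
#'   (0 = success).
#' @export
run_analyze <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) {
    if (config$verbose) message(sprintf(...))
  }
  if (config$synthetic) {
    log_msg("generating default-calibrated synthetic cohort (n = %d, seed = %d)",
            config$n_neonates, config$seed)
    cohort <- generate_cohort(default_calibration(config$n_neonates,
                                                  config$seed))
    traces <- cohort$traces
  } else {
    paths <- config$input
    if (length(paths) == 1L && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
    }
    if (length(paths) == 0L) {
      stop("no trace CSV files found under: ",
           paste(config$input, collapse = ", "))
    }
    traces <- list()
    for (p in paths) {
      tr <- tryCatch(read_trace_csv(p, config$dialect),
                     error = function(e) {
                       warning("skipping unreadable trace ", p, ": ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
      if (!is.null(tr)) traces[[tr$neonate_id]] <- tr
    }
    if (length(traces) == 0L) {
      stop("no parseable trace files in: ",
           paste(config$input, collapse = ", "))
    }
    log_msg("read %d trace file(s)", length(traces))
  }

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  filtered <- lapply(traces, apply_quality_rules)
  flt_traces <- lapply(filtered, `[[`, "trace")
  reports <- lapply(filtered, `[[`, "report")
  pooled_quality <- list(
    n_neonates = length(reports),
    total_duration_h = sum(vapply(reports, `[[`, numeric(1), "total_duration_h")),
    excluded_duration_h = sum(vapply(reports, `[[`, numeric(1),
                                     "excluded_duration_h")),
    n_invalid_spo2 = sum(vapply(reports, `[[`, numeric(1), "n_invalid_spo2")),
    n_invalid_pr = sum(vapply(reports, `[[`, numeric(1), "n_invalid_pr")),
    n_low_siq_alarm_entries_removed =
      sum(vapply(reports, `[[`, numeric(1), "n_low_siq_alarm_entries_removed")),
    n_alarm_entries_in_excluded =
      sum(vapply(reports, `[[`, numeric(1), "n_alarm_entries_in_excluded")),
    density_denominator = "quality-passing hours"
  )
  pooled_quality$excluded_fraction <-
    pooled_quality$excluded_duration_h / pooled_quality$total_duration_h
  qr_path <- file.path(config$out, "quality_report.txt")
  writeLines(c(
    sprintf("neonates: %d", pooled_quality$n_neonates),
    sprintf("total monitored hours: %.2f", pooled_quality$total_duration_h),
    sprintf("excluded hours: %.2f (%.2f%%)",
            pooled_quality$excluded_duration_h,
            100 * pooled_quality$excluded_fraction),
    sprintf("invalid SpO2 cells: %d", pooled_quality$n_invalid_spo2),
    sprintf("invalid PR cells: %d", pooled_quality$n_invalid_pr),
    sprintf("alarm entries removed for low SIQ: %d",
            pooled_quality$n_low_siq_alarm_entries_removed),
    sprintf("alarm entries in excluded cells: %d",
            pooled_quality$n_alarm_entries_in_excluded),
    sprintf("density denominator: %s", pooled_quality$density_denominator)
  ), qr_path)
  jsonlite::write_json(pooled_quality,
                       file.path(config$out, "quality_report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("quality: %.1f of %.1f hours excluded (%.2f%%)",
          pooled_quality$excluded_duration_h, pooled_quality$total_duration_h,
          100 * pooled_quality$excluded_fraction)

  cfg <- segmentation_config(gap_s = config$gap_s)
  events <- do.call(rbind, lapply(flt_traces, segment_events, config = cfg))
  rownames(events) <- NULL
  ev_path <- file.path(config$out, "events.csv")
  write_event_table(events, ev_path)
  log_msg("segmented %d alarm events", nrow(events))

  hours <- vapply(flt_traces, monitored_hours, numeric(1))
  clin <- events[events$category %in% clinical_categories(), , drop = FALSE]
  summary <- cohort_summary(per_neonate_burden(clin, hours), clin)
  sum_paths <- write_burden_summary(summary,
                                    file.path(config$out, "burden_summary"))

  sweep_path <- NULL
  if (!is.null(config$grid)) {
    log_msg("running what-if sweep over %d settings", length(config$grid))
    sweep <- what_if_sweep(flt_traces, config$grid, cfg)
    sweep_path <- file.path(config$out, "sweep.csv")
    utils::write.csv(sweep, sweep_path, row.names = FALSE)
  }

  invisible(list(status = 0L, quality_report = qr_path, events = ev_path,
                 burden_summary = unname(sum_paths), sweep = sweep_path,
                 summary = summary))
}
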