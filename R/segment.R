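#' Segmentation configuration
#'
#' Controls how per-cell alarm annotations are grouped into discrete alarm
#' events. A new event starts when the alarm category changes or when the
#' silence between consecutive alarm-flagged cells of the same category
#' exceeds `gap_s` seconds: a separation of exactly `gap_s` merges, strictly
#' more splits.
#'
#' @param gap_s Maximum silence (seconds) bridged within one event
#'   (default 30).
#' @param sample_interval_s Data cell length in seconds (fixed at 2).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(gap_s = 30, sample_interval_s = 2) {
  stopifnot(gap_s >= 0, sample_interval_s == 2)
  structure(list(gap_s = gap_s, sample_interval_s = sample_interval_s),
            class = "segmentation_config")
}

#' Segment per-cell alarm annotations into alarm events
#'
#' Converts the alarm-flagged cells of a (quality-filtered) trace into
#' discrete alarm events. Each clinical category (`spo2_low`, `spo2_high`,
#' `pr_low`, `pr_high`) and the `system` category forms its own stream, so a
#' category change always separates events while SpO2 and PR alarms
#' overlapping in time are distinct simultaneous events. Within a stream,
#' consecutive flagged cells are merged while the silence between them is at
#' most `gap_s`. Event duration counts active (flagged) cells only, at 2
#' seconds per cell; bridged gap cells are not counted.
#'
#' @param trace An `ox_trace`, normally after [apply_quality_rules()].
#' @param config A [segmentation_config()].
#' @param mapping Label table, see [default_label_map()].
#' @return A data frame with one row per event and columns `neonate_id`,
#'   `category`, `modality` (`audible`, `visual` or `audio_visual`),
#'   `start_t`, `end_t`, `active_cell_count`, `duration_s`,
#'   `merged_across_gap`.
#' @export
segment_events <- function(trace, config = segmentation_config(),
                           mapping = default_label_map()) {
  s <- trace$samples
  iv <- config$sample_interval_s
  flags <- cell_label_flags(s$events, mapping)
  keep <- if ("excluded" %in% names(s)) !s$excluded else rep(TRUE, nrow(s))

  out <- lapply(c(clinical_categories(), "system"), function(cat) {
    f <- flags[[cat]]
    idx <- which(f$flag & keep)
    if (length(idx) == 0L) return(NULL)
    ev <- events_from_cells(s$t[idx], gap_s = config$gap_s, interval_s = iv,
                            audible = f$audible[idx], visual = f$visual[idx])
    ev$category <- cat
    ev
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(empty_event_table())
  }
  out$neonate_id <- trace$neonate_id
  out <- out[order(out$start_t, out$category),
             c("neonate_id", "category", "modality", "start_t", "end_t",
               "active_cell_count", "duration_s", "merged_across_gap")]
  rownames(out) <- NULL
  out
}

# Core run-merger shared by segmentation and the alarm simulator: given the
# sorted times of flagged cells of one stream, group them under the gap rule
# and summarize each group.
events_from_cells <- function(t, gap_s, interval_s = 2,
                              audible = NULL, visual = NULL) {
  grp <- group_cells_by_gap(t, gap_s, interval_s)
  n_ev <- max(grp)
  cnt <- tabulate(grp, n_ev)
  start_t <- t[c(TRUE, diff(grp) == 1L)]
  end_t <- t[c(diff(grp) == 1L, TRUE)] + interval_s
  aud <- if (is.null(audible)) rep(TRUE, n_ev) else
    as.logical(tapply(audible, grp, any))
  vis <- if (is.null(visual)) rep(TRUE, n_ev) else
    as.logical(tapply(visual, grp, any))
  data.frame(
    modality = ifelse(aud & vis, "audio_visual",
                      ifelse(aud, "audible", "visual")),
    start_t = start_t,
    end_t = end_t,
    active_cell_count = cnt,
    duration_s = cnt * interval_s,
    merged_across_gap = (end_t - start_t) / interval_s > cnt,
    stringsAsFactors = FALSE
  )
}

empty_event_table <- function() {
  data.frame(
    neonate_id = character(0), category = character(0),
    modality = character(0), start_t = numeric(0), end_t = numeric(0),
    active_cell_count = integer(0), duration_s = numeric(0),
    merged_across_gap = logical(0), stringsAsFactors = FALSE
  )
}

#' Classify one contiguous alarm run
#'
#' Given the labels of the cells of one event and per-cell audible/visual
#' indicators, returns the event's category and modality. The modality is
#' `audio_visual` when both indicators occur within the event. A mix of
#' clinical categories within one run signals an upstream segmentation bug
#' and errors.
#'
#' @param labels Data frame of event labels as from [parse_event_labels()]
#'   (rows pooled over the event's cells).
#' @param modality_flags List with logical vectors `audible` and `visual`,
#'   one entry per cell.
#' @return A list with elements `category` and `modality`.
#' @export
classify_event <- function(labels, modality_flags) {
  if (nrow(labels) == 0L) stop("labels must be non-empty")
  clin <- intersect(unique(labels$category), clinical_categories())
  if (length(clin) > 1L) {
    stop("conflicting clinical categories within one run: ",
         paste(clin, collapse = ", "), " (segmentation bug upstream)")
  }
  category <- if (length(clin) == 1L) clin else unique(labels$category)[1]
  aud <- any(modality_flags$audible)
  vis <- any(modality_flags$visual)
  modality <- if (aud && vis) "audio_visual" else if (aud) "audible" else
    "visual"
  list(category = category, modality = modality)
}

#' Write an event table
#'
#' One row per alarm event, stable column order, seconds as integers.
#'
#' @param events Event table from [segment_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  ev <- events
  ev$start_t <- as.integer(round(ev$start_t))
  ev$end_t <- as.integer(round(ev$end_t))
  ev$duration_s <- as.integer(round(ev$duration_s))
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
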