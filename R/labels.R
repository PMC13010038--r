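#' Default event-label mapping table
#'
#' The monitor export annotates each 2-second data cell with zero or more
#' event tokens. This table maps every token of the documented trace dialect
#' to an alarm category and a modality. The six categories mirror the way
#' clinical alarm entries are split for analysis: low/high oxygen saturation,
#' low/high pulse rate, system events (sensor detached, low perfusion, cable
#' disconnected, invalid readings), and a catch-all `other` for tokens not in
#' the table. Tokens carrying the `(Silenced)` suffix are visual-only alarms
#' (the audible annunciation was suppressed at the device).
#'
#' @return A data frame with columns `raw`, `category`, `audible`, `visual`.
#' @seealso [parse_event_labels()]
#' @export
default_label_map <- function() {
  data.frame(
    raw = c(
      "SpO2 Low Alarm", "SpO2 Low Alarm (Silenced)",
      "SpO2 High Alarm", "SpO2 High Alarm (Silenced)",
      "PR Low Alarm", "PR Low Alarm (Silenced)",
      "PR High Alarm", "PR High Alarm (Silenced)",
      "Sensor Off", "Low Perfusion", "Cable Disconnect",
      "Invalid functional SpO2", "Invalid PR"
    ),
    category = c(
      "spo2_low", "spo2_low", "spo2_high", "spo2_high",
      "pr_low", "pr_low", "pr_high", "pr_high",
      "system", "system", "system", "system", "system"
    ),
    audible = c(
      TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
      TRUE, FALSE, TRUE, FALSE, FALSE
    ),
    visual = c(
      TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
      TRUE, TRUE, TRUE, FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

#' Read an event-label mapping table from a file
#'
#' Loads a label table in the same shape as [default_label_map()] from a
#' flat CSV file with columns `raw`, `category`, `audible`, `visual`, so
#' site-specific export vocabularies can be mapped without code changes.
#'
#' @param path CSV file path.
#' @return A data frame usable wherever a `mapping` argument is accepted.
#' @export
read_label_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("raw", "category", "audible", "visual")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols) > 0L) {
    stop("label map is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(map$category), alarm_categories())
  if (length(bad) > 0L) {
    stop("unknown categories in label map: ", paste(bad, collapse = ", "))
  }
  map$audible <- as.logical(map$audible)
  map$visual <- as.logical(map$visual)
  map[needed]
}

#' Alarm categories recognized by the package
#' @keywords internal
alarm_categories <- function() {
  c("spo2_low", "spo2_high", "pr_low", "pr_high", "system", "other")
}

clinical_categories <- function() {
  c("spo2_low", "spo2_high", "pr_low", "pr_high")
}

# Tokens that mark a whole cell as excluded for data integrity (system-event
# segments and invalid readings).
exclusion_tokens <- function() {
  c("Sensor Off", "Low Perfusion", "Cable Disconnect",
    "Invalid functional SpO2", "Invalid PR")
}

invalid_spo2_token <- function() "Invalid functional SpO2"
invalid_pr_token <- function() "Invalid PR"

#' Parse a delimited event string into event labels
#'
#' Splits a raw event annotation (tokens separated by `sep`) and maps each
#' distinct token through the label table. Unknown tokens map to category
#' `other` (with a warning) rather than being dropped. The result is a set:
#' duplicated tokens collapse to one row and token order does not matter.
#'
#' @param raw A single character string of delimited event tokens (may be
#'   empty or `NA`).
#' @param mapping Label table as returned by [default_label_map()].
#' @param sep Token separator used in the events column (default `";"`).
#' @param warn Warn on unknown tokens (default `TRUE`).
#' @return A data frame with one row per distinct token and columns `raw`,
#'   `category`, `audible`, `visual`.
#' @examples
#' parse_event_labels("SpO2 Low Alarm;Sensor Off")
#' parse_event_labels("")
#' @export
parse_event_labels <- function(raw, mapping = default_label_map(), sep = ";",
                               warn = TRUE) {
  empty <- data.frame(raw = character(0), category = character(0),
                      audible = logical(0), visual = logical(0),
                      stringsAsFactors = FALSE)
  if (length(raw) != 1L) stop("`raw` must be a single string")
  if (is.na(raw) || !nzchar(raw)) return(empty)
  tokens <- unique(trimws(strsplit(raw, sep, fixed = TRUE)[[1]]))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(empty)
  i <- match(tokens, mapping$raw)
  out <- data.frame(
    raw = tokens,
    category = ifelse(is.na(i), "other", mapping$category[i]),
    audible = ifelse(is.na(i), FALSE, mapping$audible[i]),
    visual = ifelse(is.na(i), FALSE, mapping$visual[i]),
    stringsAsFactors = FALSE
  )
  if (warn && anyNA(i)) {
    warning("unknown event token(s) mapped to category 'other': ",
            paste(tokens[is.na(i)], collapse = ", "), call. = FALSE)
  }
  # deterministic order for set semantics
  out <- out[order(out$raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized cell-level label flags. Event strings repeat heavily, so parse
# each unique string once. Returns, per category, logical vectors `flag`,
# `audible`, `visual` aligned with the cells.
cell_label_flags <- function(events, mapping = default_label_map(),
                             sep = ";") {
  cats <- c(clinical_categories(), "system", "other")
  n <- length(events)
  events[is.na(events)] <- ""
  uniq <- unique(events)
  idx <- match(events, uniq)
  per_u <- lapply(uniq, function(s) {
    labs <- parse_event_labels(s, mapping, sep, warn = FALSE)
    sapply(cats, function(cc) {
      sel <- labs$category == cc
      c(flag = any(sel),
        audible = any(labs$audible[sel]),
        visual = any(labs$visual[sel]))
    })
  })
  out <- lapply(seq_along(cats), function(j) {
    m <- vapply(per_u, function(u) u[, j], numeric(3))
    list(flag = as.logical(m[1, ])[idx],
         audible = as.logical(m[2, ])[idx],
         visual = as.logical(m[3, ])[idx])
  })
  names(out) <- cats
  out
}

# Strip a set of tokens from delimited event strings (vectorized via the
# unique-string trick). `which` is a logical mask of cells to edit.
strip_tokens <- function(events, which, tokens, sep = ";") {
  if (!any(which)) return(events)
  ev <- events[which]
  uniq <- unique(ev)
  stripped <- vapply(uniq, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    tk <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    tk <- tk[nzchar(tk) & !(tk %in% tokens)]
    paste(tk, collapse = sep)
  }, character(1), USE.NAMES = FALSE)
  events[which] <- stripped[match(ev, uniq)]
  events
}

# Does a delimited event string contain any of `tokens`? Vectorized.
has_token <- function(events, tokens, sep = ";") {
  events[is.na(events)] <- ""
  uniq <- unique(events)
  hit <- vapply(uniq, function(s) {
    if (!nzchar(s)) return(FALSE)
    any(trimws(strsplit(s, sep, fixed = TRUE)[[1]]) %in% tokens)
  }, logical(1), USE.NAMES = FALSE)
  hit[match(events, uniq)]
}
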