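#' Plot the alarm duration distribution
#'
#' Histogram of event durations on a log-friendly bucket axis, split by
#' category. Requires ggplot2.
#'
#' @param events Event table from [segment_events()].
#' @param edges Bucket edges in seconds.
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(events, edges = c(10, 30, 60, 120, 300, 600)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  breaks <- c(-Inf, edges, Inf)
  lab <- c(sprintf("<=%gs", edges[1]),
           if (length(edges) > 1)
             sprintf("%g-%gs", edges[-length(edges)], edges[-1]),
           sprintf(">%gs", edges[length(edges)]))
  df <- data.frame(
    bucket = factor(cut(events$duration_s, breaks, labels = lab), levels = lab),
    category = events$category
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bucket, fill = .data$category)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "event duration", y = "alarm events") +
    ggplot2::theme_minimal()
}

#' Plot per-neonate alarm densities, visual vs audible
#'
#' @param per_neonate Data frame from [per_neonate_burden()].
#' @return A ggplot object.
#' @export
plot_density_comparison <- function(per_neonate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- rbind(
    data.frame(modality = "visual", density = per_neonate$visual_per_hour),
    data.frame(modality = "audible", density = per_neonate$audible_per_hour)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$density)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "alarms per monitored hour", x = NULL) +
    ggplot2::theme_minimal()
}
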