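#' Tidy and summarise a dataset
#'
#' `tidy()` returns the canonical long records joined with their event
#' context (date, coordinates, method) — the table most analyses start
#' from. `glance()` gives a one-row overview.
#'
#' @param x A `miread_dataset`.
#' @param ... Unused.
#' @method tidy miread_dataset
#' @export
tidy.miread_dataset <- function(x, ...) {
  ev <- select(x$events, "sample_id", "start_date", "end_date",
               "latitude", "longitude", "collection_method")
  left_join(x$records, ev, by = c(event_ref = "sample_id"))
}

#' @rdname tidy.miread_dataset
#' @method glance miread_dataset
#' @export
glance.miread_dataset <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_records = nrow(x$records),
    n_taxa = dplyr::n_distinct(x$records$name),
    total_count = sum(x$records$value, na.rm = TRUE),
    date_min = suppressWarnings(min(x$events$start_date, na.rm = TRUE)),
    date_max = suppressWarnings(max(x$events$end_date, na.rm = TRUE)),
    layout = x$layout
  )
}

#' Plot abundance time series
#'
#' Counts over collection date, one line per taxon (colour) faceted by
#' life stage when more than one is present — the standard first look at
#' a surveillance series.
#'
#' @param object A `miread_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot miread_dataset
#' @export
autoplot.miread_dataset <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start_date,
                                        y = .data$value,
                                        colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "collection date", y = "count", colour = "taxon") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(df$life_stage) > 1) {
    p <- p + ggplot2::facet_wrap(~life_stage, scales = "free_y")
  }
  p
}
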