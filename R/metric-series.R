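#' Per-frame metric series
#'
#' A tibble with one row per retained frame and columns `replica`, `time`
#' (ns) and `value`, carrying the metric name and units as attributes.
#' The summary convention is the replica-level one used throughout the
#' package: the series mean is the unweighted mean of per-replica means and
#' the uncertainty is the standard error of the mean (n-1 sample SD of the
#' replica means divided by sqrt of the replica count).
#'
#' @param data tibble with columns replica, time, value.
#' @param name metric name.
#' @param units unit string (e.g. "nm", "nm^2", "count", "fraction").
#' @return a `metric_series` tibble.
#' @export
metric_series <- function(data, name, units) {
  out <- tibble::as_tibble(data)
  stopifnot(all(c("replica", "time", "value") %in% names(out)))
  attr(out, "metric_name") <- name
  attr(out, "units") <- units
  class(out) <- c("metric_series", class(out))
  out
}

#' @export
print.metric_series <- function(x, ...) {
  cat("<metric_series> ", attr(x, "metric_name"), " [", attr(x, "units"),
      "]\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname metric_series
#' @param x a `metric_series`.
#' @param ... unused.
#' @export
tidy.metric_series <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$metric <- attr(x, "metric_name")
  out$units <- attr(x, "units")
  out[, c("metric", "replica", "time", "value", "units")]
}

#' @rdname metric_series
#' @export
glance.metric_series <- function(x, ...) {
  per_rep <- tibble::as_tibble(x) %>%
    dplyr::group_by(.data$replica) %>%
    dplyr::summarise(rep_mean = mean(.data$value),
                     rep_sd = stats::sd(.data$value), .groups = "drop")
  tibble::tibble(
    metric = attr(x, "metric_name"),
    units = attr(x, "units"),
    mean = mean(per_rep$rep_mean),
    sem = sem(per_rep$rep_mean),
    sd_within = mean(per_rep$rep_sd, na.rm = TRUE),
    n_replicas = nrow(per_rep),
    n_frames = nrow(x)
  )
}

#' Plot a metric series over time
#'
#' @param object a [metric_series()].
#' @param ... unused.
#' @return a ggplot object (time traces, one colour per replica).
#' @export
autoplot.metric_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$replica)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)",
                  y = paste0(attr(object, "metric_name"),
                             " (", attr(object, "units"), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# build a metric_series from per-replica value vectors
#' @keywords internal
series_from_replicas <- function(ensemble, values_by_rep, name, units) {
  rows <- purrr::map2(ensemble$replicas, values_by_rep, function(r, v) {
    tibble::tibble(replica = r$id, time = r$time, value = v)
  })
  metric_series(dplyr::bind_rows(rows), name, units)
}
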