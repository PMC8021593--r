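#' Seizure-burden configuration
#'
#' Seizure burden is the percentage of 10-second bins in a trailing
#' 5-minute window (30 bins) classified as seizure, updated every 10
#' seconds.  The clinical thresholds are: `frequent` 10% (30 s of seizure
#' in 5 min), `abundant` 50% (2.5 min), and `continuous` 90% (4.5 min) —
#' the continuous threshold doubles as the status-epilepticus alert level,
#' since 4.5 min of seizure activity approaches the 5-min definition of
#' status epilepticus.
#'
#' @param bin_seconds Bin length in seconds (10).
#' @param window_bins Window length in bins (30, i.e. 5 min).
#' @param frequent,abundant,alert Burden thresholds in percent,
#'   `0 < frequent < abundant < alert <= 100`.
#'
#' @return An object of class `burden_config`.
#' @export
burden_config <- function(bin_seconds = 10, window_bins = 30,
                          frequent = 10, abundant = 50, alert = 90) {
  if (!(0 < frequent && frequent < abundant && abundant < alert && alert <= 100)) {
    abort("Thresholds must satisfy 0 < frequent < abundant < alert <= 100.",
          class = "szburden_error_input")
  }
  structure(
    list(bin_seconds = bin_seconds, window_bins = as.integer(window_bins),
         frequent = frequent, abundant = abundant, alert = alert),
    class = "burden_config"
  )
}

#' Rolling seizure-burden trend
#'
#' Converts a per-bin label series into the rolling burden trend: the value
#' at step *k* is `100 * sum(labels[max(0, k-29) .. k]) / 30`.  The
#' denominator stays fixed at the full window length even before 5 minutes
#' of recording have elapsed, so reaching the 90% alert level always
#' requires a genuine 4.5 minutes of seizure activity — a true seizure cut
#' short by the end (or start) of a recording before accruing 27 seizure
#' bins in some 30-bin window never alerts.
#'
#' @param labels A [bin_labels()] tibble (or 0/1 vector).
#' @param config A [burden_config()].
#'
#' @return A tibble of class `burden_trend`: `time_s` (window end time,
#'   10-s cadence), `burden_pct` in `[0, 100]`, and `level` (the
#'   [classify_burden_level()] category).
#' @export
#' @examples
#' burden_trend(bin_labels(rep(1, 30)))  # climbs to 100%
burden_trend <- function(labels, config = burden_config()) {
  if (is.data.frame(labels)) {
    lab <- labels$label
    bin_seconds <- attr(labels, "bin_seconds") %||% config$bin_seconds
  } else {
    lab <- as.integer(labels)
    bin_seconds <- config$bin_seconds
  }
  if (length(lab) == 0L) {
    abort("Label series is empty.", class = "szburden_error_empty")
  }
  w <- config$window_bins
  cs <- cumsum(lab)
  k <- seq_along(lab)
  windowed <- cs - c(rep(0, min(w, length(lab))), head(cs, -w))[k]
  pct <- 100 * windowed / w
  out <- tibble::tibble(
    time_s = k * bin_seconds,
    burden_pct = pct,
    level = classify_burden_level(pct, config)
  )
  class(out) <- c("burden_trend", class(out))
  attr(out, "config") <- config
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categorize a burden percentage
#'
#' Maps burden values to the clinical prevalence categories:
#' `none` = 0, `rare` in (0, 10), `frequent` in \[10, 50),
#' `abundant` in \[50, 90), `continuous` in \[90, 100\].
#'
#' @param value Numeric vector of burden percentages in `[0, 100]`.
#' @param config A [burden_config()].
#'
#' @return Ordered factor with levels none < rare < frequent < abundant <
#'   continuous.
#' @export
classify_burden_level <- function(value, config = burden_config()) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 100)) {
    abort("Burden values must lie in [0, 100].",
          class = "szburden_error_input")
  }
  lev <- c("none", "rare", "frequent", "abundant", "continuous")
  out <- dplyr::case_when(
    value == 0 ~ "none",
    value < config$frequent ~ "rare",
    value < config$abundant ~ "frequent",
    value < config$alert ~ "abundant",
    TRUE ~ "continuous"
  )
  factor(out, levels = lev, ordered = TRUE)
}

#' Maximum seizure burden of a record
#'
#' The record-level summary used for patient-level scoring: the maximum of
#' the burden trend over the whole recording.
#'
#' @param trend A [burden_trend()] tibble.
#' @return A single percentage.
#' @export
max_burden <- function(trend) {
  if (!is.data.frame(trend) || nrow(trend) == 0L) {
    abort("Burden trend is empty.", class = "szburden_error_empty")
  }
  max(trend$burden_pct)
}

#' Status-epilepticus alerts
#'
#' One alert per upward excursion of the burden trend across the alert
#' threshold (default 90%).  The alert latches: after firing it re-arms
#' only once the trend falls strictly below the threshold, so a sustained
#' excursion produces exactly one alert rather than one every 10 seconds.
#'
#' @param trend A [burden_trend()] tibble.
#' @param config A [burden_config()].
#'
#' @return Tibble with columns `time_s` (first step at or above threshold)
#'   and `kind` (`"status-epilepticus"`); zero rows when the threshold is
#'   never reached.
#' @export
generate_alerts <- function(trend, config = burden_config()) {
  above <- trend$burden_pct >= config$alert
  crossing <- above & !c(FALSE, head(above, -1))
  tibble::tibble(
    time_s = trend$time_s[crossing],
    kind = rep("status-epilepticus", sum(crossing))
  )
}

#' Plot a seizure-burden trend
#'
#' Burden percentage against time with the frequent/abundant/alert
#' thresholds as horizontal guides and status-epilepticus alerts marked.
#'
#' @param object A [burden_trend()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_trend <- function(object, ...) {
  config <- attr(object, "config") %||% burden_config()
  alerts <- generate_alerts(object, config)
  thr <- tibble::tibble(
    level = factor(c("frequent", "abundant", "continuous (SE alert)"),
                   levels = c("frequent", "abundant", "continuous (SE alert)")),
    value = c(config$frequent, config$abundant, config$alert)
  )
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60,
                                            y = .data$burden_pct)) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$value,
                                     linetype = .data$level),
                        colour = "grey40") +
    ggplot2::geom_line(colour = "#00441b") +
    ggplot2::labs(x = "time (min)", y = "seizure burden (%)",
                  linetype = "threshold") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (nrow(alerts) > 0) {
    p <- p + ggplot2::geom_point(
      data = alerts,
      ggplot2::aes(x = .data$time_s / 60, y = config$alert),
      colour = "red", shape = 17, size = 3, inherit.aes = FALSE
    )
  }
  p
}
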