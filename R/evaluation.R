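#' Burden-row category of a record's maximum burden
#'
#' The row labels of the patient-level confusion table: `>=90`, `50-89`,
#' `10-49`, `1-9`, `0` percent maximum seizure burden.
#'
#' @param max_burden Numeric vector of maximum burden percentages.
#' @return Ordered factor, highest row first.
#' @export
burden_row <- function(max_burden) {
  if (any(!is.finite(max_burden)) || any(max_burden < 0 | max_burden > 100)) {
    abort("Maximum burden must lie in [0, 100].",
          class = "szburden_error_input")
  }
  out <- dplyr::case_when(
    max_burden >= 90 ~ ">=90",
    max_burden >= 50 ~ "50-89",
    max_burden >= 10 ~ "10-49",
    max_burden > 0 ~ "1-9",
    TRUE ~ "0"
  )
  factor(out, levels = c(">=90", "50-89", "10-49", "1-9", "0"),
         ordered = TRUE)
}

record_categories <- c("SE", "SZ", "HEP", "NL/SL")

#' Patient-level confusion table
#'
#' Cross-tabulates record outcomes by burden row (maximum seizure burden)
#' and expert reference category, the patient-level performance summary.
#'
#' @param outcomes Tibble with one row per record: `record_id`, `category`
#'   (one of SE, SZ, HEP, NL/SL), and `max_burden` (percent).
#'
#' @return An object of class `confusion_table`: list with `counts` (5 x 4
#'   integer matrix, burden rows by categories), plus row/column totals.
#' @export
confusion_table <- function(outcomes) {
  outcomes <- tibble::as_tibble(outcomes)
  if (anyDuplicated(outcomes$record_id)) {
    abort("Duplicate record ids in outcomes.", class = "szburden_error_input")
  }
  if (nrow(outcomes) > 0 && !all(outcomes$category %in% record_categories)) {
    abort(sprintf("Record categories must be one of %s.",
                  paste(record_categories, collapse = ", ")),
          class = "szburden_error_input")
  }
  rows <- levels(burden_row(0))
  counts <- matrix(0L, nrow = 5, ncol = 4,
                   dimnames = list(rows, record_categories))
  if (nrow(outcomes) > 0) {
    tab <- table(burden_row(outcomes$max_burden),
                 factor(outcomes$category, levels = record_categories))
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  structure(
    list(counts = counts,
         row_totals = rowSums(counts),
         col_totals = colSums(counts),
         total = sum(counts)),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> burden row x reference category\n")
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$total))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile exact interval for a binomial proportion, reported in
#' percent.  `0/n` has lower bound exactly 0 and `n/n` upper bound exactly
#' 100.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `lower`, `upper` (percent).
#' @export
#' @examples
#' binomial_ci(320, 344)
binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n) {
    abort("Need 0 <= successes <= n with n > 0.",
          class = "szburden_error_input")
  }
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  tibble::tibble(estimate = 100 * successes / n,
                 lower = 100 * lower, upper = 100 * upper)
}

#' Patient-level sensitivity and specificity at a burden threshold
#'
#' A record is *flagged* at threshold `threshold` when its maximum seizure
#' burden reaches that percentage.  Sensitivity is the fraction of
#' duration-matched positive records flagged; specificity the fraction of
#' the remaining records not flagged.  The positive set depends on the
#' threshold (cumulative notification levels): at 90% it is the records
#' with a seizure of at least 4.5 min (status epilepticus), at 50% those
#' with a seizure of at least 2.5 min, at 10% any seizure.
#'
#' @param outcomes Record-outcome tibble (`record_id`, `max_burden`, ...).
#' @param threshold Burden threshold in percent.
#' @param positive Logical vector along `outcomes`, or the name of a
#'   logical column of `outcomes`, marking the duration-matched positive
#'   records.
#' @param level Confidence level for the exact binomial intervals.
#'
#' @return One-row tibble: `threshold`, `n_positive`, `detected`,
#'   `sensitivity`, `sens_lower`, `sens_upper`, `n_negative`,
#'   `false_flags`, `specificity`, `spec_lower`, `spec_upper`
#'   (all proportions in percent).
#' @export
patient_metrics <- function(outcomes, threshold, positive, level = 0.95) {
  outcomes <- tibble::as_tibble(outcomes)
  if (is.character(positive) && length(positive) == 1L) {
    positive <- outcomes[[positive]]
  }
  if (!is.logical(positive) || length(positive) != nrow(outcomes)) {
    abort("`positive` must be a logical vector along `outcomes`.",
          class = "szburden_error_input")
  }
  flagged <- outcomes$max_burden >= threshold
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    abort("Sensitivity/specificity undefined without both positives and negatives.",
          class = "szburden_error_undefined_metric")
  }
  detected <- sum(flagged & positive)
  false_flags <- sum(flagged & !positive)
  sens <- binomial_ci(detected, n_pos, level)
  spec <- binomial_ci(n_neg - false_flags, n_neg, level)
  tibble::tibble(
    threshold = threshold,
    n_positive = n_pos, detected = detected,
    sensitivity = sens$estimate, sens_lower = sens$lower,
    sens_upper = sens$upper,
    n_negative = n_neg, false_flags = false_flags,
    specificity = spec$estimate, spec_lower = spec$lower,
    spec_upper = spec$upper
  )
}

#' Negative predictive value over zero-burden records
#'
#' Among records in which no seizure bin was detected (maximum burden 0),
#' the fraction whose reference standard contains no seizure.
#'
#' @param outcomes Record-outcome tibble with `max_burden` and logical
#'   `has_seizure`.
#' @param level Confidence level.
#' @return One-row tibble: `n_zero_burden`, `true_negative`, `npv`,
#'   `lower`, `upper` (percent).
#' @export
negative_predictive_value <- function(outcomes, level = 0.95) {
  outcomes <- tibble::as_tibble(outcomes)
  zero <- outcomes$max_burden == 0
  if (!any(zero)) {
    abort("No zero-burden records; NPV undefined.",
          class = "szburden_error_undefined_metric")
  }
  tn <- sum(zero & !outcomes$has_seizure)
  ci <- binomial_ci(tn, sum(zero), level)
  tibble::tibble(n_zero_burden = sum(zero), true_negative = tn,
                 npv = ci$estimate, lower = ci$lower, upper = ci$upper)
}

#' False detections per hour
#'
#' The event-level false detection rate: false-positive events divided by
#' the total recording duration in hours (not a multiple-testing FDR).
#'
#' @param fp_events Count of false-positive events.
#' @param hours Total recording duration in hours.
#' @return Rate in events per hour.
#' @export
#' @examples
#' fdr_per_hour(383, 1052)
fdr_per_hour <- function(fp_events, hours) {
  if (!is.numeric(hours) || hours <= 0) {
    abort("`hours` must be positive.", class = "szburden_error_input")
  }
  fp_events / hours
}

#' Full diagnostic-accuracy report
#'
#' Combines patient-level sensitivity/specificity at each cumulative
#' burden threshold, event-level sensitivity and false-detection rates,
#' and the negative predictive value into one report object.
#'
#' @param outcomes Record-outcome tibble: `record_id`, `category`,
#'   `max_burden`, and logical columns `has_seizure`, `has_sz_ge_150s`,
#'   `has_sz_ge_270s` marking duration-matched positives.
#' @param event_counts Tibble with one row per threshold: `threshold`,
#'   `n_events` (reference events of the duration-matched class),
#'   `detected` (of which detected), `fp_events` (false-positive events at
#'   that threshold).
#' @param hours Total recording duration in hours.
#' @param overall_fp Optional count of false-positive events of any
#'   duration, for the overall false-detection rate.
#' @param level Confidence level.
#'
#' @return An object of class `szburden_metrics`: list with `patient`,
#'   `event`, `npv`, `overall_fdr`, `confusion`, `hours`.
#' @export
metrics_report <- function(outcomes, event_counts = NULL, hours = NULL,
                           overall_fp = NULL, level = 0.95) {
  outcomes <- tibble::as_tibble(outcomes)
  positive_col <- c("90" = "has_sz_ge_270s", "50" = "has_sz_ge_150s",
                    "10" = "has_seizure")
  patient <- purrr::map_dfr(c(90, 50, 10), function(th) {
    patient_metrics(outcomes, th, positive_col[[as.character(th)]], level)
  })
  event <- NULL
  if (!is.null(event_counts)) {
    event_counts <- tibble::as_tibble(event_counts)
    event <- purrr::map_dfr(seq_len(nrow(event_counts)), function(i) {
      row <- event_counts[i, ]
      ci <- binomial_ci(row$detected, row$n_events, level)
      tibble::tibble(
        threshold = row$threshold,
        n_events = row$n_events,
        detected = row$detected,
        sensitivity = ci$estimate,
        sens_lower = ci$lower, sens_upper = ci$upper,
        fp_events = row$fp_events,
        fdr_per_hour = if (!is.null(hours)) fdr_per_hour(row$fp_events, hours) else NA_real_
      )
    })
  }
  structure(
    list(
      patient = patient,
      event = event,
      npv = negative_predictive_value(outcomes, level),
      overall_fdr = if (!is.null(overall_fp) && !is.null(hours)) {
        fdr_per_hour(overall_fp, hours)
      } else NA_real_,
      overall_fp = overall_fp,
      confusion = confusion_table(outcomes),
      hours = hours
    ),
    class = "szburden_metrics"
  )
}

#' @export
print.szburden_metrics <- function(x, ...) {
  cat("Patient level (burden threshold, % sens / % spec):\n")
  p <- x$patient
  for (i in seq_len(nrow(p))) {
    cat(sprintf(
      "  >=%2d%%  sens %5.1f%% (%d/%d, CI %.1f-%.1f)  spec %5.1f%% (CI %.1f-%.1f)\n",
      p$threshold[i], p$sensitivity[i], p$detected[i], p$n_positive[i],
      p$sens_lower[i], p$sens_upper[i], p$specificity[i],
      p$spec_lower[i], p$spec_upper[i]
    ))
  }
  if (!is.null(x$event)) {
    cat("Event level:\n")
    e <- x$event
    for (i in seq_len(nrow(e))) {
      cat(sprintf(
        "  >=%2d%%  sens %5.1f%% (%d/%d)  FP %d  FDR %.2f/h\n",
        e$threshold[i], e$sensitivity[i], e$detected[i], e$n_events[i],
        e$fp_events[i], e$fdr_per_hour[i]
      ))
    }
  }
  cat(sprintf("NPV over zero-burden records: %.1f%% (%d/%d)\n",
              x$npv$npv, x$npv$true_negative, x$npv$n_zero_burden))
  if (!is.na(x$overall_fdr)) {
    cat(sprintf("Overall false detection rate: %.2f/h (%d events in %.0f h)\n",
                x$overall_fdr, x$overall_fp, x$hours))
  }
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `szburden_metrics` object.
#' @export
tidy.szburden_metrics <- function(x, ...) {
  out <- tidyr::pivot_longer(
    x$patient,
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "estimate"
  ) |>
    dplyr::transmute(
      level = "patient", threshold = .data$threshold,
      metric = .data$metric, estimate = .data$estimate,
      lower = ifelse(.data$metric == "sensitivity", .data$sens_lower,
                     .data$spec_lower),
      upper = ifelse(.data$metric == "sensitivity", .data$sens_upper,
                     .data$spec_upper)
    )
  if (!is.null(x$event)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::transmute(
        x$event, level = "event", threshold = .data$threshold,
        metric = "sensitivity", estimate = .data$sensitivity,
        lower = .data$sens_lower, upper = .data$sens_upper
      ),
      dplyr::transmute(
        x$event, level = "event", threshold = .data$threshold,
        metric = "fdr_per_hour", estimate = .data$fdr_per_hour,
        lower = NA_real_, upper = NA_real_
      )
    )
  }
  dplyr::bind_rows(
    out,
    tibble::tibble(level = "record", threshold = NA_real_, metric = "npv",
                   estimate = x$npv$npv, lower = x$npv$lower,
                   upper = x$npv$upper)
  )
}

#' @rdname metrics_report
#' @export
glance.szburden_metrics <- function(x, ...) {
  p90 <- x$patient[x$patient$threshold == 90, ]
  tibble::tibble(
    n_records = x$confusion$total,
    hours = x$hours %||% NA_real_,
    se_alert_sensitivity = p90$sensitivity,
    se_alert_specificity = p90$specificity,
    npv = x$npv$npv,
    overall_fdr_per_hour = x$overall_fdr
  )
}

#' Export a metrics report as JSON
#'
#' @param x A `szburden_metrics` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  stopifnot(inherits(x, "szburden_metrics"))
  obj <- list(
    patient = x$patient,
    event = x$event,
    npv = x$npv,
    overall_fdr_per_hour = x$overall_fdr,
    confusion = list(
      counts = x$confusion$counts,
      row_totals = x$confusion$row_totals,
      col_totals = x$confusion$col_totals,
      total = x$confusion$total
    ),
    hours = x$hours
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
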