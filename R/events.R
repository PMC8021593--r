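#' Extract discrete seizure events from bin labels
#'
#' Turns maximal runs of seizure-labeled bins into discrete events with
#' half-open `[start_s, end_s)` intervals.  Runs separated by at most
#' `merge_gap_bins` nonseizure bins are merged first; runs shorter than
#' `min_bins` bins are then dropped.  Predicted event durations are
#' therefore always multiples of the bin length.
#'
#' @param labels A [bin_labels()] tibble (or 0/1 vector).
#' @param merge_gap_bins Merge events separated by at most this many
#'   nonseizure bins (default 0 = no merging).
#' @param min_bins Drop events shorter than this many bins (default 1).
#' @param bin_seconds Bin length in seconds.
#'
#' @return Tibble with columns `start_s`, `end_s`, `duration_s`, `source`
#'   (`"predicted"`).
#' @export
#' @examples
#' extract_events(bin_labels(c(0, 1, 1, 1, 0)))  # one event [10, 40)
extract_events <- function(labels, merge_gap_bins = 0, min_bins = 1,
                           bin_seconds = 10) {
  if (is.data.frame(labels)) {
    lab <- labels$label
    bin_seconds <- attr(labels, "bin_seconds") %||% bin_seconds
  } else {
    lab <- as.integer(labels)
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = starts[r$values == 1L],
                         end = ends[r$values == 1L])  # 1-based inclusive bins
  if (nrow(runs) > 1 && merge_gap_bins > 0) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap_bins) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= min_bins, , drop = FALSE]
  tibble::tibble(
    start_s = (runs$start - 1L) * bin_seconds,
    end_s = runs$end * bin_seconds,
    duration_s = (runs$end - runs$start + 1L) * bin_seconds,
    source = rep("predicted", nrow(runs))
  )
}

#' Reference seizure events of an annotation set
#'
#' @param annotations An [annotation_set()].
#' @param label Event label to extract (default `"seizure"`).
#' @return Tibble `start_s`, `end_s`, `duration_s`, `source`
#'   (`"reference"`).
#' @export
reference_events <- function(annotations, label = "seizure") {
  stopifnot(inherits(annotations, "annotation_set"))
  ev <- annotations$events[annotations$events$label == label, , drop = FALSE]
  tibble::tibble(
    start_s = ev$onset_s,
    end_s = ev$onset_s + ev$duration_s,
    duration_s = ev$duration_s,
    source = rep("reference", nrow(ev))
  )
}

#' Rasterize timed events to 10-second bins
#'
#' Ideal-label rasterization of reference intervals: bin *k* is labeled 1
#' iff its half-open interval `[10 k, 10 (k+1))` overlaps any event.  Used
#' to drive the burden/evaluation pipeline with a perfect classifier.
#'
#' @param events Event tibble with `start_s`, `end_s`.
#' @param n_bins Number of bins of the record.
#' @param bin_seconds Bin length in seconds.
#' @return A [bin_labels()] tibble of length `n_bins`.
#' @export
rasterize_events <- function(events, n_bins, bin_seconds = 10) {
  lab <- integer(n_bins)
  for (i in seq_len(nrow(events))) {
    first <- floor(events$start_s[i] / bin_seconds)
    last <- ceiling(events$end_s[i] / bin_seconds) - 1
    first <- max(0, first)
    last <- min(n_bins - 1, last)
    if (last >= first) lab[(first:last) + 1L] <- 1L
  }
  bin_labels(lab, bin_seconds = bin_seconds)
}

#' Classify an event by duration
#'
#' The longest duration class the event reaches, matching the burden
#' thresholds: 270 s (4.5 min, the amount of seizure needed inside a 5-min
#' window for a status alert), 150 s (2.5 min, the abundant threshold),
#' 30 s (the frequent threshold), else `<30s`.
#'
#' @param duration_s Numeric vector of event durations in seconds.
#' @return Ordered factor with levels `<30s` < `>=30s` < `>=2.5min` <
#'   `>=4.5min`.
#' @export
#' @examples
#' classify_event_duration(c(270, 150, 20))
classify_event_duration <- function(duration_s) {
  out <- dplyr::case_when(
    duration_s >= 270 ~ ">=4.5min",
    duration_s >= 150 ~ ">=2.5min",
    duration_s >= 30 ~ ">=30s",
    TRUE ~ "<30s"
  )
  factor(out, levels = c("<30s", ">=30s", ">=2.5min", ">=4.5min"),
         ordered = TRUE)
}

#' Match predicted events against reference events
#'
#' Any-overlap matching: a reference seizure event counts as detected (TP)
#' if at least one predicted event overlaps it by any positive amount; a
#' predicted event counts as a false positive if it overlaps no reference
#' seizure event.  Predicted events overlapping a reference HEP interval
#' (but no seizure) are still false positives for seizure scoring but are
#' tagged `over_hep` so the share of false detections explained by highly
#' epileptiform patterns can be reported.
#'
#' @param predicted,reference Event tibbles with `start_s`, `end_s`.
#' @param hours Total recording duration in hours (for the false-detection
#'   rate denominator).
#' @param hep Optional tibble of reference HEP intervals (`start_s`,
#'   `end_s`).
#'
#' @return An object of class `match_result`: list with `tp`, `fn`,
#'   `fp_events`, `fp_over_hep`, `hours`, and `predicted` (the input tibble
#'   plus logical `matched` and `over_hep` columns).
#' @export
match_events <- function(predicted, reference, hours, hep = NULL) {
  if (nrow(reference) > 1) {
    o <- order(reference$start_s)
    ref <- reference[o, ]
    if (any(ref$start_s[-1] < ref$end_s[-nrow(ref)])) {
      abort("Reference events overlap.", class = "szburden_error_input")
    }
  }
  overlaps_any <- function(s, e, tab) {
    if (is.null(tab) || nrow(tab) == 0) return(FALSE)
    any(pmin(e, tab$end_s) > pmax(s, tab$start_s))
  }
  matched_ref <- vapply(seq_len(nrow(reference)), function(i) {
    overlaps_any(reference$start_s[i], reference$end_s[i], predicted)
  }, logical(1))
  matched_pred <- vapply(seq_len(nrow(predicted)), function(i) {
    overlaps_any(predicted$start_s[i], predicted$end_s[i], reference)
  }, logical(1))
  over_hep <- vapply(seq_len(nrow(predicted)), function(i) {
    overlaps_any(predicted$start_s[i], predicted$end_s[i], hep)
  }, logical(1))
  pred <- predicted
  pred$matched <- matched_pred
  pred$over_hep <- !matched_pred & over_hep
  structure(
    list(
      tp = sum(matched_ref),
      fn = sum(!matched_ref),
      fp_events = sum(!matched_pred),
      fp_over_hep = sum(pred$over_hep),
      hours = hours,
      predicted = pred
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FN %d, FP %d (%d over HEP) in %.2f h -> FDR %.2f/h\n",
    x$tp, x$fn, x$fp_events, x$fp_over_hep, x$hours,
    fdr_per_hour(x$fp_events, x$hours)
  ))
  invisible(x)
}
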