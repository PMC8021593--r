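#' Multichannel EEG recording
#'
#' `eeg_record()` is the package's container for a multichannel EEG signal:
#' a channels-by-time matrix of potentials in microvolts, a sampling rate in
#' Hz, ordered channel names and a time origin.  All times in the package are
#' seconds from the start of the record, intervals are half-open
#' `[start, end)`, and sample indexing is 0-based in time
#' (sample `i` covers `[i/rate, (i+1)/rate)`).
#'
#' @param samples Numeric matrix, channels in rows, samples in columns, in
#'   microvolts.
#' @param rate Sampling rate in Hz (samples per second), positive scalar.
#' @param channel_names Character vector of channel labels, one per row of
#'   `samples`.  Defaults to the matrix rownames, or `"ch1"..."chN"`.
#' @param start_time Time origin in seconds (default 0).
#'
#' @return An object of class `eeg_record` with elements `samples`, `rate`,
#'   `channel_names`, `start_time` and `duration` (seconds).
#' @export
#' @examples
#' x <- matrix(rnorm(500), nrow = 2)
#' rec <- eeg_record(x, rate = 250)
#' rec$duration
eeg_record <- function(samples, rate, channel_names = NULL, start_time = 0) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels-by-time matrix.",
          class = "szburden_error_input")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).",
          class = "szburden_error_input")
  }
  if (nrow(samples) == 0L) {
    abort("Record has zero channels.", class = "szburden_error_empty")
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(samples)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    abort("`channel_names` must have one entry per channel.",
          class = "szburden_error_input")
  }
  rownames(samples) <- channel_names
  structure(
    list(
      samples = samples,
      rate = rate,
      channel_names = channel_names,
      start_time = start_time,
      duration = ncol(samples) / rate
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channel(s) x %.1f s @ %g Hz (%d samples/channel)\n",
    nrow(x$samples), x$duration, x$rate, ncol(x$samples)
  ))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.eeg_record <- function(x, ...) {
  sprintf("<eeg_record: %d ch x %.1f s @ %g Hz>", nrow(x$samples), x$duration, x$rate)
}

is_eeg_record <- function(x) inherits(x, "eeg_record")

assert_eeg_record <- function(x, arg = "record") {
  if (!is_eeg_record(x)) {
    abort(sprintf("`%s` must be an <eeg_record>.", arg),
          class = "szburden_error_input")
  }
  invisible(x)
}

#' Segment a record into nonoverlapping 10-second bins
#'
#' Splits a record into contiguous, nonoverlapping analysis epochs ("bins")
#' of exactly `bin_seconds` seconds.  A trailing partial bin is discarded:
#' every downstream feature is defined on full bins only, so sub-10-s tails
#' never enter the classifier.
#'
#' @param record An [eeg_record()].
#' @param bin_seconds Epoch length in seconds (default 10, the atomic unit
#'   of classification).
#'
#' @return A tibble with one row per bin: `bin` (0-based ordinal), `start_s`,
#'   `end_s` (half-open, seconds) and `signal`, a list-column of
#'   channels-by-samples matrices of exactly `rate * bin_seconds` columns.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(2 * 250 * 35), nrow = 2), rate = 250)
#' segment_bins(rec)  # 3 bins; the trailing 5 s are dropped
segment_bins <- function(record, bin_seconds = 10) {
  assert_eeg_record(record)
  samples_per_bin <- as.integer(round(record$rate * bin_seconds))
  n_bins <- floor(ncol(record$samples) / samples_per_bin)
  if (n_bins < 1L) {
    abort(sprintf("Record is shorter than one %g-s bin.", bin_seconds),
          class = "szburden_error_too_short")
  }
  k <- seq_len(n_bins) - 1L
  tibble::tibble(
    bin = k,
    start_s = k * bin_seconds,
    end_s = (k + 1) * bin_seconds,
    signal = lapply(k, function(i) {
      record$samples[, (i * samples_per_bin + 1L):((i + 1L) * samples_per_bin),
                     drop = FALSE]
    })
  )
}
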