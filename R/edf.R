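#' Read an EDF recording
#'
#' Reads a European Data Format (EDF/EDF+) file into an [eeg_record()].
#' All ordinary signals are converted to physical units (assumed microvolts)
#' using the per-signal calibration in the header; EDF+ annotation signals
#' are skipped.  Signals whose sampling rate differs from `target_rate` are
#' resampled with a polyphase filter so that downstream 10-second bins have
#' a uniform sample count; the headband device records at a fixed 250 Hz,
#' which is the package-wide working rate.
#'
#' @param path Path to an EDF or EDF+ file.
#' @param target_rate Working sampling rate in Hz (default 250).
#'
#' @return An [eeg_record()] at `target_rate`, channel order as in the file.
#' @seealso [write_edf()]
#' @export
read_edf <- function(path, target_rate = 250) {
  if (!file.exists(path)) {
    abort(sprintf("EDF file not found: %s", path), class = "szburden_error_format")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  read_ascii <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) {
      abort("Truncated EDF header.", class = "szburden_error_format")
    }
    trimws(rawToChar(raw))
  }
  read_num <- function(n) {
    s <- read_ascii(n)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) abort(sprintf("Malformed numeric EDF header field: '%s'", s),
                        class = "szburden_error_format")
    v
  }

  version <- read_ascii(8)
  if (!identical(version, "0")) {
    abort("Not an EDF file (version field is not '0').",
          class = "szburden_error_format")
  }
  read_ascii(80)                        # patient id
  read_ascii(80)                        # recording id
  read_ascii(8)                         # start date
  read_ascii(8)                         # start time
  header_bytes <- read_num(8)
  read_ascii(44)                        # reserved / EDF+ flag
  n_records <- read_num(8)
  record_duration <- read_num(8)
  ns <- as.integer(read_num(4))
  if (ns < 1L) abort("EDF file declares zero signals.",
                     class = "szburden_error_empty")
  if (header_bytes != 256 * (ns + 1)) {
    abort("EDF header size inconsistent with signal count.",
          class = "szburden_error_format")
  }

  field <- function(width, numeric = FALSE) {
    vapply(seq_len(ns), function(i) read_ascii(width), character(1))
  }
  labels <- field(16)
  field(80)                             # transducer
  field(8)                              # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                             # prefiltering
  spr <- as.integer(field(8))           # samples per data record
  field(32)                             # reserved
  if (anyNA(phys_min) || anyNA(phys_max) || anyNA(dig_min) || anyNA(dig_max) ||
      anyNA(spr)) {
    abort("Malformed EDF signal header.", class = "szburden_error_format")
  }

  total_per_record <- sum(spr)
  data <- readBin(con, "integer", n = n_records * total_per_record,
                  size = 2, signed = TRUE, endian = "little")
  if (length(data) < n_records * total_per_record) {
    abort("EDF data section shorter than header declares.",
          class = "szburden_error_format")
  }

  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) abort("EDF file contains no signal channels.",
                        class = "szburden_error_empty")

  # column offsets of each signal inside one data record
  offsets <- c(0L, cumsum(spr))
  signals <- vector("list", ns)
  for (i in which(keep)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * total_per_record, "+"))
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    x <- (data[idx] - dig_min[i]) * gain + phys_min[i]
    rate_i <- spr[i] / record_duration
    if (abs(rate_i - target_rate) > 1e-9) {
      x <- resample_to(x, rate_i, target_rate)
    }
    signals[[i]] <- x
  }
  signals <- signals[keep]
  len <- unique(vapply(signals, length, integer(1)))
  if (length(len) != 1L) {
    n <- min(vapply(signals, length, integer(1)))
    signals <- lapply(signals, function(x) x[seq_len(n)])
  }
  mat <- do.call(rbind, signals)
  eeg_record(mat, rate = target_rate, channel_names = trimws(labels[keep]))
}

# Rational-ratio polyphase resampling from `from` Hz to `to` Hz.
resample_to <- function(x, from, to) {
  ratio <- to / from
  pq <- rational_approx(ratio)
  out <- signal::resample(x, pq[1], pq[2])
  expected <- round(length(x) * ratio)
  if (length(out) > expected) out <- out[seq_len(expected)]
  if (length(out) < expected) out <- c(out, rep(out[length(out)], expected - length(out)))
  out
}

rational_approx <- function(r, max_den = 1000L) {
  best <- c(round(r), 1L)
  best_err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    err <- abs(r - p / q)
    if (err < best_err - 1e-12) {
      best <- c(p, q)
      best_err <- err
      if (err < 1e-9) break
    }
  }
  as.integer(best)
}

#' Write an EDF recording
#'
#' Writes an [eeg_record()] as a plain continuous EDF file with one-second
#' data records.  Samples are quantized to the EDF 16-bit integer range with
#' a fixed physical calibration of +/-3276.7 microvolts at 0.1 microvolt
#' resolution; values outside that range are clipped.  The record duration
#' must be a whole number of seconds.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(record, path) {
  assert_eeg_record(record)
  rate <- record$rate
  if (abs(rate - round(rate)) > 1e-9) {
    abort("EDF writer requires an integer sampling rate.",
          class = "szburden_error_input")
  }
  n_records <- floor(ncol(record$samples) / rate)
  if (n_records < 1 || n_records * rate != ncol(record$samples)) {
    abort("EDF writer requires a whole number of seconds of signal.",
          class = "szburden_error_input")
  }
  ns <- nrow(record$samples)
  phys_max <- 3276.7
  phys_min <- -3276.7
  dig_max <- 32767L
  dig_min <- -32767L

  pad <- function(s, width) {
    s <- substr(s, 1, width)
    sprintf(paste0("%-", width, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    pad("0", 8),
    pad("X X X X", 80),
    pad("Startdate X X X X", 80),
    pad("01.01.00", 8),
    pad("00.00.00", 8),
    pad(as.character(256 * (ns + 1)), 8),
    pad("", 44),
    pad(as.character(n_records), 8),
    pad("1", 8),
    pad(as.character(ns), 4)
  ), con, eos = NULL)
  per_signal <- function(values, width) {
    writeChar(paste(vapply(values, pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  per_signal(record$channel_names, 16)
  per_signal(rep("", ns), 80)
  per_signal(rep("uV", ns), 8)
  per_signal(rep(format(phys_min, nsmall = 1), ns), 8)
  per_signal(rep(format(phys_max, nsmall = 1), ns), 8)
  per_signal(rep(as.character(dig_min), ns), 8)
  per_signal(rep(as.character(dig_max), ns), 8)
  per_signal(rep("", ns), 80)
  per_signal(rep(as.character(as.integer(rate)), ns), 8)
  per_signal(rep("", ns), 32)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- round((pmin(pmax(record$samples, phys_min), phys_max) - phys_min) *
                     gain + dig_min)
  spr <- as.integer(rate)
  # interleave: per data record, all samples of signal 1, then signal 2, ...
  out <- integer(n_records * ns * spr)
  pos <- 0L
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(digital[, cols, drop = FALSE])
    out[(pos + 1L):(pos + ns * spr)] <- as.integer(block)
    pos <- pos + ns * spr
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read or write an annotation sidecar
#'
#' Reference annotations travel next to each EDF as a plain-text sidecar:
#' a first line `record_category=<SE|SZ|HEP|NL/SL>` followed by a CSV table
#' with header `onset_s,duration_s,label`, where `label` is one of
#' `seizure`, `hep`, `slow`, `normal`, `artifact`.  Event intervals are
#' half-open `[onset_s, onset_s + duration_s)` in seconds from record start.
#'
#' @param path Sidecar file path.
#' @param annotations For writing: an `annotation_set` as returned by
#'   [annotation_set()].
#'
#' @return `read_annotations()` returns an [annotation_set()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !grepl("^record_category=", lines[1])) {
    abort("Annotation sidecar must start with 'record_category=...'.",
          class = "szburden_error_format")
  }
  category <- sub("^record_category=", "", lines[1])
  tab <- read.csv(text = paste(lines[-1], collapse = "\n"),
                  stringsAsFactors = FALSE)
  events <- tibble::as_tibble(tab)
  annotation_set(category = category, events = events)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  lines <- c(
    paste0("record_category=", annotations$category),
    "onset_s,duration_s,label"
  )
  ev <- annotations$events
  if (nrow(ev) > 0) {
    lines <- c(lines, sprintf("%g,%g,%s", ev$onset_s, ev$duration_s, ev$label))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Reference-standard annotation set
#'
#' Bundles the expert reference standard for one record: the record-level
#' category (`SE` status epilepticus, `SZ` seizure < 5 min, `HEP` highly
#' epileptiform pattern, `NL/SL` normal or diffusely slow) and a table of
#' timed events with half-open intervals.
#'
#' @param category One of `"SE"`, `"SZ"`, `"HEP"`, `"NL/SL"`.
#' @param events Tibble/data frame with columns `onset_s`, `duration_s`,
#'   `label` (`seizure`, `hep`, `slow`, `normal`, `artifact`).  May be empty.
#'
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(category,
                           events = tibble::tibble(onset_s = numeric(),
                                                   duration_s = numeric(),
                                                   label = character())) {
  valid_cat <- c("SE", "SZ", "HEP", "NL/SL")
  if (!category %in% valid_cat) {
    abort(sprintf("Record category must be one of %s.",
                  paste(valid_cat, collapse = ", ")),
          class = "szburden_error_input")
  }
  events <- tibble::as_tibble(events)
  needed <- c("onset_s", "duration_s", "label")
  if (!all(needed %in% names(events))) {
    abort("Events need columns onset_s, duration_s, label.",
          class = "szburden_error_input")
  }
  valid_lab <- c("seizure", "hep", "slow", "normal", "artifact")
  if (nrow(events) > 0 && !all(events$label %in% valid_lab)) {
    abort(sprintf("Event labels must be one of %s.",
                  paste(valid_lab, collapse = ", ")),
          class = "szburden_error_input")
  }
  structure(list(category = category, events = events),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> category %s, %d event(s)\n",
              x$category, nrow(x$events)))
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}
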