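#' Clinical EEG frequency bands
#'
#' Band edges in Hz for the standard clinical bands inside the 1-30 Hz
#' analysis range: delta 1-4, theta 4-8, alpha 8-13, beta 13-30.
#'
#' @return A tibble with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low  = c(1, 4, 8, 13),
    high = c(4, 8, 13, 30)
  )
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the output has no phase distortion and the same
#' length as the input.  The package-wide analysis band is 1-30 Hz: the 1 Hz
#' high-pass removes DC and slow drift, the 30 Hz low-pass removes line
#' noise and EMG.
#'
#' @param x Numeric vector or channels-by-samples matrix.
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param rate Sampling rate in Hz.
#' @param order Filter order (default 4).
#'
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, low = 1, high = 30, rate = 250, order = 4) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low ||
      high >= rate / 2) {
    abort("Band edges must satisfy 0 < low < high < rate/2.",
          class = "szburden_error_parameter")
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  # demean first: removes DC exactly and avoids filtfilt edge transients
  apply_filter <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.matrix(x)) {
    out <- t(apply(x, 1, apply_filter))
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_filter(x)
  }
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments (default 2 s) with
#' 50% overlap, mean removed per segment, one-sided density normalized so
#' that `sum(psd) * df` equals the signal variance (Parseval).
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param window_s Segment length in seconds.
#' @param overlap Fractional overlap between segments.
#'
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate = 250, window_s = 2, overlap = 0.5) {
  nper <- as.integer(round(window_s * rate))
  if (length(x) < nper) {
    abort("Signal shorter than one Welch segment.",
          class = "szburden_error_parameter")
  }
  step <- as.integer(round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- rate * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]  # one-sided
    acc <- acc + sp
  }
  tibble::tibble(
    freq = (seq_len(nfreq) - 1L) * rate / nper,
    psd = acc / length(starts)
  )
}

#' Band powers and band-power ratios
#'
#' Integrates the Welch spectrum over each clinical band.  Band intervals
#' are half-open `[low, high)`; the total is the power in `[1, 30)` Hz.
#' Ratios are each band's power over the total, with the degenerate 0/0
#' (all-zero signal) defined as 0 so that flat signals look maximally
#' nonseizure-like.
#'
#' @param x Numeric vector (one channel, one 10-s bin).
#' @param rate Sampling rate in Hz.
#' @param bands Band table as from [eeg_bands()].
#'
#' @return A one-row tibble: `<band>_power` (uV^2), `<band>_ratio`, and
#'   `total_power` (uV^2 in 1-30 Hz).
#' @export
band_powers <- function(x, rate = 250, bands = eeg_bands()) {
  spec <- welch_psd(x, rate = rate)
  df <- spec$freq[2] - spec$freq[1]
  total <- sum(spec$psd[spec$freq >= 1 & spec$freq < 30]) * df
  out <- list(total_power = total)
  for (i in seq_len(nrow(bands))) {
    sel <- spec$freq >= bands$low[i] & spec$freq < bands$high[i]
    p <- sum(spec$psd[sel]) * df
    out[[paste0(bands$band[i], "_power")]] <- p
    out[[paste0(bands$band[i], "_ratio")]] <- if (total > 0) p / total else 0
  }
  tibble::as_tibble(out)
}

#' Time-domain morphology features
#'
#' Per-channel amplitude and shape descriptors of a 10-s bin:
#' root-mean-square amplitude, peak-to-peak amplitude, line length
#' (`sum(|x[t+1] - x[t]|)`, a classic ictal-activity index), variance,
#' excess kurtosis (0 for a constant signal), and `delta_change`, the ratio
#' of second-half to first-half RMS (0/0 defined as 1).
#'
#' @param x Numeric vector (one channel, one bin).
#'
#' @return One-row tibble: `amplitude_rms`, `amplitude_p2p`, `line_length`,
#'   `variance`, `kurtosis`, `delta_change`.
#' @export
morphology_features <- function(x) {
  n <- length(x)
  rms <- function(v) sqrt(mean(v^2))
  half <- n %/% 2L
  r1 <- rms(x[seq_len(half)])
  r2 <- rms(x[(half + 1L):n])
  delta_change <- if (r1 == 0 && r2 == 0) 1 else r2 / max(r1, .Machine$double.xmin)
  s2 <- var(x) * (n - 1) / n
  kurt <- if (s2 > 0) mean((x - mean(x))^4) / s2^2 - 3 else 0
  tibble::tibble(
    amplitude_rms = rms(x),
    amplitude_p2p = max(x) - min(x),
    line_length = sum(abs(diff(x))),
    variance = s2,
    kurtosis = kurt,
    delta_change = delta_change
  )
}

#' Rhythmicity and regularity (entropy) features
#'
#' Sample entropy SampEn(m = 2, r = 0.2 SD) of the bin signal (lower for
#' rhythmic, self-similar ictal activity than for irregular background) and
#' spectral entropy, the Shannon entropy of the normalized 1-30 Hz Welch
#' spectrum divided by its maximum, in `[0, 1]` (low when power is
#' concentrated at one frequency).  A constant signal yields 0 for both.
#'
#' @param x Numeric vector (one channel, one bin).
#' @param rate Sampling rate in Hz.
#'
#' @return One-row tibble: `sample_entropy` (nats), `spectral_entropy`.
#' @export
entropy_features <- function(x, rate = 250) {
  s <- sd(x)
  sampen <- if (is.na(s) || s == 0) 0 else .sampen_cpp(x, 2L, 0.2 * s)
  spec <- welch_psd(x, rate = rate)
  spectral <- spectral_entropy_from_psd(spec$psd[spec$freq >= 1 & spec$freq < 30])
  tibble::tibble(sample_entropy = sampen, spectral_entropy = spectral)
}

# Normalized Shannon entropy of a (non-negative) power spectrum segment.
spectral_entropy_from_psd <- function(p) {
  tot <- sum(p)
  if (tot <= 0) return(0)
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p))
}

#' Cross-channel correlation
#'
#' Absolute Pearson correlation over all unordered channel pairs of a bin;
#' seizure activity tends to be coherent across neighbouring derivations,
#' so both the maximum and the mean are reported.  Pairs involving a
#' zero-variance channel contribute 0.
#'
#' @param x Channels-by-samples matrix with at least 2 rows.
#'
#' @return One-row tibble: `xcorr_max`, `xcorr_mean`, both in `[0, 1]`.
#' @export
cross_channel_correlation <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L) {
    abort("Cross-channel correlation needs >= 2 channels.",
          class = "szburden_error_input")
  }
  sds <- apply(x, 1, sd)
  nch <- nrow(x)
  r <- matrix(0, nch, nch)
  ok <- which(sds > 0)
  if (length(ok) >= 2) {
    r[ok, ok] <- abs(stats::cor(t(x[ok, , drop = FALSE])))
  }
  vals <- r[upper.tri(r)]
  tibble::tibble(xcorr_max = max(vals), xcorr_mean = mean(vals))
}

#' Full feature vector for one 10-second bin
#'
#' Band-passes the bin to 1-30 Hz, then computes every feature family on
#' the filtered signal: band powers and ratios, morphology, entropies
#' per channel, and cross-channel correlation for the bin as a whole.
#' Deterministic: identical input gives a bitwise-identical result.
#'
#' @param bin_signal Channels-by-samples matrix (one full 10-s bin).
#' @param rate Sampling rate in Hz.
#' @param filter Logical; apply the 1-30 Hz band-pass first (default TRUE).
#'
#' @return A tibble with one row per channel (column `channel` plus all
#'   per-channel features) carrying the bin-level `xcorr_max` / `xcorr_mean`
#'   repeated on every row.
#' @export
extract_features <- function(bin_signal, rate = 250, filter = TRUE) {
  if (!is.matrix(bin_signal)) bin_signal <- matrix(bin_signal, nrow = 1)
  if (!all(is.finite(bin_signal))) {
    abort("Bin signal contains non-finite values.",
          class = "szburden_error_input")
  }
  filt <- if (filter) bandpass_filter(bin_signal, 1, 30, rate) else bin_signal
  ch_names <- rownames(bin_signal)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(bin_signal)))
  bands <- eeg_bands()
  nch <- nrow(filt)
  cols <- c("total_power",
            paste0(rep(bands$band, each = 2), c("_power", "_ratio")),
            "amplitude_rms", "amplitude_p2p", "line_length", "variance",
            "kurtosis", "delta_change", "sample_entropy", "spectral_entropy")
  vals <- matrix(0, nrow = nch, ncol = length(cols),
                 dimnames = list(NULL, cols))
  for (i in seq_len(nch)) {
    v <- filt[i, ]
    spec <- welch_psd(v, rate = rate)
    df <- spec$freq[2] - spec$freq[1]
    in_band <- spec$freq >= 1 & spec$freq < 30
    total <- sum(spec$psd[in_band]) * df
    vals[i, "total_power"] <- total
    for (b in seq_len(nrow(bands))) {
      sel <- spec$freq >= bands$low[b] & spec$freq < bands$high[b]
      p <- sum(spec$psd[sel]) * df
      vals[i, paste0(bands$band[b], "_power")] <- p
      vals[i, paste0(bands$band[b], "_ratio")] <- if (total > 0) p / total else 0
    }
    mo <- morphology_features(v)
    vals[i, c("amplitude_rms", "amplitude_p2p", "line_length", "variance",
              "kurtosis", "delta_change")] <- unlist(mo)
    s <- sd(v)
    vals[i, "sample_entropy"] <-
      if (is.na(s) || s == 0) 0 else .sampen_cpp(v, 2L, 0.2 * s)
    vals[i, "spectral_entropy"] <- spectral_entropy_from_psd(spec$psd[in_band])
  }
  xc <- if (nch >= 2) {
    cross_channel_correlation(filt)
  } else {
    tibble::tibble(xcorr_max = 0, xcorr_mean = 0)
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(channel = ch_names), out)
  out$xcorr_max <- xc$xcorr_max
  out$xcorr_mean <- xc$xcorr_mean
  out
}

#' Feature table for a whole record
#'
#' Segments a record into 10-s bins and extracts the full feature vector
#' for each, returning one row per (bin, channel) — the tidy export format.
#'
#' @param record An [eeg_record()] (bipolar montage).
#' @param rate Ignored; the record's own rate is used.
#'
#' @return Tibble with columns `bin`, `start_s`, `end_s`, `channel`, and
#'   all feature columns.
#' @export
record_features <- function(record, rate = NULL) {
  assert_eeg_record(record)
  bins <- segment_bins(record)
  purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    fv <- extract_features(bins$signal[[i]], rate = record$rate)
    dplyr::bind_cols(
      tibble::tibble(bin = bins$bin[i], start_s = bins$start_s[i],
                     end_s = bins$end_s[i])[rep(1, nrow(fv)), ],
      fv
    )
  })
}
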