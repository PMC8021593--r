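test_that("record construction validates its invariants", {
  x <- matrix(rnorm(500), nrow = 2)
  rec <- eeg_record(x, rate = 250)
  expect_equal(rec$duration * rec$rate, ncol(x))
  expect_error(eeg_record(x, rate = 0), class = "szburden_error_input")
  expect_error(eeg_record(matrix(numeric(0), nrow = 0, ncol = 10), 250),
               class = "szburden_error_empty")
  expect_error(eeg_record(x, 250, channel_names = "only-one"),
               class = "szburden_error_input")
})

test_that("layout has 10 electrodes and 8 within-chain pairs", {
  lay <- headband_layout()
  expect_length(lay$labels, 10)
  expect_equal(nrow(lay$pairs), 8)
  # each pair is two distinct electrodes from the same chain
  left <- lay$labels[1:5]
  for (i in seq_len(8)) {
    a <- lay$pairs$anterior[i]; p <- lay$pairs$posterior[i]
    expect_true(a != p)
    expect_equal(a %in% left, p %in% left)
  }
  expect_error(headband_layout(paste0("E", 1:9)),
               class = "szburden_error_input")
})

test_that("bipolar montage subtracts adjacent electrodes", {
  lay <- headband_layout()
  # identical waveform everywhere -> exact cancellation
  wave <- sine_wave(7, seconds = 2)
  rec <- eeg_record(matrix(rep(wave, 10), nrow = 10, byrow = TRUE,
                           dimnames = list(lay$labels)), 250)
  bip <- build_bipolar_montage(rec, lay)
  expect_equal(nrow(bip$samples), 8)
  expect_true(all(bip$samples == 0))

  # constant potentials -> constant difference
  x <- matrix(0, nrow = 10, ncol = 500, dimnames = list(lay$labels))
  x["E1", ] <- 5; x["E2", ] <- 2
  bip2 <- build_bipolar_montage(eeg_record(x, 250), lay)
  expect_true(all(bip2$samples["E1-E2", ] == 3))
  expect_equal(bip2$channel_names[1], "E1-E2")

  # missing electrode
  bad <- eeg_record(x[1:9, ], 250)
  expect_error(build_bipolar_montage(bad, lay),
               class = "szburden_error_channel_mismatch")
})

test_that("montage is linear in the input", {
  lay <- headband_layout()
  rec <- referential_record(seconds = 2)
  a <- 3.7
  scaled <- eeg_record(a * rec$samples, rec$rate)
  expect_equal(build_bipolar_montage(scaled, lay)$samples,
               a * build_bipolar_montage(rec, lay)$samples)
})

test_that("segmentation yields full 10-s bins and drops the tail", {
  rec <- noise_record(n_ch = 2, seconds = 300)
  bins <- segment_bins(rec)
  expect_equal(nrow(bins), 30)
  expect_true(all(vapply(bins$signal, ncol, integer(1)) == 2500))
  expect_equal(bins$start_s, 10 * (0:29))
  expect_equal(bins$end_s, 10 * (1:30))

  rec305 <- noise_record(n_ch = 2, seconds = 305)
  expect_equal(nrow(segment_bins(rec305)), 30)

  rec9 <- eeg_record(matrix(rnorm(2 * 9 * 250), nrow = 2), 250)
  expect_error(segment_bins(rec9), class = "szburden_error_too_short")
})

test_that("concatenating bin slices reconstructs the record minus the tail", {
  rec <- noise_record(n_ch = 3, seconds = 35, seed = 4)
  bins <- segment_bins(rec)
  rebuilt <- do.call(cbind, bins$signal)
  expect_identical(rebuilt, rec$samples[, 1:7500])
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  rec <- noise_record(n_ch = 8, seconds = 60, sd = 40, seed = 9)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$rate, 250)
  expect_equal(back$duration, 60)
  expect_equal(ncol(back$samples), 15000)
  expect_equal(back$channel_names, rec$channel_names)
  # quantization step is 0.1 uV over +/-3276.7
  expect_lt(max(abs(back$samples - rec$samples)), 0.1)
})

test_that("EDF reader resamples other rates to 250 Hz", {
  # 500 Hz record carrying a 10 Hz tone
  wave <- sine_wave(10, seconds = 20, rate = 500, amplitude = 50)
  rec500 <- eeg_record(matrix(rep(wave, 2), nrow = 2, byrow = TRUE), 500)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec500, path)
  back <- read_edf(path, target_rate = 250)
  expect_equal(back$rate, 250)
  expect_equal(back$duration, 20)         # duration unchanged
  expect_equal(ncol(back$samples), 5000)  # sample count halves
  # band content below Nyquist preserved: the tone survives with its
  # power intact and still dominates the alpha band
  mid <- back$samples[1, 500:4500]    # ignore resampler edge effects
  expect_equal(sqrt(mean(mid^2)), 50 / sqrt(2), tolerance = 0.05)
  expect_gte(band_powers(back$samples[1, 251:2750])$alpha_ratio, 0.95)
})

test_that("unreadable or truncated files raise a format error", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", path)
  expect_error(read_edf(path), class = "szburden_error_format")
  expect_error(read_edf(file.path(tempdir(), "does-not-exist.edf")),
               class = "szburden_error_format")
})

test_that("annotation sidecars round-trip", {
  ann <- annotation_set("SE", tibble::tibble(
    onset_s = c(60, 400), duration_s = c(320, 45),
    label = c("seizure", "seizure")
  ))
  path <- withr::local_tempfile(fileext = ".ann")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$category, "SE")
  expect_equal(back$events$onset_s, c(60, 400))
  expect_equal(back$events$duration_s, c(320, 45))
  expect_error(annotation_set("bogus"), class = "szburden_error_input")
})

test_that("an independent EDF reader agrees with the writer", {
  # cross-check the hand-written EDF writer against MNE-Python, when the
  # interpreter and library are available on PATH
  py <- Sys.which("python")
  skip_if(py == "", "no python interpreter")
  has_mne <- system2(py, c("-c", shQuote("import mne")),
                     stdout = FALSE, stderr = FALSE)
  skip_if(has_mne != 0, "python lacks mne")
  rec <- noise_record(n_ch = 4, seconds = 10, sd = 30, seed = 21)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  out <- system2(py, c("-c", shQuote(paste0(
    "import mne, numpy as np; ",
    "raw = mne.io.read_raw_edf('", path, "', verbose='ERROR'); ",
    "d = raw.get_data() * 1e6; ",  # volts back to uV
    "print(d.shape[0], d.shape[1], np.round(float(raw.info['sfreq']),3), ",
    "np.round(float(np.max(np.abs(d))),3))"
  ))), stdout = TRUE)
  parts <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(parts[1], 4)
  expect_equal(parts[2], 2500)
  expect_equal(parts[3], 250)
  expect_equal(parts[4], max(abs(rec$samples)), tolerance = 0.01)
})
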