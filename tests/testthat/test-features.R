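test_that("band-pass filter attenuates stop band, passes pass band, kills DC", {
  rms <- function(v) sqrt(mean(v^2))
  hum <- sine_wave(60)
  expect_lt(rms(bandpass_filter(hum)), 0.05 * rms(hum))
  alpha <- sine_wave(10)
  expect_lt(abs(rms(bandpass_filter(alpha)) - rms(alpha)) / rms(alpha), 0.05)
  dc <- rep(100, 2500)
  expect_lt(abs(mean(bandpass_filter(dc))), 1e-9)
  expect_error(bandpass_filter(alpha, low = 30, high = 10),
               class = "szburden_error_parameter")
  expect_error(bandpass_filter(alpha, low = 1, high = 200),
               class = "szburden_error_parameter")
})

test_that("a 10 Hz unit sinusoid has alpha-dominated spectrum of total power 0.5", {
  x <- sine_wave(10)
  bp <- band_powers(x)
  expect_gte(bp$alpha_ratio, 0.95)
  # Parseval: a unit-amplitude sinusoid has mean square 1/2
  expect_lt(abs(bp$total_power - 0.5) / 0.5, 0.05)
})

test_that("white-noise band ratios are proportional to band widths", {
  # flat spectrum in 1-30 Hz: expected ratio = bandwidth / 29
  n_bins <- 200
  ratios <- withr::with_seed(42, {
    t(vapply(seq_len(n_bins), function(i) {
      bp <- band_powers(rnorm(2500))
      c(bp$delta_ratio, bp$theta_ratio, bp$alpha_ratio, bp$beta_ratio)
    }, numeric(4)))
  })
  expected <- c(3, 4, 5, 17) / 29
  for (b in 1:4) {
    se <- sd(ratios[, b]) / sqrt(n_bins)
    expect_lt(abs(mean(ratios[, b]) - expected[b]), 3 * se)
  }
})

test_that("morphology features match their definitions", {
  const <- rep(-4, 2500)
  m <- morphology_features(const)
  expect_equal(m$amplitude_rms, 4)
  expect_equal(m$amplitude_p2p, 0)
  expect_equal(m$line_length, 0)
  expect_equal(m$kurtosis, 0)      # degenerate convention
  expect_equal(m$delta_change, 1)  # 0-variance halves have equal RMS

  saw <- seq(0, 1, length.out = 2500)
  expect_equal(morphology_features(saw)$line_length, 1, tolerance = 1e-9)

  # second half exactly twice the first half
  half_doubled <- c(rep(1, 1250), rep(2, 1250)) * sine_wave(5)
  expect_equal(morphology_features(half_doubled)$delta_change, 2,
               tolerance = 1e-12)
})

test_that("entropies separate rhythmic from irregular signals", {
  sine <- sine_wave(10)
  e_sine <- entropy_features(sine)
  expect_lte(e_sine$spectral_entropy, 0.3)

  # noise has higher sample entropy than a sinusoid in >= 99/100 seeded draws
  wins <- withr::with_seed(7, {
    sum(vapply(1:100, function(i) {
      entropy_features(rnorm(2500))$sample_entropy > e_sine$sample_entropy
    }, logical(1)))
  })
  expect_gte(wins, 99)

  e_const <- entropy_features(rep(3, 2500))
  expect_equal(e_const$sample_entropy, 0)
  expect_equal(e_const$spectral_entropy, 0)
})

test_that("sample entropy agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  withr::with_seed(13, {
    for (x in list(rnorm(300), sine_wave(4, seconds = 2, rate = 150) + rnorm(300, sd = 0.3))) {
      r <- 0.2 * sd(x)
      expect_equal(szburden:::.sampen_cpp(x, 2L, r),
                   pracma::sample_entropy(x, edim = 2, r = r),
                   tolerance = 1e-10)
    }
  })
})

test_that("cross-channel correlation hits its extremes", {
  v <- sine_wave(6)
  same <- rbind(v, v, v)
  xc <- cross_channel_correlation(same)
  expect_equal(xc$xcorr_max, 1)
  expect_equal(xc$xcorr_mean, 1)

  opp <- rbind(v, -v)
  expect_equal(cross_channel_correlation(opp)$xcorr_max, 1)

  zero_var <- rbind(v, rep(0, 2500))
  expect_equal(cross_channel_correlation(zero_var)$xcorr_max, 0)

  low <- withr::with_seed(3, {
    vapply(1:100, function(i) {
      cross_channel_correlation(matrix(rnorm(2 * 2500), nrow = 2))$xcorr_mean
    }, numeric(1))
  })
  expect_gte(sum(low < 0.1), 99)

  expect_error(cross_channel_correlation(matrix(v, nrow = 1)),
               class = "szburden_error_input")
})

test_that("feature extraction is deterministic and handles degenerate input", {
  bins <- simulated_bins()
  f1 <- extract_features(bins$background)
  f2 <- extract_features(bins$background)
  expect_identical(f1, f2)

  zero <- extract_features(matrix(0, nrow = 8, ncol = 2500))
  expect_true(all(zero$total_power == 0))
  expect_true(all(zero$line_length == 0))
  expect_true(all(zero$sample_entropy == 0))
  expect_true(all(zero$delta_change == 1))
  expect_true(all(zero$xcorr_max == 0))

  expect_error(extract_features(matrix(c(1, NA, 1, 1), nrow = 2)),
               class = "szburden_error_input")
})

test_that("ictal bins differ from background in the expected directions", {
  bins <- simulated_bins()
  bg <- extract_features(bins$background)
  ict <- extract_features(bins$ictal)
  expect_gt(mean(ict$line_length), mean(bg$line_length))
  expect_gt(ict$xcorr_max[1], bg$xcorr_max[1])
  expect_lt(mean(ict$sample_entropy), mean(bg$sample_entropy))
})

test_that("features obey amplitude-scaling covariance", {
  bins <- simulated_bins()
  x <- bins$background
  a <- 2.5
  f <- extract_features(x)
  fa <- extract_features(a * x)
  expect_equal(fa$amplitude_rms, a * f$amplitude_rms, tolerance = 1e-8)
  expect_equal(fa$amplitude_p2p, a * f$amplitude_p2p, tolerance = 1e-8)
  expect_equal(fa$line_length, a * f$line_length, tolerance = 1e-8)
  expect_equal(fa$variance, a^2 * f$variance, tolerance = 1e-8)
  expect_equal(fa$kurtosis, f$kurtosis, tolerance = 1e-6)
  expect_equal(fa$alpha_ratio, f$alpha_ratio, tolerance = 1e-8)
  expect_equal(fa$sample_entropy, f$sample_entropy, tolerance = 1e-8)
  expect_equal(fa$spectral_entropy, f$spectral_entropy, tolerance = 1e-8)
  expect_equal(fa$xcorr_max, f$xcorr_max, tolerance = 1e-6)
})

test_that("band powers sum to at most the total 1-30 Hz power", {
  bins <- simulated_bins()
  f <- extract_features(bins$ictal)
  band_sum <- f$delta_power + f$theta_power + f$alpha_power + f$beta_power
  expect_true(all(band_sum <= f$total_power * 1.02))
})

test_that("features are invariant to channel-wise DC offsets", {
  bins <- simulated_bins()
  x <- bins$background
  shifted <- x + matrix(seq(10, 80, by = 10), nrow = 8, ncol = ncol(x))
  f <- extract_features(x)
  fs <- extract_features(shifted)
  expect_equal(fs$amplitude_rms, f$amplitude_rms, tolerance = 1e-3)
  expect_equal(fs$total_power, f$total_power, tolerance = 1e-3)
  expect_equal(fs$xcorr_max, f$xcorr_max, tolerance = 1e-3)
})

test_that("record_features exports one row per bin and channel", {
  rec <- noise_record(n_ch = 3, seconds = 30, seed = 2)
  ft <- record_features(rec)
  expect_equal(nrow(ft), 3 * 3)
  expect_true(all(c("bin", "channel", "line_length", "xcorr_max") %in% names(ft)))
})
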