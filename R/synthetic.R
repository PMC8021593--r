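#' Simulation specification for one synthetic EEG record
#'
#' Describes one synthetic 8-channel, 250 Hz recording in one of the five
#' study categories: `NL` normal (posterior-dominant alpha over pink
#' noise), `SL` diffusely slow (1-3 Hz delta replacing the alpha), `HEP`
#' highly epileptiform (lateralized periodic sharp transients), `SZ`
#' seizure (every ictal interval shorter than 5 min) and `SE` status
#' epilepticus (at least one ictal interval of 5 min or longer).  Ictal
#' intervals superimpose rhythmic activity whose frequency and amplitude
#' evolve linearly, spread coherently across channels.  All signal recipes
#' are documented stand-ins aimed at feature-level separability, not
#' clinical realism.
#'
#' @param category One of `"NL"`, `"SL"`, `"HEP"`, `"SZ"`, `"SE"`.
#' @param duration_s Record duration in seconds (whole number).
#' @param seed Integer seed; all randomness in [simulate_record()] flows
#'   from it.
#' @param seizure_intervals Tibble with one row per ictal interval:
#'   `start_s`, `end_s` (half-open, within the record, nonoverlapping),
#'   `onset_freq_hz`, `amplitude_uv`, `freq_slope_hz_per_min`,
#'   `amp_slope_uv_per_min`.  Defaults depend on the category.
#' @param hep_rate_hz Periodic-discharge rate for HEP records (0.5-2 Hz).
#' @param alpha_freq_hz,alpha_amp_uv Posterior alpha rhythm (NL only).
#' @param delta_amp_uv Diffuse delta amplitude (SL only).
#' @param pink_amp_uv RMS of the 1/f background on every channel.
#' @param noise_sd_uv SD of additive white sensor noise.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(category,
                            duration_s = 600,
                            seed = 1L,
                            seizure_intervals = NULL,
                            hep_rate_hz = 1,
                            alpha_freq_hz = 9.5,
                            alpha_amp_uv = 15,
                            delta_amp_uv = 20,
                            pink_amp_uv = 12,
                            noise_sd_uv = 3) {
  if (!category %in% c("NL", "SL", "HEP", "SZ", "SE")) {
    abort("Category must be one of NL, SL, HEP, SZ, SE.",
          class = "szburden_error_input")
  }
  if (hep_rate_hz < 0.5 || hep_rate_hz > 2) {
    abort("`hep_rate_hz` must lie in [0.5, 2].",
          class = "szburden_error_input")
  }
  if (is.null(seizure_intervals)) {
    seizure_intervals <- default_seizure_intervals(category, duration_s)
  }
  seizure_intervals <- tibble::as_tibble(seizure_intervals)
  if (nrow(seizure_intervals) > 0) {
    si <- seizure_intervals[order(seizure_intervals$start_s), ]
    if (any(si$start_s < 0) || any(si$end_s > duration_s) ||
        any(si$end_s <= si$start_s)) {
      abort("Seizure intervals must be half-open, within [0, duration).",
            class = "szburden_error_input")
    }
    if (nrow(si) > 1 && any(si$start_s[-1] < si$end_s[-nrow(si)])) {
      abort("Seizure intervals overlap.", class = "szburden_error_input")
    }
  }
  durs <- seizure_intervals$end_s - seizure_intervals$start_s
  if (category == "SE" && !any(durs >= 300)) {
    abort("SE records need at least one ictal interval of >= 300 s.",
          class = "szburden_error_input")
  }
  if (category == "SZ" && (nrow(seizure_intervals) == 0 || any(durs >= 300))) {
    abort("SZ records need ictal intervals, all shorter than 300 s.",
          class = "szburden_error_input")
  }
  if (category %in% c("NL", "SL", "HEP") && nrow(seizure_intervals) > 0) {
    abort("Only SZ/SE records carry ictal intervals.",
          class = "szburden_error_input")
  }
  structure(
    list(category = category, duration_s = duration_s, seed = as.integer(seed),
         seizure_intervals = seizure_intervals, hep_rate_hz = hep_rate_hz,
         alpha_freq_hz = alpha_freq_hz, alpha_amp_uv = alpha_amp_uv,
         delta_amp_uv = delta_amp_uv, pink_amp_uv = pink_amp_uv,
         noise_sd_uv = noise_sd_uv),
    class = "simulation_spec"
  )
}

empty_intervals <- function() {
  tibble::tibble(start_s = numeric(), end_s = numeric(),
                 onset_freq_hz = numeric(), amplitude_uv = numeric(),
                 freq_slope_hz_per_min = numeric(),
                 amp_slope_uv_per_min = numeric())
}

default_seizure_intervals <- function(category, duration_s) {
  if (category == "SZ") {
    # one 2-min electrographic seizure in mid-record (shorter records get
    # a proportionally shorter seizure, never under 30 s)
    len <- min(120, max(30, round(duration_s / 3)))
    s <- min(round(duration_s * 0.3), duration_s - len)
    tibble::tibble(start_s = s, end_s = s + len,
                   onset_freq_hz = 4, amplitude_uv = 70,
                   freq_slope_hz_per_min = -0.5, amp_slope_uv_per_min = 5)
  } else if (category == "SE") {
    # one 6-min run of continuous seizure activity (or as long as the
    # record allows while staying a valid SE, i.e. >= 300 s)
    len <- min(360, duration_s - 20)
    s <- max(0, round((duration_s - len) / 2))
    tibble::tibble(start_s = s, end_s = s + len,
                   onset_freq_hz = 3.5, amplitude_uv = 70,
                   freq_slope_hz_per_min = -0.3, amp_slope_uv_per_min = 3)
  } else {
    empty_intervals()
  }
}

# Evaluate `code` with the RNG seeded to `seed`, restoring global RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# 1/f ("pink") noise, unit SD.
pink_noise <- function(n) {
  white <- stats::fft(rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)           # frequency bin magnitude
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(white * scale, inverse = TRUE)) / n
  x / sd(x)
}

# Smoothed biphasic sharp transient (unit peak), ~140 ms long at 250 Hz.
sharp_transient <- function(rate) {
  t <- seq(-0.07, 0.07, by = 1 / rate)
  w <- -t / 0.02 * exp(-(t / 0.02)^2 / 2)
  w / max(abs(w))
}

#' Simulate one synthetic EEG record
#'
#' Generates the 8-channel bipolar record and its ground-truth annotations
#' from a [simulation_spec()].  Bitwise deterministic for a fixed spec:
#' the same spec (including seed) always yields the identical record.
#'
#' @param spec A [simulation_spec()].
#'
#' @return A list with elements `record` (an [eeg_record()]) and
#'   `annotations` (an [annotation_set()] carrying the exact ictal
#'   interval times).
#' @export
#' @examples
#' rec <- simulate_record(simulation_spec("NL", duration_s = 60, seed = 42))
#' rec$record
simulate_record <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  rate <- 250
  n <- as.integer(round(spec$duration_s * rate))
  n_ch <- 8L
  layout <- headband_layout()
  t <- (seq_len(n) - 1L) / rate

  with_local_seed(spec$seed, {
    x <- matrix(0, nrow = n_ch, ncol = n)
    # 1/f background + sensor noise on every channel
    for (c in seq_len(n_ch)) {
      x[c, ] <- spec$pink_amp_uv * pink_noise(n) +
        rnorm(n, sd = spec$noise_sd_uv)
    }
    # position within each lateral chain (1 anterior ... 4 posterior)
    chain_pos <- rep(1:4, 2)

    if (spec$category == "NL") {
      post_w <- c(0.4, 0.55, 0.75, 1.0)[chain_pos]
      env <- 1 + 0.3 * slow_modulation(n, rate)
      alpha <- sin(2 * pi * spec$alpha_freq_hz * t + runif(1, 0, 2 * pi)) * env
      for (c in seq_len(n_ch)) {
        x[c, ] <- x[c, ] + spec$alpha_amp_uv * post_w[c] * alpha
      }
    }
    if (spec$category == "SL") {
      # diffuse polymorphic delta, 1-3 Hz
      freq <- 2 + 0.8 * slow_modulation(n, rate)
      phase <- cumsum(2 * pi * pmax(freq, 0.8) / rate)
      delta <- sin(phase + runif(1, 0, 2 * pi)) * (1 + 0.2 * slow_modulation(n, rate))
      for (c in seq_len(n_ch)) {
        x[c, ] <- x[c, ] + spec$delta_amp_uv * runif(1, 0.8, 1.1) * delta
      }
    }
    if (spec$category == "HEP") {
      # lateralized periodic discharges over the left chain
      w <- sharp_transient(rate)
      ch_weights <- c(1, 0.8, 0.5, 0.3, 0, 0, 0, 0)
      period <- 1 / spec$hep_rate_hz
      times <- seq(0.5, spec$duration_s - 0.5, by = period)
      times <- times + runif(length(times), -0.05, 0.05) * period
      amps <- 80 * runif(length(times), 0.8, 1.2)
      spike_train <- numeric(n)
      half <- (length(w) - 1L) %/% 2L
      for (i in seq_along(times)) {
        center <- as.integer(round(times[i] * rate))
        lo <- center - half
        hi <- lo + length(w) - 1L
        if (lo >= 1L && hi <= n) {
          spike_train[lo:hi] <- spike_train[lo:hi] + amps[i] * w
        }
      }
      for (c in seq_len(n_ch)) {
        if (ch_weights[c] > 0) x[c, ] <- x[c, ] + ch_weights[c] * spike_train
      }
    }
    si <- spec$seizure_intervals
    for (i in seq_len(nrow(si))) {
      i0 <- as.integer(round(si$start_s[i] * rate)) + 1L
      i1 <- as.integer(round(si$end_s[i] * rate))
      tt <- (seq(i0, i1) - i0) / rate          # seconds since onset
      freq <- si$onset_freq_hz[i] + si$freq_slope_hz_per_min[i] * tt / 60
      freq <- pmin(pmax(freq, 1), 29)
      phase <- cumsum(2 * pi * freq / rate)
      amp <- si$amplitude_uv[i] + si$amp_slope_uv_per_min[i] * tt / 60
      dur <- max(tt)
      ramp <- pmin(1, tt / 5) * pmin(1, (dur - tt) / 5)   # 5-s on/off ramps
      wave <- (sin(phase) + 0.35 * sin(2 * phase + 0.8)) * pmax(amp, 0) * ramp
      gains <- runif(n_ch, 0.7, 1.2)
      for (c in seq_len(n_ch)) {
        x[c, i0:i1] <- x[c, i0:i1] + gains[c] * wave
      }
    }
    record <- eeg_record(x, rate = rate, channel_names = layout$pairs$name)
    events <- if (nrow(si) > 0) {
      tibble::tibble(onset_s = si$start_s,
                     duration_s = si$end_s - si$start_s,
                     label = "seizure")
    } else if (spec$category == "HEP") {
      tibble::tibble(onset_s = 0, duration_s = spec$duration_s, label = "hep")
    } else if (spec$category == "SL") {
      tibble::tibble(onset_s = 0, duration_s = spec$duration_s, label = "slow")
    } else {
      tibble::tibble(onset_s = 0, duration_s = spec$duration_s, label = "normal")
    }
    category <- switch(spec$category, SE = "SE", SZ = "SZ", HEP = "HEP",
                       "NL/SL")
    list(record = record, annotations = annotation_set(category, events))
  })
}

# Smooth random modulation in [-1, 1]-ish range at ~0.1 Hz.
slow_modulation <- function(n, rate) {
  n_knots <- max(4L, as.integer(ceiling(n / rate / 10)) + 2L)
  knots <- rnorm(n_knots)
  approx(seq(0, 1, length.out = n_knots), knots,
         xout = seq(0, 1, length.out = n))$y
}

#' Simulate a cohort of synthetic records
#'
#' Expands per-category counts into a deterministic cohort manifest; each
#' record's seed is derived from the master seed, so the whole cohort is
#' reproducible and records can be generated lazily one at a time with
#' [simulate_record()].
#'
#' @param counts Named integer vector with any of `SE`, `SZ`, `HEP`, `NL`,
#'   `SL` (e.g. `c(SE = 2, SZ = 2, HEP = 5, NL = 6, SL = 5)`).
#' @param duration_s Per-record duration in seconds.
#' @param master_seed Integer master seed.
#'
#' @return A tibble manifest: `record_id`, `category` (simulation
#'   category), `duration_s`, `seed`, and a list-column `spec` of
#'   [simulation_spec()] objects.
#' @export
simulate_cohort <- function(counts, duration_s = 600, master_seed = 1L) {
  valid <- c("SE", "SZ", "HEP", "NL", "SL")
  if (length(counts) == 0 || is.null(names(counts)) ||
      !all(names(counts) %in% valid) || any(counts < 0)) {
    abort("`counts` must be a named vector over SE, SZ, HEP, NL, SL with counts >= 0.",
          class = "szburden_error_input")
  }
  cats <- rep(names(counts), times = counts)
  n <- length(cats)
  if (n == 0) {
    return(tibble::tibble(record_id = character(), category = character(),
                          duration_s = numeric(), seed = integer(),
                          spec = list()))
  }
  seeds <- as.integer((as.numeric(master_seed) * 10007 +
                         seq_len(n) * 7919) %% 2147483647)
  specs <- purrr::map(seq_len(n), function(i) {
    simulation_spec(cats[i], duration_s = duration_s, seed = seeds[i])
  })
  tibble::tibble(
    record_id = sprintf("sim%03d", seq_len(n)),
    category = cats,
    duration_s = duration_s,
    seed = seeds,
    spec = specs
  )
}
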