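# Shared fixtures, all generated in code.

sine_wave <- function(freq, seconds = 10, rate = 250, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (seq_len(seconds * rate) - 1) / rate + phase)
}

# n_ch channels of seeded white noise as an eeg_record
noise_record <- function(n_ch = 8, seconds = 60, rate = 250, sd = 15, seed = 1) {
  withr::with_seed(seed, {
    eeg_record(matrix(rnorm(n_ch * seconds * rate, sd = sd), nrow = n_ch),
               rate = rate)
  })
}

# referential 10-electrode record for montage tests
referential_record <- function(seconds = 10, rate = 250, seed = 1) {
  lay <- headband_layout()
  withr::with_seed(seed, {
    eeg_record(matrix(rnorm(10 * seconds * rate), nrow = 10,
                      dimnames = list(lay$labels)), rate = rate)
  })
}

# one simulated ictal and one background 10-s bin (bipolar, 8 ch)
simulated_bins <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_record(simulation_spec("SE", duration_s = 600, seed = 11))
      bins <- segment_bins(sim$record)
      cache <<- list(
        background = bins$signal[[3]],   # bin 2, before the seizure
        ictal = bins$signal[[30]],       # bin 29, mid-seizure
        record = sim$record,
        annotations = sim$annotations
      )
    }
    cache
  }
})
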