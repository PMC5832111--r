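# shared small fixtures, built in code

# a flat-gain profile responding identically at all four targets
flat_profile <- function(id = "S01", gain = 5, harmonic_ratio = 0.3,
                         n_channels = 8) {
  subject_profile(id,
                  gain = c(`8.5` = gain, `10` = gain, `12` = gain,
                           `15` = gain),
                  harmonic_ratio = harmonic_ratio,
                  channel_weights = rep(1, n_channels))
}

# noiseless single-target segment
tone_segment <- function(f, duration = 10, fs = 250, seed = 1,
                         harmonic_ratio = 0.3, jitter_mean = 1,
                         jitter_sd = 0) {
  generate_segment(flat_profile(harmonic_ratio = harmonic_ratio),
                   stimulus_schedule(f, jitter_mean = jitter_mean,
                                     jitter_sd = jitter_sd),
                   noise_model(0, 0), duration = duration, fs = fs,
                   seed = seed)
}

# raw sinusoid wrapped as a segment (for filter tests)
sine_segment <- function(f, duration = 10, fs = 250, n_channels = 1,
                         amp = 1) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  eeg_segment(matrix(rep(amp * sin(2 * pi * f * t), n_channels),
                     ncol = n_channels), fs)
}

# small labeled dataset + per-frame features, computed once and cached for
# the gmm / decode / transform tests
small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(random_profiles(3, seed = 11),
                             lapply(c(8.5, 10, 12, 15), stimulus_schedule),
                             trials_per_frequency = 3, snr = 6,
                             duration = 5, seed = 42)
      ds <- preprocess_dataset(ds)
      cache <<- extract_features(ds)
    }
    cache
  }
})

rms <- function(x) sqrt(mean(x^2))
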