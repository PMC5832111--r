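#' Subject response profile for the synthetic SSVEP generator
#'
#' Describes how one subject responds to flickering stimuli: the amplitude
#' and phase of the fundamental steady-state response at each target
#' frequency, the relative strength of the second harmonic, the spatial
#' distribution of the response over channels, and subject-specific
#' "off-target" responses - low-amplitude peaks at non-stimulated
#' frequencies, the kind of idiosyncratic structure that makes SSVEP score
#' curves informative about subject identity.
#'
#' @param subject_id Subject identifier string.
#' @param gain Named numeric vector of fundamental amplitudes (microvolts),
#'   one per target frequency; names are the frequencies in Hz (e.g. "10").
#' @param harmonic_ratio Amplitude of the 2nd harmonic relative to the
#'   fundamental, in `[0, 1]`.
#' @param phase Named numeric vector of response phases (radians), same
#'   names as `gain`.
#' @param channel_weights Nonnegative spatial mixing vector (length = number
#'   of channels, 8 by default); at least one entry must be positive.
#' @param offtarget_response Named numeric vector mapping non-target
#'   frequencies (Hz, as names) to amplitudes (microvolts). May be empty.
#'
#' @return An object of class `subject_profile`.
#' @seealso [random_profiles()] to draw a population of distinct profiles.
#' @export
subject_profile <- function(subject_id,
                            gain,
                            harmonic_ratio = 0.3,
                            phase = setNames(numeric(length(gain)), names(gain)),
                            channel_weights = c(1, 0.9, 0.8, 0.7, 0.5, 0.4, 0.3, 0.2),
                            offtarget_response = numeric(0)) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (is.null(names(gain)) || any(names(gain) == "")) {
    stop("`gain` must be named by target frequency (Hz)")
  }
  if (any(gain < 0)) stop("amplitudes in `gain` must be >= 0")
  if (harmonic_ratio < 0 || harmonic_ratio > 1) {
    stop("`harmonic_ratio` must lie in [0, 1]")
  }
  if (any(channel_weights < 0) || !any(channel_weights > 0)) {
    stop("`channel_weights` must be nonnegative with at least one positive entry")
  }
  if (length(offtarget_response) &&
      (is.null(names(offtarget_response)) || any(offtarget_response < 0))) {
    stop("`offtarget_response` must be a named nonnegative vector")
  }
  structure(
    list(subject_id = subject_id, gain = gain,
         harmonic_ratio = harmonic_ratio, phase = phase,
         channel_weights = channel_weights,
         offtarget_response = offtarget_response),
    class = "subject_profile"
  )
}

#' Draw a population of distinct subject profiles
#'
#' Samples `n` subject profiles with subject-specific gains, phases, spatial
#' weights and off-target signatures. Off-target peaks are placed at
#' frequencies drawn from the analysis band away from the targets, so that
#' subject identity is expressed across the whole 7-17 Hz score curve and
#' not only at the stimulated frequencies.
#'
#' @param n Number of subjects.
#' @param frequencies Target frequencies (Hz).
#' @param n_channels Number of EEG channels.
#' @param gain_range Range (microvolts) for fundamental amplitudes.
#' @param n_offtarget Number of off-target peaks per subject.
#' @param offtarget_gain_frac Off-target amplitude as a fraction of the
#'   subject's mean gain (a range to sample from).
#' @param seed Integer seed; the draw is deterministic given the seed.
#'
#' @return A list of [subject_profile()] objects with ids "S01", "S02", ...
#' @export
random_profiles <- function(n,
                            frequencies = c(8.5, 10, 12, 15),
                            n_channels = 8,
                            gain_range = c(3, 6),
                            n_offtarget = 3,
                            offtarget_gain_frac = c(0.25, 0.6),
                            seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      gains <- stats::runif(length(frequencies), gain_range[1], gain_range[2])
      names(gains) <- as.character(frequencies)
      phases <- stats::runif(length(frequencies), 0, 2 * pi)
      names(phases) <- names(gains)
      w <- stats::runif(n_channels, 0.05, 1)
      # candidate off-target locations: band interior, >= 0.7 Hz from targets
      cand <- seq(7.5, 16.5, by = 0.5)
      cand <- cand[vapply(cand, function(f) min(abs(f - frequencies)) >= 0.7,
                          logical(1))]
      off_f <- sample(cand, min(n_offtarget, length(cand)))
      off_a <- mean(gains) * stats::runif(length(off_f),
                                          offtarget_gain_frac[1],
                                          offtarget_gain_frac[2])
      names(off_a) <- as.character(off_f)
      subject_profile(sprintf("S%02d", i), gain = gains,
                      harmonic_ratio = stats::runif(1, 0.2, 0.5),
                      phase = phases, channel_weights = w,
                      offtarget_response = off_a)
    })
  })
}

#' Stimulus schedule with flicker-period jitter
#'
#' A flickering stimulus at `target_frequency` Hz has nominal period
#' `1000 / target_frequency` ms. Rendering on a tablet screen with a limited
#' refresh rate realises each epoch (a ~2.5 s stretch of a trial) with a
#' slightly wrong average period; the jitter model captures this as a
#' per-epoch multiplicative period error: realised period =
#' nominal * r_e with r_e ~ Normal(`jitter_mean[e]`, `jitter_sd`).
#'
#' @param target_frequency Target frequency in Hz.
#' @param epoch_length Epoch duration in seconds (2.5 s default, four epochs
#'   per 10 s trial).
#' @param jitter_mean Per-epoch mean multiplicative period error (unitless;
#'   recycled over epochs). 1 means no systematic deviation.
#' @param jitter_sd Standard deviation of the per-epoch multiplicative error.
#'
#' @return An object of class `stimulus_schedule` with fields
#'   `target_frequency`, `nominal_period` (ms), `epoch_length`,
#'   `jitter_mean`, `jitter_sd`.
#' @seealso [jitter_measured()] for the measured tablet-rendering deviations.
#' @export
#' @examples
#' stimulus_schedule(8.5)$nominal_period  # 117.647... ms
stimulus_schedule <- function(target_frequency,
                              epoch_length = 2.5,
                              jitter_mean = 1,
                              jitter_sd = 0) {
  stopifnot(target_frequency > 0, epoch_length > 0, jitter_sd >= 0,
            all(jitter_mean > 0))
  structure(
    list(target_frequency = target_frequency,
         nominal_period = 1000 / target_frequency,
         epoch_length = epoch_length,
         jitter_mean = jitter_mean, jitter_sd = jitter_sd),
    class = "stimulus_schedule"
  )
}

# Measured average display periods (ms) over four consecutive 2.5 s epochs
# of a 10 s trial, per target frequency, for a tablet-rendered stimulus.
.measured_epoch_periods <- list(
  `8.5` = c(115.7391, 116.913, 116.6957, 113.2083),
  `10`  = c(98.92308, 100.1923, 100.1154, 100.1538),
  `12`  = c(82.125, 83.5, 83.40625, 83.40625),
  `15`  = c(65.71795, 66.79487, 66.69231, 65.95)
)

#' Measured tablet-rendering period jitter
#'
#' Per-epoch multiplicative period errors measured for tablet-rendered
#' flicker at the four target frequencies: the realised average display
#' period of each 2.5 s epoch divided by the nominal period. Use as
#' `jitter_mean` in [stimulus_schedule()] to emulate a realistically
#' imprecise stimulus.
#'
#' @param target_frequency One of 8.5, 10, 12, 15 (Hz).
#' @return Numeric vector of four per-epoch period ratios (realised/nominal).
#' @export
#' @examples
#' jitter_measured(8.5)  # all below 1: the tablet renders 8.5 Hz slightly fast
jitter_measured <- function(target_frequency) {
  key <- as.character(target_frequency)
  if (!key %in% names(.measured_epoch_periods)) {
    stop("measured jitter is available for 8.5, 10, 12 and 15 Hz only")
  }
  .measured_epoch_periods[[key]] / (1000 / target_frequency)
}

#' Background noise model
#'
#' Additive noise for synthetic EEG: pink (1/f^beta) background, white
#' sensor noise, and optional 60 Hz line interference. Scales are standard
#' deviations in microvolts per channel.
#'
#' @param pink_scale RMS of the pink component (microvolts).
#' @param white_sd Standard deviation of the white component (microvolts).
#' @param line_amp Amplitude of the 60 Hz line component (microvolts).
#' @param pink_exponent Spectral slope beta of the 1/f^beta component.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(pink_scale = 1, white_sd = 0.5, line_amp = 0,
                        pink_exponent = 1) {
  stopifnot(pink_scale >= 0, white_sd >= 0, line_amp >= 0, pink_exponent >= 0)
  structure(
    list(pink_scale = pink_scale, white_sd = white_sd,
         line_amp = line_amp, pink_exponent = pink_exponent),
    class = "noise_model"
  )
}

# fraction of a unit-RMS pink realisation's variance falling inside `band`,
# computed from the deterministic FFT amplitude weights
.pink_band_fraction <- function(n, fs, beta, band) {
  f <- seq_len(floor(n / 2)) * fs / n
  w2 <- f^(-beta)
  sum(w2[f >= band[1] & f <= band[2]]) / sum(w2)
}

#' Scale a noise model to a target in-band SNR
#'
#' Rescales the pink and white components jointly so that the expected noise
#' RMS inside `band` equals `gain / snr`; with `gain` the fundamental SSVEP
#' amplitude, the named `snr` is then amplitude over in-band noise RMS.
#'
#' @param noise A [noise_model()].
#' @param gain Fundamental amplitude (microvolts) the SNR refers to.
#' @param snr Target signal-to-noise ratio (amplitude / in-band noise RMS).
#' @param fs Sampling rate (Hz).
#' @param duration Segment duration (s) (sets the FFT grid of the pink
#'   component).
#' @param band Analysis band (Hz) over which noise RMS is measured.
#' @return A rescaled `noise_model`.
#' @export
calibrate_noise <- function(noise, gain, snr, fs = 250, duration = 10,
                            band = c(7, 17)) {
  stopifnot(inherits(noise, "noise_model"), gain > 0, snr > 0)
  n <- round(fs * duration)
  pink_band <- if (noise$pink_scale > 0) {
    noise$pink_scale *
      sqrt(.pink_band_fraction(n, fs, noise$pink_exponent, band))
  } else 0
  white_band <- noise$white_sd * sqrt(diff(band) / (fs / 2))
  band_rms <- sqrt(pink_band^2 + white_band^2)
  if (band_rms == 0) return(noise)
  k <- (gain / snr) / band_rms
  noise_model(noise$pink_scale * k, noise$white_sd * k,
              noise$line_amp, noise$pink_exponent)
}

# one channel of unit-RMS pink noise via FFT amplitude shaping
.pink_noise <- function(n, beta) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))            # avoid DC blow-up; DC zeroed below
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  w <- f^(-beta / 2)
  w[1] <- 0
  y <- Re(fft(X * w, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Generate one synthetic SSVEP EEG segment
#'
#' Synthesises a labeled multichannel segment: a phase-continuous sinusoid
#' (plus 2nd harmonic) whose instantaneous period is drawn per epoch from
#' the schedule's jitter model, subject-specific off-target sinusoids,
#' spatial mixing over channels by the profile's channel weights, and
#' additive pink + white + line noise. Identical inputs and seed give a
#' bit-identical segment.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [stimulus_schedule()].
#' @param noise A [noise_model()].
#' @param duration Segment duration in seconds.
#' @param fs Sampling rate in Hz. Must exceed four times the target
#'   frequency so the 2nd harmonic stays below Nyquist.
#' @param seed Integer seed.
#' @return An [eeg_segment()] labeled with the target frequency and subject.
#' @export
#' @examples
#' pr <- subject_profile("S01", gain = c(`10` = 5))
#' seg <- generate_segment(pr, stimulus_schedule(10),
#'                         noise_model(0, 0), duration = 2, seed = 7)
#' dim(seg)
generate_segment <- function(profile, schedule, noise = noise_model(),
                             duration = 10, fs = 250, seed = 1) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(schedule, "stimulus_schedule"),
            inherits(noise, "noise_model"),
            duration > 0, fs > 0)
  f0 <- schedule$target_frequency
  if (2 * f0 >= fs / 2) {
    stop(sprintf(
      "2nd harmonic of %g Hz is at or above Nyquist (fs = %g Hz); increase fs",
      f0, fs))
  }
  key <- as.character(f0)
  if (!key %in% names(profile$gain)) {
    stop(sprintf("profile '%s' has no gain for target frequency %g Hz",
                 profile$subject_id, f0))
  }
  n <- round(fs * duration)
  n_ch <- length(profile$channel_weights)
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    # per-epoch realised period ratios, phase-continuous accumulation
    ep_len <- round(schedule$epoch_length * fs)
    n_ep <- ceiling(n / ep_len)
    means <- rep(schedule$jitter_mean, length.out = n_ep)
    ratios <- means + rnorm(n_ep, 0, schedule$jitter_sd)
    ratios <- pmax(ratios, 1e-3)
    inst_f <- rep(f0 / ratios, each = ep_len)[seq_len(n)]
    phase0 <- unname(profile$phase[key])
    phi <- phase0 + 2 * pi * cumsum(inst_f) / fs

    amp <- unname(profile$gain[key])
    src <- amp * sin(phi) + amp * profile$harmonic_ratio * sin(2 * phi)
    if (length(profile$offtarget_response)) {
      offt <- as.numeric(names(profile$offtarget_response))
      for (j in seq_along(offt)) {
        src <- src + profile$offtarget_response[j] *
          sin(2 * pi * offt[j] * t + j)   # fixed per-peak phase offset
      }
    }
    samples <- outer(src, profile$channel_weights)

    if (noise$pink_scale > 0 || noise$white_sd > 0 || noise$line_amp > 0) {
      for (c in seq_len(n_ch)) {
        nz <- numeric(n)
        if (noise$pink_scale > 0) {
          nz <- nz + noise$pink_scale * .pink_noise(n, noise$pink_exponent)
        }
        if (noise$white_sd > 0) nz <- nz + rnorm(n, 0, noise$white_sd)
        if (noise$line_amp > 0) {
          nz <- nz + noise$line_amp * sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
        }
        samples[, c] <- samples[, c] + nz
      }
    }
    eeg_segment(samples, fs, frequency = f0, subject = profile$subject_id)
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' For every subject profile and every schedule (one per target frequency),
#' generates `trials_per_frequency` segments, mirroring a session of
#' repeated cued trials per target. The result is a tibble, one row per
#' trial, with the segment in a list-column.
#'
#' @param profiles List of [subject_profile()] objects.
#' @param schedules List of [stimulus_schedule()] objects, one per target
#'   frequency.
#' @param trials_per_frequency Trials per (subject, frequency) cell.
#' @param noise A [noise_model()], or `NULL` for noise-free data.
#' @param snr If non-`NULL`, the noise model is rescaled per subject and
#'   frequency with [calibrate_noise()] so that fundamental amplitude over
#'   in-band noise RMS equals `snr`.
#' @param duration,fs Segment duration (s) and sampling rate (Hz).
#' @param seed Integer seed; per-segment seeds are derived deterministically.
#' @return A tibble with columns `subject`, `frequency`, `trial`, `segment`
#'   (list of `eeg_segment`).
#' @export
#' @examples
#' ds <- generate_dataset(random_profiles(2, seed = 1),
#'                        lapply(c(10, 12), stimulus_schedule),
#'                        trials_per_frequency = 2, duration = 2, seed = 5)
#' nrow(ds)  # 2 subjects x 2 frequencies x 2 trials = 8
generate_dataset <- function(profiles, schedules,
                             trials_per_frequency = 10,
                             noise = noise_model(), snr = NULL,
                             duration = 10, fs = 250, seed = 1) {
  if (!length(profiles)) stop("`profiles` must contain at least one subject")
  stopifnot(trials_per_frequency >= 1)
  grid <- tidyr::expand_grid(
    s = seq_along(profiles),
    f = seq_along(schedules),
    trial = seq_len(trials_per_frequency)
  )
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(grid)))
  rows <- purrr::pmap(list(grid$s, grid$f, grid$trial, seeds),
                      function(si, fi, trial, sd_i) {
    pr <- profiles[[si]]
    sch <- schedules[[fi]]
    nz <- if (is.null(noise)) {
      noise_model(0, 0, 0)
    } else if (!is.null(snr)) {
      calibrate_noise(noise, unname(pr$gain[as.character(sch$target_frequency)]),
                      snr, fs, duration)
    } else noise
    seg <- generate_segment(pr, sch, nz, duration, fs, seed = sd_i)
    tibble::tibble(subject = pr$subject_id,
                   frequency = sch$target_frequency,
                   trial = trial, segment = list(seg))
  })
  dplyr::bind_rows(rows)
}
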