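#' Filtering front-end specification
#'
#' Parameters of the preprocessing chain applied to every raw segment: a
#' 60 Hz notch to suppress line interference followed by a 5th-order
#' Butterworth bandpass restricting the signal to the SSVEP analysis range.
#' Both filters are applied per channel, forward-backward (zero phase), so
#' downstream score-curve features are not phase-distorted.
#'
#' @param notch_freq Notch centre frequency (Hz).
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @param bp_order Butterworth order (the order of the analog prototype;
#'   the digital bandpass has twice as many poles).
#' @param bp_low,bp_high Bandpass edges (Hz). The default 5-45 Hz covers the
#'   7-17 Hz analysis band and its 2nd harmonics (17-34 Hz) with margin.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 60, notch_q = 30,
                        bp_order = 5, bp_low = 5, bp_high = 45) {
  stopifnot(notch_freq > 0, notch_q > 0, bp_order >= 1,
            bp_low > 0, bp_low < bp_high)
  structure(
    list(notch_freq = notch_freq, notch_q = notch_q,
         bp_order = bp_order, bp_low = bp_low, bp_high = bp_high),
    class = "filter_spec"
  )
}

# RBJ biquad notch coefficients (b, a) for centre f0 and quality q at rate fs
.notch_coefficients <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

.apply_filtfilt <- function(segment, b, a) {
  x <- segment$samples
  if (any(!is.finite(x))) stop("segment contains non-finite samples")
  y <- apply(x, 2, function(col) signal::filtfilt(b, a, col))
  eeg_segment(y, segment$fs, segment$frequency, segment$subject)
}

#' Notch filter a segment
#'
#' Second-order IIR notch at `spec$notch_freq`, applied per channel with
#' zero-phase (forward-backward) filtering. Line interference at the notch
#' frequency is strongly attenuated while in-band SSVEP components pass
#' essentially unchanged.
#'
#' @param segment An [eeg_segment()].
#' @param spec A [filter_spec()].
#' @return A filtered `eeg_segment`.
#' @export
notch_filter <- function(segment, spec = filter_spec()) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(spec, "filter_spec"))
  if (spec$notch_freq >= segment$fs / 2) {
    stop(sprintf("notch frequency %g Hz is not below Nyquist (%g Hz)",
                 spec$notch_freq, segment$fs / 2))
  }
  co <- .notch_coefficients(spec$notch_freq, spec$notch_q, segment$fs)
  .apply_filtfilt(segment, co$b, co$a)
}

#' Bandpass filter a segment
#'
#' Butterworth bandpass of order `spec$bp_order` between `spec$bp_low` and
#' `spec$bp_high` Hz, applied per channel with zero-phase filtering.
#'
#' @inheritParams notch_filter
#' @return A filtered `eeg_segment`.
#' @export
bandpass_filter <- function(segment, spec = filter_spec()) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(spec, "filter_spec"))
  nyq <- segment$fs / 2
  if (spec$bp_high >= nyq) {
    stop(sprintf("bandpass edge %g Hz is not below Nyquist (%g Hz)",
                 spec$bp_high, nyq))
  }
  bt <- signal::butter(spec$bp_order, c(spec$bp_low, spec$bp_high) / nyq,
                       type = "pass")
  .apply_filtfilt(segment, bt$b, bt$a)
}

#' Apply the full preprocessing chain
#'
#' Notch then bandpass, per [filter_spec()].
#'
#' @inheritParams notch_filter
#' @return A filtered `eeg_segment`.
#' @export
preprocess_segment <- function(segment, spec = filter_spec()) {
  bandpass_filter(notch_filter(segment, spec), spec)
}

#' Preprocess every segment of a dataset
#'
#' @param data A tibble with a `segment` list-column, as returned by
#'   [generate_dataset()] or [read_segments()].
#' @param spec A [filter_spec()].
#' @return `data` with the `segment` column filtered.
#' @export
preprocess_dataset <- function(data, spec = filter_spec()) {
  stopifnot("segment" %in% names(data))
  dplyr::mutate(data,
                segment = purrr::map(.data$segment, preprocess_segment,
                                     spec = spec))
}
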