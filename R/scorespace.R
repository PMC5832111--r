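#' Analysis frequency grid
#'
#' The grid over which CCA and PSDA score curves are evaluated: 7-17 Hz in
#' 0.1 Hz steps by default (101 points). The step is fine enough to localise
#' stimulus peaks displaced by rendering jitter while a 2.5 s analysis
#' window can still separate neighbouring grid points after interpolation;
#' all four default targets (8.5, 10, 12, 15 Hz) land exactly on grid
#' points.
#'
#' @param f_min,f_max Band edges in Hz.
#' @param step Grid step in Hz.
#' @return An object of class `frequency_grid` with element `freqs`.
#' @export
frequency_grid <- function(f_min = 7, f_max = 17, step = 0.1) {
  stopifnot(f_min < f_max, step > 0)
  freqs <- seq(f_min, f_max, by = step)
  targets <- c(8.5, 10, 12, 15)
  inside <- targets[targets >= f_min & targets <= f_max]
  if (length(inside)) {
    on_grid <- vapply(inside, function(f) min(abs(freqs - f)) < 1e-9,
                      logical(1))
    if (!all(on_grid)) {
      stop("grid must include the target frequencies ",
           paste(inside[!on_grid], collapse = ", "), " Hz exactly")
    }
  }
  structure(list(f_min = f_min, f_max = f_max, step = step, freqs = freqs),
            class = "frequency_grid")
}

#' CCA reference signal matrix
#'
#' Sine/cosine pairs at a candidate frequency and its harmonics, the
#' standard reference set canonical correlation is computed against in
#' SSVEP decoding.
#'
#' @param f Candidate frequency (Hz).
#' @param n_harmonics Number of harmonics (1 = fundamental only).
#' @param fs Sampling rate (Hz).
#' @param n_samples Number of time samples.
#' @return A `n_samples x (2 * n_harmonics)` matrix with columns
#'   `sin(2*pi*f*t), cos(2*pi*f*t), sin(2*pi*2f*t), ...`
#' @export
reference_signals <- function(f, n_harmonics = 2, fs = 250, n_samples) {
  stopifnot(f > 0, n_harmonics >= 1, n_samples >= 2)
  if (n_harmonics * f >= fs / 2) {
    stop(sprintf("harmonic %d of %g Hz is at or above Nyquist (fs = %g Hz)",
                 n_harmonics, f, fs))
  }
  t <- (seq_len(n_samples) - 1) / fs
  cols <- lapply(seq_len(n_harmonics), function(h) {
    cbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t))
  })
  do.call(cbind, cols)
}

# symmetric inverse square root with eigenvalue clamping (regularised whitener)
.inv_sqrt <- function(S, ridge = 1e-9) {
  e <- eigen(S, symmetric = TRUE)
  floor_val <- max(e$values[1], .Machine$double.eps) * ridge
  vals <- pmax(e$values, floor_val)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# maximum canonical correlation between column-centred X and Y via
# regularised covariance whitening; rank-deficient inputs (e.g. a constant
# channel) are handled by the eigenvalue clamp rather than failing
.cca_max_cor <- function(X, Y, ridge = 1e-9) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  Sxx <- crossprod(Xc) / n
  Syy <- crossprod(Yc) / n
  Sxy <- crossprod(Xc, Yc) / n
  K <- .inv_sqrt(Sxx, ridge) %*% Sxy %*% .inv_sqrt(Syy, ridge)
  rho <- svd(K, nu = 0, nv = 0)$d[1]
  min(max(rho, 0), 1)
}

#' Maximum canonical correlation at one candidate frequency
#'
#' Correlates the multichannel segment with [reference_signals()] at `f`
#' and returns the largest canonical correlation, the per-frequency score
#' SSVEP detection by CCA is built on. Covariances are regularised so a
#' rank-deficient segment (a constant channel) degrades gracefully instead
#' of failing.
#'
#' @param segment An [eeg_segment()] (ideally preprocessed).
#' @param f Candidate frequency (Hz).
#' @param n_harmonics Harmonics in the reference set.
#' @return A score in `[0, 1]`.
#' @export
cca_score <- function(segment, f, n_harmonics = 2) {
  stopifnot(inherits(segment, "eeg_segment"))
  Y <- reference_signals(f, n_harmonics, segment$fs, nrow(segment$samples))
  .cca_max_cor(segment$samples, Y)
}

#' CCA score curve over the analysis grid
#'
#' [cca_score()] evaluated at every grid frequency. The curve as a whole -
#' peak locations, widths, and subject-specific off-target structure -
#' carries more information than the score at the stimulated frequency
#' alone, which is what the partition features downstream exploit.
#'
#' @inheritParams cca_score
#' @param grid A [frequency_grid()].
#' @return A tibble of class `cca_curve` with columns `frequency`, `score`.
#' @export
cca_score_curve <- function(segment, grid = frequency_grid(),
                            n_harmonics = 2) {
  stopifnot(inherits(segment, "eeg_segment"),
            inherits(grid, "frequency_grid"))
  bank <- .reference_bank(grid, n_harmonics, segment$fs,
                          nrow(segment$samples))
  scores <- .cca_curve_scores(segment$samples, bank)
  out <- tibble::tibble(frequency = grid$freqs, score = scores)
  class(out) <- c("cca_curve", class(out))
  out
}

# precompute, per grid frequency, the centred & whitened reference matrix
# (n x 2h) so that a score curve costs one whitening of X plus one small
# SVD per frequency
.reference_bank <- function(grid, n_harmonics, fs, n_samples, ridge = 1e-9) {
  lapply(grid$freqs, function(f) {
    Y <- reference_signals(f, n_harmonics, fs, n_samples)
    Yc <- sweep(Y, 2, colMeans(Y))
    Yc %*% .inv_sqrt(crossprod(Yc) / n_samples, ridge)
  })
}

.cca_curve_scores <- function(X, bank, ridge = 1e-9) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  A <- Xc %*% .inv_sqrt(crossprod(Xc) / n, ridge)
  vapply(bank, function(B) {
    rho <- svd(crossprod(A, B) / n, nu = 0, nv = 0)$d[1]
    min(max(rho, 0), 1)
  }, numeric(1))
}

#' Welch power spectral density curve per channel
#'
#' Welch's method (Hann windows, 50% overlap by default, one-sided,
#' microvolts squared per Hz), interpolated onto the analysis grid, for
#' every channel of the segment.
#'
#' @param segment An [eeg_segment()].
#' @param grid A [frequency_grid()].
#' @param window_sec Welch window length in seconds (2.5 s default, giving
#'   four windows per 10 s segment).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A tibble of class `psd_curve` with columns `frequency`,
#'   `channel`, `power`.
#' @export
psd_curve <- function(segment, grid = frequency_grid(),
                      window_sec = 2.5, overlap = 0.5) {
  stopifnot(inherits(segment, "eeg_segment"),
            inherits(grid, "frequency_grid"),
            overlap >= 0, overlap < 1)
  x <- segment$samples
  fs <- segment$fs
  win <- round(window_sec * fs)
  if (win > nrow(x)) {
    stop(sprintf("Welch window (%d samples) is longer than the segment (%d)",
                 win, nrow(x)))
  }
  pw <- .welch_psd(x, fs, win, overlap, grid$step)
  # interpolate each channel onto the grid (exact when bins align)
  vals <- apply(pw$psd, 2, function(p) {
    approx(pw$freq, p, xout = grid$freqs, rule = 2)$y
  })
  out <- tibble::tibble(
    frequency = rep(grid$freqs, times = ncol(x)),
    channel = rep(seq_len(ncol(x)), each = length(grid$freqs)),
    power = as.vector(vals)
  )
  class(out) <- c("psd_curve", class(out))
  out
}

# Welch estimator: Hann-windowed, zero-padded so the FFT bin spacing is at
# most `step` Hz, averaged over overlapping windows; one-sided density
.welch_psd <- function(x, fs, win, overlap, step) {
  n <- nrow(x)
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, n - win + 1L, by = hop)
  nfft <- max(win, 2L * ceiling(fs / step / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  U <- sum(w^2)
  nfreq <- floor(nfft / 2) + 1L
  acc <- matrix(0, nfreq, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + win - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))     # detrend (mean removal)
    seg <- seg * w
    padded <- rbind(seg, matrix(0, nfft - win, ncol(x)))
    X <- stats::mvfft(padded)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  psd[c(-1, -nfreq), ] <- 2 * psd[c(-1, -nfreq), ]  # one-sided
  list(freq = (seq_len(nfreq) - 1) * fs / nfft, psd = psd)
}

# local maxima of a curve, endpoints included when they dominate their
# single neighbour
.local_peaks <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  idx <- integer(0)
  if (v[1] > v[2]) idx <- c(idx, 1L)
  if (n > 2L) {
    interior <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    idx <- c(idx, interior)
  }
  if (v[n] > v[n - 1]) idx <- c(idx, n)
  if (!length(idx)) idx <- which.max(v)
  idx
}

#' Select the best-responding channel from a PSD curve
#'
#' Ranks channels by the "first-max minus second-max" margin: the height of
#' the channel's largest spectral peak minus its second-largest local peak
#' (or minus zero if the channel has a single peak). A channel with one
#' dominant peak and a quiet background wins over one with several
#' comparable peaks. Ties break to the lowest channel index.
#'
#' @param curve A [psd_curve()].
#' @return The selected channel index (1-based).
#' @export
select_best_channel <- function(curve) {
  stopifnot(inherits(curve, "psd_curve"))
  margins <- curve |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(margin = {
      pk <- sort(.data$power[.local_peaks(.data$power)], decreasing = TRUE)
      if (length(pk) >= 2) pk[1] - pk[2] else pk[1]
    }, .groups = "drop")
  margins$channel[which.max(margins$margin)]
}
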