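#' EEG segment container
#'
#' A fixed-rate multichannel EEG sample matrix with optional stimulus and
#' subject labels. This is the unit of data every stage of the pipeline
#' consumes: `T x C` samples in microvolts at sampling rate `fs`, where
#' `T = round(fs * duration)`.
#'
#' @param samples Numeric matrix, time by channel (microvolts). All values
#'   must be finite.
#' @param fs Sampling rate in Hz.
#' @param frequency Optional stimulus (target) frequency label in Hz.
#' @param subject Optional subject identifier.
#'
#' @return An object of class `eeg_segment`: a list with elements `samples`,
#'   `fs`, `frequency`, `subject`.
#' @export
#' @examples
#' seg <- eeg_segment(matrix(rnorm(500 * 2), 500, 2), fs = 250)
#' seg
eeg_segment <- function(samples, fs, frequency = NULL, subject = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (any(!is.finite(samples))) stop("`samples` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  structure(
    list(samples = samples, fs = fs,
         frequency = frequency, subject = subject),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  dur <- nrow(x$samples) / x$fs
  cat(sprintf("<eeg_segment> %d samples x %d channels, fs = %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, dur))
  if (!is.null(x$frequency)) cat("  stimulus: ", x$frequency, " Hz\n", sep = "")
  if (!is.null(x$subject)) cat("  subject:  ", x$subject, "\n", sep = "")
  invisible(x)
}

#' @export
dim.eeg_segment <- function(x) dim(x$samples)

# duration in seconds
segment_duration <- function(segment) nrow(segment$samples) / segment$fs

# run `expr` with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
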