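#' Pipeline run configuration
#'
#' All knobs of the end-to-end run in one serialisable object: simulation
#' settings (or an input directory of recorded segments), filtering, score
#' grid, partitioning, GMM and decoder settings. The configuration is
#' written alongside every output for provenance, and a run is reproducible
#' from that file alone.
#'
#' @param n_subjects Number of synthetic subjects (ignored when
#'   `input_dir` is given).
#' @param frequencies Target frequencies (Hz).
#' @param trials_per_frequency Trials per (subject, frequency) cell.
#' @param duration,fs Segment duration (s) and sampling rate (Hz).
#' @param snr Generator signal-to-noise ratio (amplitude over in-band noise
#'   RMS); `NULL` leaves the noise model unscaled.
#' @param jitter `"none"` or `"measured"` (tablet-rendering period errors).
#' @param band Bandpass edges (Hz).
#' @param notch Notch frequency (Hz).
#' @param n_harmonics CCA reference harmonics.
#' @param mixtures GMM components `M`.
#' @param eta MAP relevance factor.
#' @param mode Decoder feature space: `"supervector"`, `"llr"` or
#'   `"fusion"`.
#' @param folds Outer CV folds.
#' @param seed Master seed; all stage seeds derive from it.
#' @param input_dir Optional directory of `segment_*.csv` files to use
#'   instead of simulation.
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 10,
                       frequencies = c(8.5, 10, 12, 15),
                       trials_per_frequency = 10,
                       duration = 10, fs = 250,
                       snr = 4, jitter = c("measured", "none"),
                       band = c(5, 45), notch = 60,
                       n_harmonics = 2,
                       mixtures = 8, eta = 16,
                       mode = c("supervector", "llr", "fusion"),
                       folds = 10, seed = 1,
                       input_dir = NULL, out_dir = NULL) {
  structure(
    list(n_subjects = n_subjects, frequencies = frequencies,
         trials_per_frequency = trials_per_frequency,
         duration = duration, fs = fs, snr = snr,
         jitter = match.arg(jitter), band = band, notch = notch,
         n_harmonics = n_harmonics, mixtures = mixtures, eta = eta,
         mode = match.arg(mode), folds = folds, seed = seed,
         input_dir = input_dir, out_dir = out_dir),
    class = "run_config"
  )
}

# strip table/class attributes so jsonlite serialises a plain matrix
.plain_matrix <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

# deterministic per-stage seeds derived from the master seed
.stage_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max, 4L)
    list(simulate = s[1], ubm = s[2], cv = s[3], profiles = s[4])
  })
}

.schedules_for <- function(config) {
  lapply(config$frequencies, function(f) {
    if (config$jitter == "measured" && as.character(f) %in%
        names(.measured_epoch_periods)) {
      stimulus_schedule(f, jitter_mean = jitter_measured(f),
                        jitter_sd = 0.002)
    } else {
      stimulus_schedule(f)
    }
  })
}

#' Run the full decoding pipeline
#'
#' Simulate (or read) -> filter -> score curves -> partition features ->
#' UBM -> per-subject MAP adaptation -> feature transform -> stratified
#' cross-validated SVM decoding. Stage timings are logged to `stderr`, and
#' when `out_dir` is set the configuration, per-trial features, models and
#' report are written there.
#'
#' @param config A [run_config()].
#' @param quiet Suppress the stage log.
#' @return A list of class `ssvep_report`: the [cross_validate()] result
#'   (`cv`), the mean accuracy, ITR (bits/min, at `duration` seconds per
#'   selection), the transform dimension, the subject models and UBM, and
#'   the configuration.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .stage_seeds(config$seed)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[ssvepid] ", fmt), ...))
  }
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  data <- if (!is.null(config$input_dir)) {
    read_segments(config$input_dir)
  } else {
    profiles <- random_profiles(config$n_subjects,
                                frequencies = config$frequencies,
                                seed = seeds$profiles)
    generate_dataset(profiles, .schedules_for(config),
                     trials_per_frequency = config$trials_per_frequency,
                     noise = noise_model(), snr = config$snr,
                     duration = config$duration, fs = config$fs,
                     seed = seeds$simulate)
  }
  say("segments: %d (%.1fs)", nrow(data), tic() - t0)

  t0 <- tic()
  spec <- filter_spec(notch_freq = config$notch,
                      bp_low = config$band[1], bp_high = config$band[2])
  data <- preprocess_dataset(data, spec)
  say("preprocessed (%.1fs)", tic() - t0)

  t0 <- tic()
  features <- extract_features(data, n_harmonics = config$n_harmonics)
  say("features: %d frames x 54 (%.1fs)", nrow(features), tic() - t0)

  t0 <- tic()
  X <- feature_matrix(features)
  ubm <- em_fit(X, config$mixtures, seed = seeds$ubm)
  subjects <- unique(features$subject)
  models <- lapply(subjects, function(s) {
    map_adapt(ubm, X[features$subject == s, , drop = FALSE],
              eta = config$eta, subject_id = s)
  })
  say("UBM (M = %d) + %d adapted subject models (%.1fs)",
      config$mixtures, length(models), tic() - t0)

  t0 <- tic()
  trials <- transform_features(features, models, ubm, mode = config$mode)
  say("transform '%s': %d trials x %d (%.1fs)", config$mode, nrow(trials),
      ncol(trials) - 3L, tic() - t0)

  t0 <- tic()
  cv <- cross_validate(trials, config = decoder_config(folds = config$folds,
                                                       seed = seeds$cv))
  say("decoding: %.2f%% mean accuracy (%.1fs)", cv$mean_accuracy, tic() - t0)

  report <- structure(
    list(cv = cv, mean_accuracy = cv$mean_accuracy,
         itr = itr(cv$mean_accuracy / 100, length(config$frequencies),
                   config$duration),
         transform_dim = ncol(trials) - 3L,
         mode = config$mode, ubm = ubm, models = models, config = config),
    class = "ssvep_report"
  )
  if (!is.null(config$out_dir)) .write_report(report, features, trials)
  report
}

.write_report <- function(report, features, trials) {
  dir <- report$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(trials, file.path(dir, "trial_features.csv"),
                   row.names = FALSE)
  write_gmm(report$ubm, file.path(dir, "ubm.json"))
  for (m in report$models) {
    write_gmm(m, file.path(dir, sprintf("model_%s.json", m$subject_id)))
  }
  jsonlite::write_json(
    list(mean_accuracy = report$mean_accuracy,
         itr_bit_per_min = report$itr,
         mode = report$mode, transform_dim = report$transform_dim,
         fold_accuracy = report$cv$fold_results$accuracy,
         confusion = .plain_matrix(report$cv$confusion),
         classes = report$cv$classes),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(dir)
}

#' @export
print.ssvep_report <- function(x, ...) {
  cat(sprintf("<ssvep_report> mode '%s' (%d-dim), %d-fold CV\n",
              x$mode, x$transform_dim, x$config$folds))
  cat(sprintf("  mean accuracy: %.2f%%   ITR: %.2f bit/min\n",
              x$mean_accuracy, x$itr))
  invisible(x)
}

#' @method glance ssvep_report
#' @export
glance.ssvep_report <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$cv),
    tibble::tibble(itr_bit_per_min = x$itr, mode = x$mode,
                   transform_dim = x$transform_dim)
  )
}

#' Cross-validated subject identification from GMM scores
#'
#' Complements frequency decoding: how well do the adapted models tell the
#' subjects themselves apart? Trials are split into stratified folds (by
#' subject); per fold, the UBM is fitted on the training frames, each
#' subject's model is MAP-adapted from it on their training frames, and
#' every held-out trial is assigned to the model with the highest total
#' log-likelihood ([identify_subject()]).
#'
#' @param features Frame-level feature tibble from [extract_features()].
#' @param mixtures GMM components.
#' @param eta MAP relevance factor.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @param adapt If `FALSE`, subject models are EM-trained from scratch on
#'   each subject's training frames instead of MAP-adapted from the UBM.
#' @return A list of class `ssvep_subject_cv` with `accuracy` (%),
#'   `confusion` and `folds`.
#' @export
subject_identification <- function(features, mixtures = 8, eta = 16,
                                   folds = 10, seed = 1, adapt = TRUE) {
  trials <- features |>
    dplyr::distinct(.data$subject, .data$frequency, .data$trial)
  fold <- .stratified_folds(trials$subject, folds, seed)
  subjects <- sort(unique(trials$subject))
  feat_key <- paste(features$subject, features$frequency, features$trial)
  trial_key <- paste(trials$subject, trials$frequency, trials$trial)
  X <- feature_matrix(features)

  truth <- character(0)
  pred <- character(0)
  for (f in sort(unique(fold))) {
    tr_keys <- trial_key[fold != f]
    te_keys <- trial_key[fold == f]
    tr_rows <- feat_key %in% tr_keys
    ubm <- em_fit(X[tr_rows, , drop = FALSE], mixtures, seed = seed + f)
    models <- lapply(subjects, function(s) {
      rows <- tr_rows & features$subject == s
      if (adapt) {
        map_adapt(ubm, X[rows, , drop = FALSE], eta = eta, subject_id = s)
      } else {
        m <- em_fit(X[rows, , drop = FALSE], min(mixtures, sum(rows)),
                    seed = seed + f)
        m$subject_id <- s
        m
      }
    })
    for (k in te_keys) {
      rows <- feat_key == k
      truth <- c(truth, features$subject[rows][1])
      pred <- c(pred, as.character(identify_subject(models,
                                                    X[rows, , drop = FALSE])))
    }
  }
  confusion <- table(truth = factor(truth, levels = subjects),
                     predicted = factor(pred, levels = subjects))
  structure(list(accuracy = accuracy(confusion), confusion = confusion,
                 folds = folds),
            class = "ssvep_subject_cv")
}

#' @export
print.ssvep_subject_cv <- function(x, ...) {
  cat(sprintf("<ssvep_subject_cv> %d-fold CV subject identification: %.2f%%\n",
              x$folds, x$accuracy))
  invisible(x)
}
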