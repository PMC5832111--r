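#' Score-space partition scheme
#'
#' Ten increasing boundary frequencies defining nine half-open bands
#' `[b_k, b_{k+1})` (the last band closed) that tile the analysis range.
#' Partitioning the score curves into bands and summarising each band with
#' statistics makes the features robust to stimulus peaks displaced by
#' rendering jitter, and captures subject-specific off-target structure:
#' a peak that wanders within its band changes the band statistics only
#' mildly, while each target frequency stays strictly inside one band.
#'
#' @param boundaries Increasing numeric vector of 10 band edges (Hz).
#' @return An object of class `partition_scheme`.
#' @export
partition_scheme <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 10L || any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be 10 strictly increasing frequencies")
  }
  targets <- c(8.5, 10, 12, 15)
  inside <- targets[targets > boundaries[1] & targets < boundaries[10]]
  on_edge <- inside[vapply(inside,
                           function(f) any(abs(f - boundaries) < 1e-9),
                           logical(1))]
  if (length(on_edge)) {
    stop("target frequencies must lie strictly inside a partition; ",
         paste(on_edge, collapse = ", "), " Hz fall on a boundary")
  }
  structure(list(boundaries = boundaries, n_partitions = 9L),
            class = "partition_scheme")
}

#' Default nine-band partition of 7-17 Hz
#'
#' Nine equal-width bands (width 10/9 Hz) over the analysis range. All four
#' target frequencies (8.5, 10, 12, 15 Hz) lie strictly inside a band.
#'
#' @return A [partition_scheme()].
#' @export
#' @examples
#' default_partitions()$boundaries
default_partitions <- function() {
  partition_scheme(seq(7, 17, length.out = 10))
}

# band index (1..9) per frequency; [b_k, b_{k+1}), last band closed
.assign_partition <- function(freqs, scheme) {
  k <- findInterval(freqs, scheme$boundaries, rightmost.closed = TRUE)
  if (any(k < 1L | k > 9L)) {
    stop("curve contains frequencies outside the partition range [",
         scheme$boundaries[1], ", ", scheme$boundaries[10], "] Hz")
  }
  k
}

# Shannon entropy (natural log) of scores normalised to sum to one;
# an all-zero band is mapped to the maximal (uniform) entropy log(n)
.partition_entropy <- function(s) {
  if (any(s < 0)) stop("entropy is defined for nonnegative scores")
  tot <- sum(s)
  if (tot <= 0) return(log(length(s)))
  p <- s / tot
  -sum(ifelse(p > 0, p * log(p), 0))
}

.pop_sd <- function(s) sqrt(mean((s - mean(s))^2))

#' Partition statistics of a CCA score curve
#'
#' For each of the nine bands: power (mean squared score, an energy density
#' that does not depend on the grid step), mean, population standard
#' deviation, and Shannon entropy (natural log) of the band's scores
#' normalised to sum to one.
#'
#' @param curve A [cca_score_curve()] (tibble with `frequency`, `score`).
#' @param scheme A [partition_scheme()].
#' @return A named numeric vector of length 36, partition-major:
#'   `cca_p1_power, cca_p1_mean, cca_p1_sd, cca_p1_entropy, cca_p2_power, ...`
#' @export
partition_stats_cca <- function(curve, scheme = default_partitions()) {
  k <- .assign_partition(curve$frequency, scheme)
  if (length(unique(k)) < 9L) {
    empty <- setdiff(1:9, unique(k))
    stop("partition(s) ", paste(empty, collapse = ", "),
         " contain no grid point; use a finer grid")
  }
  out <- unlist(lapply(1:9, function(p) {
    s <- curve$score[k == p]
    c(power = mean(s^2), mean = mean(s), sd = .pop_sd(s),
      entropy = .partition_entropy(s))
  }))
  names(out) <- as.vector(t(outer(1:9, c("power", "mean", "sd", "entropy"),
                                  function(p, st) sprintf("cca_p%d_%s", p, st))))
  out
}

#' Partition statistics of a PSD curve
#'
#' Mean and population standard deviation of the selected channel's power
#' in each of the nine bands. Power itself is not re-extracted (the PSD is
#' already a power score) and the entropy of near-flat power bands is too
#' unstable to be useful, so the PSDA block carries two statistics per band.
#'
#' @param curve A [psd_curve()].
#' @param scheme A [partition_scheme()].
#' @param channel Channel whose power curve is summarised (see
#'   [select_best_channel()]).
#' @return A named numeric vector of length 18, partition-major:
#'   `psd_p1_mean, psd_p1_sd, psd_p2_mean, ...`
#' @export
partition_stats_psd <- function(curve, scheme = default_partitions(),
                                channel = 1L) {
  cur <- curve[curve$channel == channel, , drop = FALSE]
  if (!nrow(cur)) stop("channel ", channel, " not present in the PSD curve")
  k <- .assign_partition(cur$frequency, scheme)
  if (length(unique(k)) < 9L) {
    empty <- setdiff(1:9, unique(k))
    stop("partition(s) ", paste(empty, collapse = ", "),
         " contain no grid point; use a finer grid")
  }
  out <- unlist(lapply(1:9, function(p) {
    s <- cur$power[k == p]
    c(mean = mean(s), sd = .pop_sd(s))
  }))
  names(out) <- as.vector(t(outer(1:9, c("mean", "sd"),
                                  function(p, st) sprintf("psd_p%d_%s", p, st))))
  out
}

#' Fuse CCA and PSDA partition statistics
#'
#' Ordered concatenation of the 36 CCA statistics and the 18 PSDA
#' statistics into the 54-dimensional fusion vector (CCA block first, then
#' PSDA block, partition-major within each block).
#'
#' @param cca_feats Numeric vector of length 36 from [partition_stats_cca()].
#' @param psd_feats Numeric vector of length 18 from [partition_stats_psd()].
#' @return A named numeric vector of length 54.
#' @export
fuse <- function(cca_feats, psd_feats) {
  if (length(cca_feats) != 36L) {
    stop("`cca_feats` must have length 36, got ", length(cca_feats))
  }
  if (length(psd_feats) != 18L) {
    stop("`psd_feats` must have length 18, got ", length(psd_feats))
  }
  if (any(!is.finite(c(cca_feats, psd_feats)))) {
    stop("fusion features must be finite")
  }
  c(cca_feats, psd_feats)
}

#' Column names of the 54-dimensional fusion space
#' @return Character vector of length 54.
#' @export
fusion_feature_names <- function() {
  c(as.vector(t(outer(1:9, c("power", "mean", "sd", "entropy"),
                      function(p, st) sprintf("cca_p%d_%s", p, st)))),
    as.vector(t(outer(1:9, c("mean", "sd"),
                      function(p, st) sprintf("psd_p%d_%s", p, st)))))
}

#' Extract per-frame fusion features from a dataset
#'
#' Splits every segment into nonoverlapping frames (2.5 s by default, four
#' per 10 s trial), computes the CCA score curve and Welch PSD curve per
#' frame, selects one best-responding PSDA channel per subject (by the
#' first-max minus second-max margin of the subject's frame-averaged PSD),
#' and emits the 54-dimensional fusion vector of every frame.
#'
#' @param data A tibble with columns `subject`, `frequency`, `trial`,
#'   `segment` (list of [eeg_segment()]).
#' @param grid A [frequency_grid()].
#' @param scheme A [partition_scheme()].
#' @param n_harmonics Harmonics in the CCA reference set.
#' @param frame_sec Frame length in seconds.
#' @return A tibble, one row per frame: `subject`, `frequency`, `trial`,
#'   `frame`, `channel` (the subject's selected PSDA channel), then the 54
#'   feature columns named per [fusion_feature_names()].
#' @export
extract_features <- function(data, grid = frequency_grid(),
                             scheme = default_partitions(),
                             n_harmonics = 2, frame_sec = 2.5) {
  stopifnot(all(c("subject", "frequency", "trial", "segment") %in% names(data)))
  if (!nrow(data)) stop("`data` is empty")
  seg1 <- data$segment[[1]]
  fs <- seg1$fs
  frame_len <- round(frame_sec * fs)
  bank <- .reference_bank(grid, n_harmonics, fs, frame_len)

  # per frame: CCA scores over the grid and per-channel PSD over the grid
  per_segment <- purrr::map(seq_len(nrow(data)), function(i) {
    seg <- data$segment[[i]]
    n <- nrow(seg$samples)
    n_frames <- n %/% frame_len
    if (n_frames < 1L) {
      stop("segment ", i, " is shorter than one frame (", frame_sec, " s)")
    }
    purrr::map(seq_len(n_frames), function(fr) {
      idx <- ((fr - 1L) * frame_len + 1L):(fr * frame_len)
      frame_seg <- eeg_segment(seg$samples[idx, , drop = FALSE], fs,
                               seg$frequency, seg$subject)
      list(row = i, frame = fr,
           cca = .cca_curve_scores(frame_seg$samples, bank),
           psd = psd_curve(frame_seg, grid, window_sec = frame_sec,
                           overlap = 0))
    })
  })
  frames <- purrr::flatten(per_segment)

  # one PSDA channel per subject, from the subject's mean PSD curve
  subj_of_frame <- vapply(frames, function(fr) data$subject[fr$row],
                          character(1))
  channel_for <- vapply(unique(data$subject), function(s) {
    sel <- which(subj_of_frame == s)
    mean_psd <- frames[[sel[1]]]$psd
    acc <- Reduce(`+`, lapply(frames[sel], function(fr) fr$psd$power))
    mean_psd$power <- acc / length(sel)
    select_best_channel(mean_psd)
  }, integer(1))

  rows <- purrr::map(frames, function(fr) {
    ch <- channel_for[[data$subject[fr$row]]]
    cca_curve <- tibble::tibble(frequency = grid$freqs, score = fr$cca)
    feats <- fuse(partition_stats_cca(cca_curve, scheme),
                  partition_stats_psd(fr$psd, scheme, channel = ch))
    dplyr::bind_cols(
      tibble::tibble(subject = data$subject[fr$row],
                     frequency = data$frequency[fr$row],
                     trial = data$trial[fr$row],
                     frame = fr$frame, channel = ch),
      tibble::as_tibble_row(as.list(feats))
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract the feature matrix from a feature tibble
#'
#' @param features A tibble from [extract_features()] or
#'   [transform_features()].
#' @return A numeric matrix of the feature columns (everything except the
#'   label columns `subject`, `frequency`, `trial`, `frame`, `channel`).
#' @export
feature_matrix <- function(features) {
  label_cols <- intersect(c("subject", "frequency", "trial", "frame",
                            "channel"), names(features))
  as.matrix(features[, setdiff(names(features), label_cols), drop = FALSE])
}
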