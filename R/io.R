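#' Write segments to CSV interchange files
#'
#' One comma-separated UTF-8 file per segment: leading `key,value` header
#' lines (`fs` mandatory; `subject` and `frequency` when labeled), a
#' channel-name row, then the sample matrix in time-by-channel order at
#' full double precision, so a write/read round trip is bit-identical.
#'
#' @param data Tibble with a `segment` list-column, or a single
#'   [eeg_segment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_segments <- function(data, dir) {
  if (inherits(data, "eeg_segment")) {
    data <- tibble::tibble(segment = list(data))
  }
  stopifnot("segment" %in% names(data))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(nrow(data)), function(i) {
    seg <- data$segment[[i]]
    path <- file.path(dir, sprintf("segment_%04d.csv", i))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("fs,%.17g", seg$fs), con)
    if (!is.null(seg$subject)) writeLines(paste0("subject,", seg$subject), con)
    if (!is.null(seg$frequency)) {
      writeLines(sprintf("frequency,%.17g", seg$frequency), con)
    }
    writeLines(paste(sprintf("ch%d", seq_len(ncol(seg$samples))),
                     collapse = ","), con)
    chr <- matrix(sprintf("%.17g", seg$samples), nrow = nrow(seg$samples))
    utils::write.table(chr, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}

.read_segment_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty segment file: ", path)
  # header: key,value lines until the channel-name row
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^(fs|subject|frequency),", lines[i])) {
    kv <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  if (is.null(hdr$fs)) {
    stop("segment file ", path, " is missing the required `fs` header field")
  }
  if (i > length(lines) || !grepl("^ch1(,|$)", lines[i])) {
    stop("segment file ", path, " is missing the channel-name row")
  }
  n_ch <- length(strsplit(lines[i], ",", fixed = TRUE)[[1]])
  i <- i + 1L
  body <- lines[seq(i, length(lines))]
  cells <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != n_ch)) {
    stop("segment file ", path, " has inconsistent row lengths: expected ",
         n_ch, " columns, found ", paste(unique(lens[lens != n_ch]),
                                         collapse = ", "))
  }
  samples <- matrix(as.numeric(unlist(cells)), ncol = n_ch, byrow = TRUE)
  if (any(!is.finite(samples))) {
    stop("segment file ", path, " contains non-numeric or non-finite samples")
  }
  eeg_segment(samples, as.numeric(hdr$fs),
              frequency = if (!is.null(hdr$frequency))
                as.numeric(hdr$frequency) else NULL,
              subject = hdr$subject)
}

#' Read segments from CSV interchange files
#'
#' Reads every `segment_*.csv` in a directory (or a single file) written by
#' [write_segments()].
#'
#' @param path Directory of segment files, or one file path.
#' @param format Interchange format. Only `"csv"` is supported; `"edf"` is
#'   recognised but not implemented.
#' @return A tibble with columns `subject`, `frequency`, `trial`, `segment`.
#' @export
read_segments <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("unsupported format 'edf': this build reads and writes the CSV ",
         "interchange dialect only")
  }
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "^segment_.*\\.csv$", full.names = TRUE))
  } else if (file.exists(path)) {
    path
  } else {
    stop("path does not exist: ", path)
  }
  if (!length(files)) stop("no segment_*.csv files found under ", path)
  segs <- lapply(files, .read_segment_csv)
  tibble::tibble(
    subject = vapply(segs, function(s)
      if (is.null(s$subject)) NA_character_ else s$subject, character(1)),
    frequency = vapply(segs, function(s)
      if (is.null(s$frequency)) NA_real_ else s$frequency, numeric(1)),
    trial = seq_along(segs),
    segment = segs
  )
}

#' Serialise a GMM (or subject model) to a structured key-value file
#'
#' Writes a versioned JSON schema with `M`, `d`, weights, means, variances
#' and, for adapted subject models, the subject id and relevance factor.
#'
#' @param model An [ssvep_gmm()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "ssvep_gmm"))
  obj <- list(
    schema_version = 1L,
    type = if (inherits(model, "ssvep_subject_model")) "subject_model" else "gmm",
    M = model$M, d = model$d,
    weights = model$weights,
    means = model$means, variances = model$variances,
    subject_id = model$subject_id, eta = model$eta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a GMM written by [write_gmm()]
#'
#' @param path File path.
#' @return An [ssvep_gmm()] (subclass `ssvep_subject_model` when the file
#'   holds an adapted model).
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported model schema in ", path)
  }
  model <- ssvep_gmm(obj$weights,
                     matrix(obj$means, obj$M, obj$d, byrow = FALSE),
                     matrix(obj$variances, obj$M, obj$d, byrow = FALSE))
  if (identical(obj$type, "subject_model")) {
    model$subject_id <- obj$subject_id
    model$eta <- obj$eta
    class(model) <- c("ssvep_subject_model", class(model))
  }
  model
}
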