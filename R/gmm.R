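#' Diagonal-covariance Gaussian mixture model
#'
#' Container for a GMM with `M` components over `d` dimensions: simplex
#' weights, component means and strictly positive diagonal variances.
#' Subject models adapted from a universal background model (UBM) carry the
#' same structure plus the adaptation statistics.
#'
#' @param weights Numeric vector of `M` mixture weights (nonnegative,
#'   summing to one).
#' @param means `M x d` matrix of component means.
#' @param variances `M x d` matrix of positive diagonal variances.
#' @return An object of class `ssvep_gmm`.
#' @export
ssvep_gmm <- function(weights, means, variances) {
  means <- as.matrix(means)
  variances <- as.matrix(variances)
  M <- length(weights)
  if (nrow(means) != M || nrow(variances) != M ||
      ncol(means) != ncol(variances)) {
    stop("weights, means and variances have inconsistent dimensions")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be nonnegative and sum to one")
  }
  if (any(variances <= 0)) stop("`variances` must be strictly positive")
  dimnames(means) <- NULL
  dimnames(variances) <- NULL
  structure(list(weights = as.numeric(unname(weights)), means = means,
                 variances = variances, M = M, d = ncol(means)),
            class = "ssvep_gmm")
}

#' @export
print.ssvep_gmm <- function(x, ...) {
  cat(sprintf("<ssvep_gmm> %d components, %d dimensions\n", x$M, x$d))
  if (!is.null(x$subject_id)) cat("  subject: ", x$subject_id, "\n", sep = "")
  invisible(x)
}

# n x M matrix of per-component weighted log-densities log(xi_m N(x|mu,Sigma))
.comp_logdens <- function(model, X) {
  X <- .as_frames(X, model$d)
  n <- nrow(X)
  out <- matrix(0, n, model$M)
  for (m in seq_len(model$M)) {
    v <- model$variances[m, ]
    mu <- model$means[m, ]
    q <- colSums((t(X) - mu)^2 / v)
    out[, m] <- log(model$weights[m]) -
      0.5 * (model$d * log(2 * pi) + sum(log(v)) + q)
  }
  out
}

.as_frames <- function(X, d) {
  if (is.null(dim(X))) {
    if (length(X) != d) {
      stop("input dimension ", length(X), " does not match model dimension ", d)
    }
    X <- matrix(X, 1L, d)
  } else {
    X <- as.matrix(X)
    if (ncol(X) != d) {
      stop("input dimension ", ncol(X), " does not match model dimension ", d)
    }
  }
  X
}

.logsumexp_rows <- function(L) {
  mx <- apply(L, 1, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Mixture log-density
#'
#' `log sum_m xi_m N(x | mu_m, Sigma_m)`, evaluated stably via log-sum-exp.
#'
#' @param model An [ssvep_gmm()].
#' @param x A `d`-vector or an `n x d` matrix of frames.
#' @return A numeric vector of per-frame log-densities.
#' @export
#' @examples
#' g <- ssvep_gmm(1, matrix(0), matrix(1))
#' log_density(g, 0)  # log(1/sqrt(2*pi))
log_density <- function(model, x) {
  stopifnot(inherits(model, "ssvep_gmm"))
  .logsumexp_rows(.comp_logdens(model, x))
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the nearest chosen centre
.kmeanspp_centers <- function(X, M) {
  n <- nrow(X)
  centers <- matrix(NA_real_, M, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (M > 1L) {
    d2 <- colSums((t(X) - centers[1L, ])^2)
    for (m in 2:M) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = p)
      centers[m, ] <- X[idx, ]
      d2 <- pmin(d2, colSums((t(X) - centers[m, ])^2))
    }
  }
  centers
}

#' Fit a diagonal-covariance GMM by expectation-maximisation
#'
#' Maximum-likelihood fit with k-means++ seeding, responsibility-weighted
#' updates, and a variance floor. The total log-likelihood is nondecreasing
#' over iterations (up to floating-point rounding); iteration stops when
#' the relative improvement drops below `tol` or after `max_iter`
#' iterations. With `M = 1` the fit is the closed-form sample mean and
#' population variance.
#'
#' @param X `n x d` matrix of frames (rows).
#' @param M Number of mixture components. Typical operating points are 4, 8
#'   and 16; `M` may not exceed the number of frames.
#' @param seed Integer seed for the initialisation.
#' @param tol Relative log-likelihood improvement tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Variance floor as a fraction of each dimension's pooled
#'   variance.
#' @return An [ssvep_gmm()] with an attribute `log_likelihood` holding the
#'   per-iteration total log-likelihood trace.
#' @export
em_fit <- function(X, M, seed = 1, tol = 1e-4, max_iter = 200,
                   var_floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (M > n) {
    stop(sprintf(
      "cannot fit %d mixture components with only %d frames; reduce M", M, n))
  }
  if (n < 5L * M) {
    warning(sprintf("only %d frames for %d components; estimates may be poor",
                    n, M))
  }
  pooled <- pmax(apply(X, 2, function(col) mean((col - mean(col))^2)),
                 .Machine$double.eps)
  floor_v <- pmax(var_floor * pooled, .Machine$double.eps)

  with_seed(seed, {
    means <- .kmeanspp_centers(X, M)
    variances <- matrix(pooled, M, d, byrow = TRUE)
    weights <- rep(1 / M, M)
    model <- ssvep_gmm(weights, means, variances)
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      L <- .comp_logdens(model, X)
      lse <- .logsumexp_rows(L)
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      R <- exp(L - lse)                       # n x M responsibilities
      Nk <- colSums(R)
      Nk <- pmax(Nk, .Machine$double.xmin)
      weights <- Nk / n
      weights <- weights / sum(weights)
      means <- crossprod(R, X) / Nk
      variances <- crossprod(R, X^2) / Nk - means^2
      variances <- pmax(variances, matrix(floor_v, M, d, byrow = TRUE))
      model <- ssvep_gmm(weights, means, variances)
      if (it > 1L) {
        rel <- (ll - ll_trace[it - 1L]) / max(abs(ll_trace[it - 1L]), 1)
        if (rel >= 0 && rel < tol) break
      }
    }
    attr(model, "log_likelihood") <- ll_trace
    model
  })
}

#' MAP-adapt a UBM to one subject's frames (mean-only adaptation)
#'
#' Maximum a posteriori adaptation of the component means towards a
#' subject's data, leaving weights and variances at the UBM values. With
#' posterior responsibilities `p(i | x_t)` under the UBM, the soft count
#' `l_i = sum_t p(i | x_t)` and data-dependent mean
#' `xbar_i = (1/l_i) sum_t p(i | x_t) x_t` give the adaptation coefficient
#' `alpha_i = l_i / (l_i + eta)` and the adapted mean
#' `alpha_i * xbar_i + (1 - alpha_i) * mu_i`. The relevance factor `eta`
#' controls how strongly subject data pulls the means away from the UBM:
#' `eta = 0` reproduces the data-dependent means wherever `l_i > 0`, large
#' `eta` keeps the UBM means. Components a subject's data never touches
#' (`l_i = 0`) stay at the UBM mean.
#'
#' @param ubm An [ssvep_gmm()] fitted on pooled background frames of all
#'   subjects.
#' @param X `n x d` matrix of the subject's frames.
#' @param eta Relevance factor, `>= 0` (16 by default, the classic
#'   GMM-UBM operating point).
#' @param subject_id Optional subject identifier stored in the model.
#' @return An `ssvep_gmm` of subclass `ssvep_subject_model` with fields
#'   `subject_id`, `eta` and `stats` (a list with `l`, `xbar`, `alpha`).
#' @export
map_adapt <- function(ubm, X, eta = 16, subject_id = NULL) {
  stopifnot(inherits(ubm, "ssvep_gmm"))
  if (eta < 0) stop("relevance factor `eta` must be >= 0")
  X <- .as_frames(X, ubm$d)
  if (!nrow(X)) stop("subject data is empty")
  L <- .comp_logdens(ubm, X)
  R <- exp(L - .logsumexp_rows(L))
  l <- colSums(R)
  xbar <- ubm$means                         # untouched components keep mu_i
  touched <- l > 0
  if (any(touched)) {
    xbar[touched, ] <- crossprod(R[, touched, drop = FALSE], X) / l[touched]
  }
  alpha <- if (eta == 0) as.numeric(touched) else l / (l + eta)
  means <- alpha * xbar + (1 - alpha) * ubm$means
  out <- ssvep_gmm(ubm$weights, means, ubm$variances)
  out$subject_id <- subject_id
  out$eta <- eta
  out$stats <- list(l = l, xbar = xbar, alpha = alpha)
  class(out) <- c("ssvep_subject_model", class(out))
  out
}

#' Identify the subject a test segment belongs to
#'
#' Scores the test frames against every subject model and returns the
#' identifier of the model maximising the total log-likelihood
#' `sum_t log p(x_t | lambda_s)`. Ties break to the lowest model index.
#'
#' @param models List of subject models (see [map_adapt()] or [em_fit()]).
#' @param X `n x d` matrix of test frames.
#' @return The winning model's `subject_id` (or its index as a string if
#'   the model carries no id), with the per-model total log-likelihoods
#'   attached as attribute `scores`.
#' @export
identify_subject <- function(models, X) {
  if (!length(models)) stop("`models` must contain at least one model")
  scores <- vapply(models, function(m) sum(log_density(m, X)), numeric(1))
  ids <- vapply(seq_along(models), function(i) {
    id <- models[[i]]$subject_id
    if (is.null(id)) as.character(i) else id
  }, character(1))
  best <- which.max(scores)                  # which.max takes the first tie
  structure(ids[best], scores = setNames(scores, ids))
}

#' Log-likelihood-ratio transform of a test segment
#'
#' Frame-averaged log-likelihood ratio of every subject model against the
#' UBM: entry `s` is `(1/T) sum_t [log p(x_t | lambda_s) - log p(x_t | UBM)]`.
#' A segment is thereby re-expressed as an `S`-dimensional vector of
#' subject-model scores - a discriminative transform of the fusion
#' features.
#'
#' @param models List of `S` subject models.
#' @param ubm The [ssvep_gmm()] UBM the models were adapted from.
#' @param X `n x d` matrix of test frames.
#' @return A named numeric vector of length `S`.
#' @export
llr_transform <- function(models, ubm, X) {
  if (!length(models)) stop("`models` must contain at least one model")
  stopifnot(inherits(ubm, "ssvep_gmm"))
  lp0 <- log_density(ubm, X)
  out <- vapply(models, function(m) mean(log_density(m, X) - lp0), numeric(1))
  names(out) <- vapply(seq_along(models), function(i) {
    id <- models[[i]]$subject_id
    if (is.null(id)) sprintf("llr_%d", i) else paste0("llr_", id)
  }, character(1))
  out
}

#' Supervector transform of a test segment
#'
#' A higher-resolution discriminative transform: one scalar per (subject
#' model, mixture component) pair, namely the frame-averaged weighted
#' component log-density
#' `(1/T) sum_t log[xi_m N(x_t | mu_m^s, Sigma_m^s)]`
#' against the MAP-adapted component. With `S` subjects and `M` components
#' the supervector has length `S x M` (subject-major ordering), e.g. 40,
#' 80 or 160 dimensions for 10 subjects and M = 4, 8, 16.
#'
#' @param models List of `S` subject models sharing the same `M`.
#' @param X `n x d` matrix of test frames.
#' @return A named numeric vector of length `S * M`.
#' @export
supervector_transform <- function(models, X) {
  if (!length(models)) stop("`models` must contain at least one model")
  Ms <- vapply(models, function(m) m$M, integer(1))
  if (length(unique(Ms)) != 1L) {
    stop("all subject models must share the same number of components")
  }
  pieces <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    v <- colMeans(.comp_logdens(m, X))
    id <- if (is.null(m$subject_id)) as.character(i) else m$subject_id
    setNames(v, sprintf("sv_%s_m%d", id, seq_len(m$M)))
  })
  unlist(pieces)
}

#' Transform a per-frame feature table into per-trial decoder features
#'
#' Groups the frame-level fusion features by trial and emits one feature
#' row per trial in the requested space: the raw 54-dimensional fusion
#' vector (frame-averaged), the `S`-dimensional LLR vector, or the
#' `S x M`-dimensional supervector.
#'
#' @param features Frame-level feature tibble from [extract_features()].
#' @param models List of subject models (required for `"llr"` and
#'   `"supervector"`).
#' @param ubm The UBM (required for `"llr"`).
#' @param mode One of `"fusion"`, `"llr"`, `"supervector"`.
#' @return A tibble, one row per trial: `subject`, `frequency`, `trial`,
#'   then the feature columns of the chosen space.
#' @export
transform_features <- function(features, models = NULL, ubm = NULL,
                               mode = c("supervector", "llr", "fusion")) {
  mode <- match.arg(mode)
  if (mode != "fusion" && is.null(models)) {
    stop("`models` is required for mode '", mode, "'")
  }
  if (mode == "llr" && is.null(ubm)) stop("`ubm` is required for mode 'llr'")
  feat_cols <- setdiff(names(features),
                       c("subject", "frequency", "trial", "frame", "channel"))
  grouped <- features |>
    dplyr::group_by(.data$subject, .data$frequency, .data$trial)
  keys <- dplyr::group_keys(grouped)
  rows <- grouped |>
    dplyr::group_map(function(df, key) {
      X <- as.matrix(df[, feat_cols, drop = FALSE])
      v <- switch(mode,
        fusion = setNames(colMeans(X), feat_cols),
        llr = llr_transform(models, ubm, X),
        supervector = supervector_transform(models, X)
      )
      tibble::as_tibble_row(as.list(v))
    })
  dplyr::bind_cols(keys, dplyr::bind_rows(rows))
}

#' @method tidy ssvep_gmm
#' @export
tidy.ssvep_gmm <- function(x, ...) {
  tibble::tibble(
    component = rep(seq_len(x$M), each = x$d),
    dimension = rep(seq_len(x$d), times = x$M),
    weight = rep(x$weights, each = x$d),
    mean = as.vector(t(x$means)),
    variance = as.vector(t(x$variances))
  )
}

#' @method glance ssvep_gmm
#' @export
glance.ssvep_gmm <- function(x, ...) {
  ll <- attr(x, "log_likelihood")
  tibble::tibble(
    components = x$M, dimensions = x$d,
    log_likelihood = if (length(ll)) ll[length(ll)] else NA_real_,
    iterations = length(ll),
    subject = if (is.null(x$subject_id)) NA_character_ else x$subject_id
  )
}
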