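#' SVM decoder configuration
#'
#' Settings for the RBF soft-margin SVM that decodes the attended target
#' frequency from transformed feature vectors, and for the stratified
#' cross-validation harness with its nested hyperparameter grid search.
#'
#' @param cost_grid Candidate soft-margin trade-off values `C`.
#' @param gamma_grid Candidate RBF widths (`gamma = 1 / (2 * sigma^2)`).
#' @param folds Outer cross-validation folds.
#' @param inner_folds Folds of the nested grid-search cross-validation run
#'   inside each training fold.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(cost_grid = c(0.1, 1, 10, 100),
                           gamma_grid = 10^seq(-3, 1),
                           folds = 10, inner_folds = 3, seed = 1) {
  stopifnot(all(cost_grid > 0), all(gamma_grid > 0), folds >= 2,
            inner_folds >= 2)
  structure(
    list(cost_grid = cost_grid, gamma_grid = gamma_grid,
         folds = folds, inner_folds = inner_folds, seed = seed),
    class = "decoder_config"
  )
}

#' Train a multiclass soft-margin RBF SVM
#'
#' One-vs-one soft-margin SVM with a radial basis kernel. Features are
#' standardised with statistics of the training data only; the returned
#' model carries the centring/scaling so that test data is mapped into the
#' same space.
#'
#' @param X `n x d` numeric feature matrix.
#' @param y Class labels (coerced to factor); at least two classes.
#' @param cost Soft-margin trade-off `C`.
#' @param gamma RBF kernel width.
#' @return An object of class `ssvep_svm`.
#' @export
svm_train <- function(X, y, cost = 1, gamma = 1 / (2 * ncol(X))) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("training data contains a single class ('", levels(y)[1],
         "'); at least two classes are required")
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center, scale_)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_,
                 levels = levels(y), cost = cost, gamma = gamma),
            class = "ssvep_svm")
}

#' @export
predict.ssvep_svm <- function(object, newdata, decision.values = FALSE, ...) {
  Xs <- scale(as.matrix(newdata), object$center, object$scale)
  predict(object$fit, Xs, decision.values = decision.values, ...)
}

# stratified fold assignment: per class, shuffled round-robin with a
# rotating offset so overall fold sizes differ by at most one
.stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop(sprintf(
          "class '%s' has %d samples, fewer than %d folds; reduce `folds`",
          cl, length(idx), k))
      }
      idx <- sample(idx)
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

# mean accuracy of (cost, gamma) over an inner stratified CV
.grid_point_score <- function(X, y, cost, gamma, inner_fold) {
  correct <- 0L
  for (f in sort(unique(inner_fold))) {
    tr <- inner_fold != f
    fit <- svm_train(X[tr, , drop = FALSE], y[tr], cost, gamma)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Stratified cross-validated decoding
#'
#' Stratified k-fold cross-validation of the RBF SVM decoder with the
#' hyperparameter grid search nested inside each training fold: for every
#' outer fold, each `(C, gamma)` pair is scored by an inner stratified
#' cross-validation on the training fold only, the winner is refit on the
#' whole training fold, and the held-out fold is predicted once. Every
#' sample is validated exactly once.
#'
#' @param features A per-trial feature tibble (see [transform_features()])
#'   or a numeric matrix.
#' @param labels Class labels; defaults to the `frequency` column when
#'   `features` is a tibble.
#' @param config A [decoder_config()].
#' @return An object of class `ssvep_cv`: per-fold accuracies and chosen
#'   hyperparameters, mean accuracy (%), and the pooled confusion matrix.
#' @export
cross_validate <- function(features, labels = NULL,
                           config = decoder_config()) {
  if (is.data.frame(features)) {
    if (is.null(labels)) {
      if (!"frequency" %in% names(features)) {
        stop("`labels` not given and `features` has no `frequency` column")
      }
      labels <- features$frequency
    }
    X <- feature_matrix(features)
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("`labels` is required for matrix input")
  }
  y <- factor(labels)
  fold <- .stratified_folds(y, config$folds, config$seed)
  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid)

  per_fold <- purrr::map(sort(unique(fold)), function(f) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    inner <- .stratified_folds(ytr, config$inner_folds,
                               seed = config$seed + f)
    scores <- purrr::pmap_dbl(grid, function(cost, gamma) {
      .grid_point_score(Xtr, ytr, cost, gamma, inner)
    })
    best <- grid[which.max(scores), ]
    fit <- svm_train(Xtr, ytr, best$cost, best$gamma)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    tibble::tibble(
      fold = f,
      accuracy = 100 * mean(as.character(pred) == as.character(y[!tr])),
      cost = best$cost, gamma = best$gamma,
      truth = list(as.character(y[!tr])), predicted = list(as.character(pred))
    )
  }) |> dplyr::bind_rows()

  confusion <- table(
    truth = factor(unlist(per_fold$truth), levels = levels(y)),
    predicted = factor(unlist(per_fold$predicted), levels = levels(y))
  )
  structure(
    list(fold_results = per_fold[, c("fold", "accuracy", "cost", "gamma")],
         mean_accuracy = mean(per_fold$accuracy),
         confusion = confusion, config = config, n = nrow(X),
         classes = levels(y)),
    class = "ssvep_cv"
  )
}

#' @export
print.ssvep_cv <- function(x, ...) {
  cat(sprintf("<ssvep_cv> %d-fold stratified CV on %d trials, %d classes\n",
              x$config$folds, x$n, length(x$classes)))
  cat(sprintf("  mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}

#' @method tidy ssvep_cv
#' @export
tidy.ssvep_cv <- function(x, ...) x$fold_results

#' @method glance ssvep_cv
#' @export
glance.ssvep_cv <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = sd(x$fold_results$accuracy),
    folds = x$config$folds, n = x$n, classes = length(x$classes)
  )
}

#' Classification accuracy of a confusion matrix
#'
#' @param confusion A square nonnegative confusion matrix (rows = truth,
#'   columns = prediction).
#' @return Accuracy in percent: `100 * trace / total`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!length(confusion) || sum(confusion) == 0) {
    stop("confusion matrix is empty")
  }
  if (any(confusion < 0)) stop("confusion matrix must be nonnegative")
  100 * sum(diag(confusion)) / sum(confusion)
}

#' Information transfer rate
#'
#' Bits communicated per minute for an `M`-target selection task with
#' accuracy `P` and `t` seconds per selection:
#' `B = log2(M) + P log2(P) + (1 - P) log2((1 - P) / (M - 1))` bits per
#' selection (with `0 log 0 = 0`), scaled by `60 / t` selections per
#' minute. At chance (`P = 1/M`) the rate is zero.
#'
#' @param P Selection accuracy in `[0, 1]`.
#' @param M Number of selectable targets (`>= 2`).
#' @param t Time per selection in seconds.
#' @return ITR in bits per minute.
#' @export
#' @examples
#' itr(1, 4, 30)    # 2 bits/selection at 2 selections/min = 4 bit/min
#' itr(0.25, 4, 10) # chance: 0
itr <- function(P, M, t) {
  if (P < 0 || P > 1) stop("`P` must lie in [0, 1]")
  stopifnot(M >= 2, t > 0)
  plog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  B <- log2(M) + plog2(P) + plog2(1 - P) - (1 - P) * log2(M - 1)
  max(B, 0) * 60 / t
}
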