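#' Random Forest hyperparameter specification
#'
#' @param n_estimators Number of trees (>= 1). Default 300.
#' @param max_depth Maximum tree depth, or `NULL` for unlimited.
#' @param min_samples_split Minimum node size eligible for splitting (>= 2).
#' @param max_features `"sqrt"`, `"log2"`, or a fraction in (0, 1] of the
#'   number of features tried at each split.
#' @param seed Integer seed; identical seeds give identical forests.
#' @return Object of class `forest_spec`.
#' @export
forest_spec <- function(n_estimators = 300L, max_depth = NULL,
                        min_samples_split = 2L, max_features = "sqrt",
                        seed = 1L) {
  if (n_estimators < 1L) stop("n_estimators must be >= 1", call. = FALSE)
  if (min_samples_split < 2L) stop("min_samples_split must be >= 2", call. = FALSE)
  if (is.character(max_features)) {
    if (!max_features %in% c("sqrt", "log2")) {
      stop("max_features must be 'sqrt', 'log2' or a fraction", call. = FALSE)
    }
  } else if (max_features <= 0 || max_features > 1) {
    stop("fractional max_features must be in (0, 1]", call. = FALSE)
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 max_features = max_features,
                 seed = as.integer(seed)),
            class = "forest_spec")
}

resolve_mtry <- function(max_features, p) {
  m <- if (identical(max_features, "sqrt")) {
    ceiling(sqrt(p))
  } else if (identical(max_features, "log2")) {
    max(1, ceiling(log2(p)))
  } else {
    max(1, round(max_features * p))
  }
  min(m, p)
}

#' Stratified train/test split
#'
#' Per class, `round(n_class * test_fraction)` records go to the test set,
#' so every class keeps its overall proportion within one record.
#' Deterministic per seed.
#'
#' @param labels Class label vector.
#' @param test_fraction Fraction held out, in (0, 1). Default 0.2.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("stratification requires every class to have >= 2 members; singleton: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    test <- integer(0)
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      n_test <- min(max(round(length(idx) * test_fraction), 1L), length(idx) - 1L)
      test <- c(test, sort(sample(idx, n_test)))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Stratified cross-validation folds
#' @keywords internal
stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs at least as many members as folds; too small: ",
         paste(names(counts)[counts < folds], collapse = ", "), call. = FALSE)
  }
  fold_of <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in sort(names(counts))) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

#' Train a probability Random Forest
#'
#' Ensemble of trees grown on bootstrap resamples with per-split feature
#' subsampling; predictions are probability averages across trees. Backed by
#' [ranger::ranger()] with single-threaded, seeded execution so identical
#' seeds give identical forests.
#'
#' @param x Data frame of features (numeric and/or factor columns).
#' @param y Class labels (coerced to factor).
#' @param spec A [forest_spec()].
#' @return Object of class `hl_forest` wrapping the fitted ensemble.
#' @export
train_forest <- function(x, y, spec = forest_spec()) {
  y <- droplevels(as.factor(y))
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (nlevels(y) < 2L) stop("training set must contain at least two classes", call. = FALSE)
  num <- vapply(x, is.numeric, TRUE)
  if (any(num) && !all(is.finite(as.matrix(x[, num, drop = FALSE])))) {
    stop("features must be finite", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = spec$n_estimators,
    mtry = resolve_mtry(spec$max_features, ncol(x)),
    min.node.size = spec$min_samples_split,
    max.depth = if (is.null(spec$max_depth)) 0L else spec$max_depth,
    probability = TRUE,
    importance = "impurity",
    seed = spec$seed,
    num.threads = 1L
  )
  structure(list(fit = fit, classes = levels(y), features = names(x), spec = spec),
            class = "hl_forest")
}

#' Predict class probabilities
#'
#' @param object An `hl_forest`.
#' @param newdata Feature data frame with the training schema.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
predict.hl_forest <- function(object, newdata, ...) {
  if (!identical(names(newdata), object$features)) {
    stop("feature schema mismatch: expected columns ",
         paste(object$features, collapse = ", "), call. = FALSE)
  }
  p <- stats::predict(object$fit, data = newdata, num.threads = 1L)$predictions
  p[, object$classes, drop = FALSE]
}

#' Multi-class log loss
#'
#' Mean negative log predicted probability of the true class, with
#' probabilities clipped to `[eps, 1 - eps]` before the log. Natural
#' logarithm: perfect confident prediction scores 0 and uniform guessing
#' over C classes scores log(C).
#'
#' @param prob Probability matrix with class columns.
#' @param truth True class labels.
#' @param eps Clipping constant. Default 1e-15.
#' @return Log loss in nats.
#' @export
log_loss <- function(prob, truth, eps = 1e-15) {
  truth <- as.character(truth)
  if (!all(truth %in% colnames(prob))) {
    stop("truth contains classes absent from the probability matrix", call. = FALSE)
  }
  p <- prob[cbind(seq_along(truth), match(truth, colnames(prob)))]
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(log(p))
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Precision is the positive
#' predictive value per predicted class, recall the sensitivity per true
#' class, F1 their harmonic mean (0 when undefined).
#'
#' @param confusion Square counts matrix, rows = truth, columns = predicted.
#' @return List with accuracy, per-class precision/recall/f1.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / sum(confusion),
       precision = stats::setNames(precision, rownames(confusion)),
       recall = stats::setNames(recall, rownames(confusion)),
       f1 = stats::setNames(f1, rownames(confusion)))
}

#' Evaluate a fitted forest on a test set
#'
#' @param model An `hl_forest`.
#' @param x_test,y_test Held-out features and labels.
#' @return Object of class `metrics_report`: accuracy, per-class
#'   precision/recall/F1, log_loss, confusion matrix (rows = truth).
#' @export
evaluate <- function(model, x_test, y_test) {
  if (nrow(x_test) == 0L) stop("empty test set", call. = FALSE)
  prob <- predict(model, x_test)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  lv <- union(model$classes, unique(as.character(y_test)))
  confusion <- table(truth = factor(as.character(y_test), levels = lv),
                     predicted = factor(pred, levels = lv))
  m <- metrics_from_confusion(confusion)
  structure(list(accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1,
                 log_loss = log_loss(prob, y_test),
                 confusion = confusion, n = nrow(x_test)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.4f, log loss = %.4f\n",
              x$n, x$accuracy, x$log_loss))
  tab <- cbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(tab, 4))
  invisible(x)
}

#' Stratified k-fold cross-validation accuracy
#'
#' Mean and population standard deviation (divide by the number of folds) of
#' per-fold hold-out accuracies.
#'
#' @param x,y Full dataset features and labels.
#' @param spec A [forest_spec()].
#' @param folds Number of folds (>= 2). Default 5.
#' @param seed Integer seed for fold composition.
#' @return List with `mean`, `std`, `fold_accuracy`.
#' @export
cross_validate <- function(x, y, spec = forest_spec(), folds = 5L, seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  y <- as.character(y)
  fold_of <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    model <- train_forest(x[tr, , drop = FALSE], y[tr], spec)
    prob <- predict(model, x[!tr, , drop = FALSE])
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    mean(pred == y[!tr])
  }, 0)
  list(mean = mean(acc),
       std = sqrt(mean((acc - mean(acc))^2)),
       fold_accuracy = acc)
}

#' Grid search over forest hyperparameters
#'
#' Evaluates every combination by stratified k-fold cross-validation
#' accuracy; ties are broken toward the smaller model (fewer trees, then
#' shallower depth).
#'
#' @param x,y Training data.
#' @param grid Named list of candidate values for `n_estimators`,
#'   `max_depth`, `min_samples_split`, `max_features` (missing entries use
#'   the [forest_spec()] defaults). `NA` in `max_depth` means unlimited.
#' @param folds CV folds. Default 5.
#' @param seed Integer seed (fold composition and forests).
#' @return List with `best` ([forest_spec()]) and `scores` (data frame of
#'   every combination and its CV mean/std).
#' @export
grid_search <- function(x, y, grid, folds = 5L, seed = 1L) {
  defaults <- list(n_estimators = 300L, max_depth = NA, min_samples_split = 2L,
                   max_features = "sqrt")
  for (nm in names(defaults)) if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0L) stop("empty grid", call. = FALSE)
  combos$cv_mean <- NA_real_
  combos$cv_std <- NA_real_
  for (i in seq_len(nrow(combos))) {
    spec <- forest_spec(
      n_estimators = combos$n_estimators[i],
      max_depth = if (is.na(combos$max_depth[i])) NULL else combos$max_depth[i],
      min_samples_split = combos$min_samples_split[i],
      max_features = combos$max_features[i],
      seed = seed
    )
    cv <- cross_validate(x, y, spec, folds = folds, seed = seed)
    combos$cv_mean[i] <- cv$mean
    combos$cv_std[i] <- cv$std
  }
  depth_rank <- ifelse(is.na(combos$max_depth), Inf, combos$max_depth)
  ord <- order(-combos$cv_mean, combos$n_estimators, depth_rank)
  b <- combos[ord[1L], ]
  best <- forest_spec(n_estimators = b$n_estimators,
                      max_depth = if (is.na(b$max_depth)) NULL else b$max_depth,
                      min_samples_split = b$min_samples_split,
                      max_features = b$max_features,
                      seed = seed)
  list(best = best, scores = combos)
}

#' Normalized feature importances
#'
#' Mean impurity-decrease importances of a fitted forest, normalized to sum
#' to one and sorted in descending order. A feature constant across the
#' training records gets weight 0.
#'
#' @param model An `hl_forest`.
#' @return Named numeric vector of weights summing to 1.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "hl_forest")) stop("model must be a fitted hl_forest", call. = FALSE)
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  sort(imp, decreasing = TRUE)
}
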