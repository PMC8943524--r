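# CV regression: train/validation split, k-fold grid search over
# gradient-boosted trees, evaluation metrics and SHAP-style attribution.

#' Split labeled examples into training and validation sets
#'
#' The training set receives `floor(train_fraction * n)` examples; with
#' `shuffle = TRUE` the assignment is a seed-determined random partition,
#' otherwise the first rows train.
#'
#' @param x A data frame (split by rows) or a vector.
#' @param train_fraction Fraction of examples for training, in (0, 1);
#'   default 0.8.
#' @param seed Integer seed controlling the shuffle.
#' @param shuffle Randomise before splitting (default TRUE).
#' @return A list with `train`, `validation`, and the corresponding index
#'   vectors `train_idx`, `validation_idx`.
#' @export
#' @examples
#' sp <- split_train_validation(seq_len(4431), seed = 1)
#' length(sp$train)       # 3544
#' length(sp$validation)  # 887
split_train_validation <- function(x, train_fraction = 0.8, seed = 1,
                                   shuffle = TRUE) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 2L) stop("need at least 2 examples to split, got ", n, call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- floor(train_fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop("train_fraction ", train_fraction, " leaves an empty set for n = ", n,
         call. = FALSE)
  }
  idx <- if (shuffle) withr::with_seed(seed, sample.int(n)) else seq_len(n)
  train_idx <- sort(idx[seq_len(n_train)])
  validation_idx <- sort(idx[(n_train + 1L):n])
  take <- function(i) if (is.data.frame(x)) x[i, , drop = FALSE] else x[i]
  list(train = take(train_idx), validation = take(validation_idx),
       train_idx = train_idx, validation_idx = validation_idx)
}

#' Hyperparameter grids for the boosted-tree regressor
#'
#' `"default"` is a small desk-scale grid (24 combinations); `"full"` is a
#' 1152-combination grid spanning depth, learning rate, boosting rounds,
#' L1/L2 regularisation and row/column subsampling.
#'
#' @param preset `"default"` or `"full"`.
#' @return A data frame with one row per hyperparameter combination.
#' @export
hyper_grid_preset <- function(preset = c("default", "full")) {
  preset <- match.arg(preset)
  grid <- switch(preset,
    default = list(max_depth = c(3, 5, 7), eta = c(0.1, 0.3),
                   nrounds = c(60, 120), subsample = c(0.8, 1)),
    full = list(max_depth = c(3, 4, 5, 6), eta = c(0.05, 0.1, 0.2, 0.3),
                nrounds = c(50, 100, 200), lambda = c(0.5, 1),
                alpha = c(0, 0.5), subsample = c(0.6, 0.8, 1),
                colsample_bytree = c(0.8, 1))
  )
  hyper_grid(grid)
}

#' Expand named hyperparameter lists into a grid
#'
#' @param values Named list; each element a vector of candidate values.
#'   Recognised names: `max_depth`, `eta`, `nrounds`, `lambda`, `alpha`,
#'   `subsample`, `colsample_bytree`, `min_child_weight`, `gamma`.
#' @return Data frame with `prod(lengths(values))` rows.
#' @export
hyper_grid <- function(values) {
  if (length(values) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  known <- c("max_depth", "eta", "nrounds", "lambda", "alpha", "subsample",
             "colsample_bytree", "min_child_weight", "gamma")
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(expand.grid(values, KEEP.OUT.ATTRS = FALSE))
}

as_xgb_params <- function(hyperparams, seed) {
  hp <- as.list(hyperparams)
  hp$nrounds <- NULL
  c(hp, list(objective = "reg:squarederror", nthread = 1, seed = seed))
}

#' Grid search by k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by k-fold cross-validated
#' mean squared error and returns the minimiser together with the full
#' score table. Fold assignment is determined entirely by `seed`.
#'
#' @param features Numeric feature matrix or data frame.
#' @param labels Numeric label vector (CV in volts).
#' @param grid Data frame of hyperparameter combinations, e.g. from
#'   [hyper_grid_preset()].
#' @param k_folds Number of folds (default 3).
#' @param seed Integer seed for fold assignment and tree fitting.
#' @return A list with `best` (one-row data frame), `best_index`, and
#'   `scores` (the grid plus a `cv_mse` column).
#' @export
grid_search <- function(features, labels, grid, k_folds = 3, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0L) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n >= k_folds, length(labels) == n)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
    fold_mse <- vapply(seq_len(k_folds), function(f) {
      hold <- folds == f
      fit <- fit_booster(x[!hold, , drop = FALSE], labels[!hold],
                         grid[i, , drop = FALSE], seed)
      pred <- predict_booster(fit, x[hold, , drop = FALSE])
      mean((pred - labels[hold])^2)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  best_index <- which.min(cv_mse)
  scores <- grid
  scores$cv_mse <- cv_mse
  list(best = grid[best_index, , drop = FALSE], best_index = best_index,
       scores = scores)
}

fit_booster <- function(x, y, hyperparams, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  nrounds <- if ("nrounds" %in% names(hyperparams)) hyperparams$nrounds else 100
  withr::with_seed(seed,
    xgboost::xgb.train(as_xgb_params(hyperparams, seed), dtrain,
                       nrounds = nrounds, verbose = 0))
}

predict_booster <- function(booster, x) {
  predict(booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Train the boosted-tree CV regressor
#'
#' Fits a gradient-boosted tree regressor (squared-error objective) on a
#' feature matrix and CV labels. The returned object carries the feature
#' names and hyperparameters and is deterministic under a fixed seed.
#'
#' @param features Numeric feature matrix or data frame (rows = examples).
#' @param labels CV labels in volts.
#' @param hyperparams One-row data frame or named list (see [hyper_grid()]);
#'   default `list(max_depth = 6, eta = 0.1, nrounds = 200)`.
#' @param seed Integer seed.
#' @return An object of class `faims_cv_model`.
#' @export
train_cv_regressor <- function(features, labels,
                               hyperparams = list(max_depth = 6, eta = 0.1,
                                                  nrounds = 200),
                               seed = 1) {
  x <- as.matrix(features)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (!all(is.finite(labels))) stop("non-finite labels", call. = FALSE)
  booster <- fit_booster(x, labels, as.data.frame(hyperparams), seed)
  structure(
    list(booster = booster, feature_names = colnames(x),
         hyperparams = as.list(hyperparams), seed = seed, n_train = nrow(x)),
    class = "faims_cv_model"
  )
}

#' Predict CVs from a fitted model
#'
#' @param object A `faims_cv_model`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Predicted CV values in volts.
#' @export
predict.faims_cv_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    missing <- setdiff(object$feature_names, colnames(x))
    if (length(missing) > 0L) {
      stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  predict_booster(object$booster, x)
}

#' @export
print.faims_cv_model <- function(x, ...) {
  cat("faims_cv_model: gradient-boosted CV regressor\n")
  cat("  features:", length(x$feature_names), " training examples:",
      x$n_train, "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Prediction metrics against observed CVs
#'
#' Computes the Pearson correlation, mean squared error and the fractions
#' of predictions within +-5 V and +-10 V of the observed CV (boundaries
#' inclusive). A degenerate Pearson correlation (zero variance on either
#' side) is reported as 0 with `degenerate = TRUE`.
#'
#' @param predicted Predicted CVs (volts).
#' @param observed Observed CVs (volts).
#' @return A list with `pearson`, `mse`, `frac_within_5`, `frac_within_10`,
#'   `n` and `degenerate`.
#' @export
cv_metrics <- function(predicted, observed) {
  n <- length(observed)
  if (n == 0L) stop("no examples to evaluate", call. = FALSE)
  stopifnot(length(predicted) == n)
  err <- predicted - observed
  degenerate <- stats::sd(predicted) == 0 || stats::sd(observed) == 0
  pearson <- if (degenerate) 0 else stats::cor(predicted, observed)
  list(pearson = pearson, mse = mean(err^2),
       frac_within_5 = mean(abs(err) <= 5),
       frac_within_10 = mean(abs(err) <= 10),
       n = n, degenerate = degenerate)
}

#' Evaluate a fitted model on labeled examples
#'
#' @param model A `faims_cv_model`.
#' @param features Feature matrix or data frame.
#' @param labels Observed CVs (volts).
#' @return Metrics as in [cv_metrics()].
#' @export
evaluate_cv_model <- function(model, features, labels) {
  cv_metrics(predict(model, features), labels)
}

#' SHAP-style feature attribution for a fitted model
#'
#' Computes per-example per-feature additive attributions with the tree
#' path-dependent explainer (via the booster's contribution predictions)
#' and a global ranking by mean absolute attribution. Local accuracy holds:
#' each example's attributions plus the base value sum to its prediction.
#'
#' @param model A `faims_cv_model`.
#' @param features Feature matrix or data frame to explain (typically the
#'   validation set).
#' @return A list with `values` (n x p attribution matrix, volts),
#'   `base_value` (expected model output), and `importance` (tibble of
#'   `feature`, `mean_abs_shap`, sorted descending).
#' @export
shap_importance <- function(model, features) {
  if (!inherits(model, "faims_cv_model")) {
    stop("model must be a faims_cv_model with tree structure", call. = FALSE)
  }
  x <- as.matrix(features)
  if (!is.null(colnames(x)) && !is.null(model$feature_names)) {
    x <- x[, model$feature_names, drop = FALSE]
  }
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1),
                     predcontrib = TRUE)
  p <- ncol(x)
  values <- contrib[, seq_len(p), drop = FALSE]
  colnames(values) <- colnames(x)
  base <- contrib[, p + 1L]
  imp <- colMeans(abs(values))
  importance <- tibble::tibble(feature = names(imp), mean_abs_shap = unname(imp))
  importance <- importance[order(-importance$mean_abs_shap), ]
  list(values = values, base_value = base, importance = importance)
}
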