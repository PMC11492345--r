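#' Specification of a tree-ensemble GPR regressor
#'
#' Defaults follow the tuned hyperparameters of the reference workflow:
#' random forest with 150 trees, depth 10, `min_split` 5, `min_leaf` 1;
#' gradient boosting with 180 trees, depth 12, `min_split` 10, `min_leaf` 4
#' and learning rate 0.01. `min_split` is the minimum number of samples
#' needed to split an internal node, `min_leaf` the minimum per leaf.
#'
#' @param family `"random_forest"` or `"gradient_boosting"`.
#' @param n_trees,max_depth,min_split,min_leaf tree-growing controls.
#' @param learning_rate shrinkage (gradient boosting only).
#' @param mtry features considered per split; `NULL` = all (both ensembles
#'   consider every feature by default).
#' @param seed integer RNG seed for the fit.
#' @return A list of class `regressor_spec`.
#' @export
regressor_spec <- function(family = c("random_forest", "gradient_boosting"),
                           n_trees = NULL, max_depth = NULL, min_split = NULL,
                           min_leaf = NULL, learning_rate = NULL, mtry = NULL,
                           seed = 1L) {
  family <- match.arg(family)
  d <- if (family == "random_forest") {
    list(n_trees = 150L, max_depth = 10L, min_split = 5L, min_leaf = 1L, learning_rate = NA_real_)
  } else {
    list(n_trees = 180L, max_depth = 12L, min_split = 10L, min_leaf = 4L, learning_rate = 0.01)
  }
  structure(
    list(
      family = family,
      n_trees = as.integer(n_trees %||% d$n_trees),
      max_depth = as.integer(max_depth %||% d$max_depth),
      min_split = as.integer(min_split %||% d$min_split),
      min_leaf = as.integer(min_leaf %||% d$min_leaf),
      learning_rate = as.numeric(learning_rate %||% d$learning_rate),
      mtry = if (is.null(mtry)) NA_integer_ else as.integer(mtry),
      seed = as.integer(seed)
    ),
    class = "regressor_spec"
  )
}

#' Feature matrix from complexity vectors
#'
#' @param vectors a data.frame holding the 27 metric columns (extra columns
#'   ignored), or a list of named 27-metric vectors.
#' @return List with `X` (numeric matrix, columns in [metric_names()]
#'   order) and `names`.
#' @export
make_feature_matrix <- function(vectors) {
  cols <- metric_names()
  if (is.data.frame(vectors)) {
    missing <- setdiff(cols, names(vectors))
    if (length(missing)) stopf("missing metric columns: %s", paste(missing, collapse = ", "))
    X <- as.matrix(vectors[, cols])
  } else {
    X <- do.call(rbind, lapply(vectors, function(v) v[cols]))
    colnames(X) <- cols
  }
  storage.mode(X) <- "double"
  if (nrow(X) == 0L) stopf("empty feature matrix")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf(
      "invalid feature: non-finite %s in row %d", cols[bad[1, 2]],
      bad[1, 1]
    )
  }
  list(X = X, names = cols)
}

#' Reproducible train/test split
#'
#' @param n_rows number of rows.
#' @param frac training fraction in (0, 1); `round(frac * n)` rows train.
#' @param seed RNG seed.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n_rows, frac = 0.8, seed = 1L) {
  if (frac <= 0 || frac >= 1) stopf("frac must lie in (0, 1)")
  if (n_rows < 10L) stopf("need >= 10 rows to split")
  perm <- with_seed(seed, sample.int(n_rows))
  n_train <- round(frac * n_rows)
  list(train = sort(perm[seq_len(n_train)]), test = sort(perm[-seq_len(n_train)]))
}

fit_engine <- function(spec, X, y) {
  mtry <- if (is.na(spec$mtry)) ncol(X) else spec$mtry
  with_seed(spec$seed, {
    if (spec$family == "random_forest") {
      .rf_fit(X, y, spec$n_trees, spec$max_depth, spec$min_split, spec$min_leaf, mtry)
    } else {
      .gb_fit(X, y, spec$n_trees, spec$learning_rate, spec$max_depth, spec$min_split, spec$min_leaf)
    }
  })
}

#' Train a final model on a training set
#'
#' @param spec a [regressor_spec()].
#' @param X_train numeric feature matrix (rows >= 10).
#' @param y_train GPR targets (percent).
#' @return An object of class `gpr_model`.
#' @export
train_final <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "regressor_spec"))
  if (nrow(X_train) < 10L) stopf("train_final: need >= 10 training rows")
  if (nrow(X_train) != length(y_train)) stopf("X/y size mismatch")
  engine <- fit_engine(spec, X_train, y_train)
  structure(
    list(
      spec = spec, engine = engine,
      feature_names = colnames(X_train) %||% paste0("x", seq_len(ncol(X_train))),
      n_train = nrow(X_train)
    ),
    class = "gpr_model"
  )
}

#' Predict GPR values, clipped to [0, 100]
#'
#' @param object a `gpr_model` from [train_final()].
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Numeric vector of predicted GPR (percent).
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  if (is.null(object$engine)) stopf("unfitted model")
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  raw <- if (object$spec$family == "random_forest") {
    .rf_predict(object$engine, X)
  } else {
    .gb_predict(object$engine, X)
  }
  pmin(100, pmax(0, raw))
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> %s, %d trees, depth %d, trained on %d rows\n",
    x$spec$family, x$spec$n_trees, x$spec$max_depth, x$n_train
  ))
  invisible(x)
}

#' Impurity-based feature importances
#'
#' Total squared-error reduction attributed to each feature across all
#' trees, normalized to sum 1 and sorted descending (ties broken by name).
#'
#' @param model a `gpr_model`.
#' @return data.frame `feature`, `importance`.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "gpr_model")) stopf("unfitted model")
  imp <- as.numeric(model$engine$importance)
  df <- data.frame(
    feature = model$feature_names, importance = imp,
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$importance, df$feature), ]
  rownames(df) <- NULL
  df
}

#' k-fold cross-validated evaluation
#'
#' Shuffles rows into `k` folds (seeded), trains on each complement and
#' predicts the held-out fold. `mae` and `mse` are over all held-out
#' predictions; `accuracy = 100 - MAPE` where MAPE is the mean absolute
#' percentage error of predicted versus measured GPR. Feature importances
#' come from a final fit on all rows.
#'
#' @param spec a [regressor_spec()].
#' @param X feature matrix.
#' @param y GPR targets, in `[0, 100]`.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @return A list of class `eval_report`: `mae`, `mse`, `accuracy`,
#'   `per_fold_mae`, `feature_importances`, `n_train`, `n_test`,
#'   `predictions` (held-out, in input row order).
#' @export
crossval_evaluate <- function(spec, X, y, k = 5L, seed = 1L) {
  n <- nrow(X)
  if (n < k) stopf("need n >= k")
  if (any(y < 0 | y > 100)) stopf("y must be GPR percentages in [0, 100]")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(fold)) == 0L) stopf("degenerate fold")
  preds <- numeric(n)
  per_fold_mae <- numeric(k)
  for (f in seq_len(k)) {
    hold <- which(fold == f)
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f
    model <- train_final(fold_spec, X[-hold, , drop = FALSE], y[-hold])
    preds[hold] <- predict(model, X[hold, , drop = FALSE])
    per_fold_mae[f] <- mean(abs(preds[hold] - y[hold]))
  }
  final <- train_final(spec, X, y)
  err <- preds - y
  structure(
    list(
      mae = mean(abs(err)), mse = mean(err^2),
      accuracy = 100 - mean(abs(err) / y) * 100,
      per_fold_mae = per_fold_mae,
      feature_importances = feature_importances(final),
      n_train = n, n_test = n, predictions = preds
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> MAE %.3f%%, MSE %.3f, accuracy %.2f%% (n = %d)\n",
    x$mae, x$mse, x$accuracy, x$n_train
  ))
  top <- head(x$feature_importances, 5L)
  cat(
    "top features:",
    paste(sprintf("%s (%.2f)", top$feature, top$importance), collapse = ", "),
    "\n"
  )
  invisible(x)
}
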