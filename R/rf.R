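# Random-forest regressor (ranger backend) with per-tree prediction
# access, impurity importances and grid-search hyperparameter selection.

#' Random-forest configuration
#'
#' @param n_estimators number of trees.
#' @param max_features `"sqrt"`, `"log2"`, or a fraction in (0, 1] of the
#'   feature count tried at each node.
#' @param min_samples_leaf minimum terminal-node size.
#' @param seed integer.
#' @return a `pcm_rf_config` list.
#' @export
rf_config <- function(n_estimators = 1000L, max_features = "sqrt",
                      min_samples_leaf = 1L, seed = 1L) {
  stopifnot(n_estimators >= 1, min_samples_leaf >= 1)
  if (is.character(max_features)) {
    stopifnot(max_features %in% c("sqrt", "log2"))
  } else {
    stopifnot(is.numeric(max_features), max_features > 0, max_features <= 1)
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = max_features,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "pcm_rf_config")
}

.mtry_of <- function(max_features, p) {
  m <- if (identical(max_features, "sqrt")) sqrt(p)
  else if (identical(max_features, "log2")) log2(p)
  else max_features * p
  max(1L, min(p, floor(m)))
}

#' Train a random-forest regressor
#'
#' Bagged CART ensemble (ranger backend). The fitted model retains
#' per-tree prediction access, per-feature impurity importances, and the
#' feature-schema hash of its training matrix so predict-time mismatches
#' fail fast.
#'
#' @param fm training `pcm_features` matrix.
#' @param labels numeric labels (scaled pIC50), one per row.
#' @param config a [rf_config()].
#' @return a `pcm_rf` model.
#' @export
train_rf <- function(fm, labels, config = rf_config()) {
  stopifnot(inherits(fm, "pcm_features"), inherits(config, "pcm_rf_config"))
  n <- nrow(fm$values)
  if (n < 2 || ncol(fm$values) == 0) stop("degenerate training input")
  if (length(labels) != n) stop("labels length must match rows")
  fit <- ranger::ranger(
    x = fm$values, y = as.numeric(labels),
    num.trees = config$n_estimators,
    mtry = .mtry_of(config$max_features, ncol(fm$values)),
    min.node.size = config$min_samples_leaf,
    importance = "impurity",
    seed = config$seed, num.threads = 1L, verbose = FALSE
  )
  structure(list(fit = fit, config = config,
                 block_index = fm$block_index,
                 schema_hash = .schema_hash(fm)),
            class = "pcm_rf")
}

.check_schema <- function(model, fm) {
  if (!identical(model$schema_hash, .schema_hash(fm))) {
    stop("feature-schema mismatch between model and matrix (block layout or columns differ)")
  }
}

#' Predict with per-instance uncertainty from tree spread
#'
#' Mean of the per-tree predictions and their population standard
#' deviation.
#'
#' @param model a `pcm_rf`.
#' @param fm a `pcm_features` matrix with the training schema.
#' @return a `pcm_uncertainty` list with `mean` and `spread` vectors.
#' @export
rf_predict_uncertainty <- function(model, fm) {
  stopifnot(inherits(model, "pcm_rf"), inherits(fm, "pcm_features"))
  .check_schema(model, fm)
  per_tree <- stats::predict(model$fit, fm$values, predict.all = TRUE,
                             num.threads = 1L)$predictions
  m <- rowMeans(per_tree)
  spread <- sqrt(pmax(0, rowMeans(per_tree^2) - m^2))
  structure(list(mean = m, spread = spread), class = "pcm_uncertainty")
}

# Per-tree prediction matrix (rows = instances, cols = trees); used by
# spread-oracle tests.
rf_per_tree_predictions <- function(model, fm) {
  .check_schema(model, fm)
  stats::predict(model$fit, fm$values, predict.all = TRUE,
                 num.threads = 1L)$predictions
}

#' Grid-search hyperparameter optimization for the random forest
#'
#' Trains every combination in the grid and scores it on the validation
#' split; returns the argmin configuration together with the full table.
#'
#' @param grid list with elements `n_estimators`, `max_features`,
#'   `min_samples_leaf` (vectors of candidate values).
#' @param fm_train,labels_train training matrix and labels.
#' @param fm_valid,labels_valid validation matrix and labels.
#' @param seed seed passed to every candidate fit.
#' @return list with `best_config` (a `pcm_rf_config`), `best_mse`, and
#'   `table` (one row per combination with its validation MSE).
#' @export
grid_search_rf <- function(grid, fm_train, labels_train, fm_valid,
                           labels_valid, seed = 1L) {
  stopifnot(is.list(grid),
            all(c("n_estimators", "max_features", "min_samples_leaf") %in% names(grid)),
            all(lengths(grid[c("n_estimators", "max_features", "min_samples_leaf")]) > 0))
  combos <- expand.grid(n_estimators = grid$n_estimators,
                        max_features = grid$max_features,
                        min_samples_leaf = grid$min_samples_leaf,
                        stringsAsFactors = FALSE)
  mse <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    mf <- combos$max_features[i]
    mf_num <- suppressWarnings(as.numeric(mf))
    if (!is.na(mf_num)) mf <- mf_num
    cfg <- rf_config(combos$n_estimators[i], mf,
                     combos$min_samples_leaf[i], seed = seed)
    model <- train_rf(fm_train, labels_train, cfg)
    pred <- rf_predict_uncertainty(model, fm_valid)$mean
    mse[i] <- mean((labels_valid - pred)^2)
  }
  combos$validation_mse <- mse
  best <- which.min(mse)
  mf <- combos$max_features[best]
  mf_num <- suppressWarnings(as.numeric(mf))
  if (!is.na(mf_num)) mf <- mf_num
  list(best_config = rf_config(combos$n_estimators[best], mf,
                               combos$min_samples_leaf[best], seed = seed),
       best_mse = mse[best], table = combos)
}

#' Persist a trained model
#'
#' The stored object embeds the feature-schema fingerprint of its
#' training matrix, so predictions against a mismatched matrix fail fast
#' after reload.
#'
#' @param model a `pcm_rf` or `pcm_ffn`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pcm_rf") || inherits(model, "pcm_ffn"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a persisted model
#'
#' @param path file written by [save_model()].
#' @return the model object.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!(inherits(model, "pcm_rf") || inherits(model, "pcm_ffn"))) {
    stop("not a pcmcp model file")
  }
  model
}

#' Ensemble-average two prediction vectors
#'
#' Elementwise arithmetic mean of two models' mean predictions.
#'
#' @param pred_a,pred_b equal-length numeric vectors (or `pcm_uncertainty`
#'   objects, whose `mean` elements are used).
#' @return numeric vector of averaged predictions.
#' @export
ensemble_average <- function(pred_a, pred_b) {
  a <- if (inherits(pred_a, "pcm_uncertainty")) pred_a$mean else pred_a
  b <- if (inherits(pred_b, "pcm_uncertainty")) pred_b$mean else pred_b
  if (length(a) != length(b)) stop("prediction length mismatch")
  (a + b) / 2
}
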