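# Evaluation: regression metrics (MSE, Pearson r, Kendall tau-b),
# per-protein breakdowns, residual correlation between models, feature
# importance rankings and error-vs-label profiles.

#' Regression metrics
#'
#' MSE, Pearson correlation and tie-corrected Kendall tau-b. Correlations
#' are `NA` (flagged) when either vector has zero variance; the MSE is
#' still computed.
#'
#' @param y_true,y_pred equal-length numeric vectors (n >= 2).
#' @return a `pcm_metrics` list with `mse`, `pearson_r`, `kendall_tau`,
#'   `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  mse <- mean((y_true - y_pred)^2)
  degenerate <- stats::sd(y_true) == 0 || stats::sd(y_pred) == 0
  r <- if (degenerate) NA_real_ else stats::cor(y_true, y_pred)
  tau <- if (degenerate) NA_real_ else
    stats::cor(y_true, y_pred, method = "kendall")
  structure(list(mse = mse, pearson_r = r, kendall_tau = tau,
                 n = length(y_true)),
            class = "pcm_metrics")
}

#' @export
print.pcm_metrics <- function(x, ...) {
  cat(sprintf("n=%d  MSE=%.4f  Pearson r=%.4f  Kendall tau=%.4f\n",
              x$n, x$mse, x$pearson_r, x$kendall_tau))
  invisible(x)
}

#' Per-group performance metrics
#'
#' Metrics per group with more than `min_n` instances, plus the unweighted
#' mean and sample SD across qualifying groups.
#'
#' @param y_true,y_pred instance-level labels and predictions.
#' @param groups group label per instance (e.g. UniProt ID).
#' @param min_n groups with n <= `min_n` are excluded.
#' @return list with `table` (group, n, mse, pearson_r, kendall_tau),
#'   `mean`, `sd`, and `n_groups`; an empty table is flagged via
#'   `n_groups = 0`.
#' @export
per_group_metrics <- function(y_true, y_pred, groups, min_n = 100L) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(groups))
  tab <- table(groups)
  keep <- names(tab)[tab > min_n]
  rows <- lapply(keep, function(g) {
    i <- groups == g
    m <- regression_metrics(y_true[i], y_pred[i])
    data.frame(group = g, n = m$n, mse = m$mse, pearson_r = m$pearson_r,
               kendall_tau = m$kendall_tau, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(group = character(0), n = integer(0), mse = numeric(0),
               pearson_r = numeric(0), kendall_tau = numeric(0))
  metric_cols <- c("mse", "pearson_r", "kendall_tau")
  list(table = out,
       mean = if (nrow(out) > 0) colMeans(out[metric_cols]) else
         stats::setNames(rep(NA_real_, 3), metric_cols),
       sd = if (nrow(out) > 1) vapply(out[metric_cols], stats::sd, numeric(1))
       else stats::setNames(rep(0, 3), metric_cols),
       n_groups = nrow(out))
}

#' Squared correlation of two models' residuals
#'
#' R^2 between (y - pred_a) and (y - pred_b); high values mean the two
#' models make correlated errors and ensembling them buys little.
#'
#' @param y_true labels.
#' @param pred_a,pred_b the two models' predictions.
#' @return squared Pearson correlation (`NA` flagged for zero-variance
#'   residuals).
#' @export
residual_correlation <- function(y_true, pred_a, pred_b) {
  stopifnot(length(y_true) == length(pred_a),
            length(y_true) == length(pred_b))
  ra <- y_true - pred_a; rb <- y_true - pred_b
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  stats::cor(ra, rb)^2
}

.block_of <- function(block_index, idx) {
  out <- character(length(idx))
  for (b in names(block_index)) out[idx %in% block_index[[b]]] <- b
  out
}

#' Impurity-based feature importance of a random forest
#'
#' Per-feature impurity importances normalized to sum 1, ranked descending,
#' with each feature's block label attached.
#'
#' @param model a trained `pcm_rf`.
#' @return data frame (feature, block, importance, rank).
#' @export
rf_impurity_importance <- function(model) {
  stopifnot(inherits(model, "pcm_rf"))
  imp <- ranger::importance(model$fit)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp)
  data.frame(feature = names(imp)[ord],
             block = .block_of(model$block_index, ord),
             importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Permutation feature importance
#'
#' Model-agnostic: the increase in MSE when a feature column is permuted
#' (seeded) within the matrix. Works for either model type via its
#' prediction function.
#'
#' @param model a `pcm_rf` or `pcm_ffn`.
#' @param fm evaluation `pcm_features` matrix.
#' @param y labels.
#' @param features column indices to evaluate (default: all).
#' @param seed permutation seed.
#' @return data frame (feature, block, importance, rank), importance =
#'   permuted MSE - baseline MSE.
#' @export
permutation_importance <- function(model, fm, y, features = NULL, seed = 1L) {
  predict_fun <- if (inherits(model, "pcm_rf")) {
    function(m) rf_predict_uncertainty(model, m)$mean
  } else if (inherits(model, "pcm_ffn")) {
    function(m) predict_ffn(model, m)
  } else stop("unsupported model type")
  if (is.null(features)) features <- seq_len(ncol(fm$values))
  base_mse <- mean((y - predict_fun(fm))^2)
  .with_seed(seed, {
    imp <- vapply(features, function(j) {
      fm2 <- fm
      fm2$values[, j] <- fm2$values[sample.int(nrow(fm2$values)), j]
      mean((y - predict_fun(fm2))^2) - base_mse
    }, numeric(1))
    ord <- order(-imp)
    data.frame(feature = colnames(fm$values)[features][ord],
               block = .block_of(fm$block_index, features[ord]),
               importance = imp[ord],
               rank = seq_along(imp), stringsAsFactors = FALSE)
  })
}

#' Squared error profiled over the label range
#'
#' Buckets squared errors by quantile bins of the true label.
#'
#' @param y_true,y_pred labels and predictions.
#' @param n_bins number of quantile bins (>= 2).
#' @return data frame (bin, lower, upper, n, mse).
#' @export
error_vs_label_profile <- function(y_true, y_pred, n_bins = 10L) {
  stopifnot(n_bins >= 2, length(y_true) == length(y_pred))
  qs <- stats::quantile(y_true, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(y_true, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  err <- (y_true - y_pred)^2
  agg <- tapply(err, bin, mean)
  cnt <- tapply(err, bin, length)
  lo <- tapply(y_true, bin, min); hi <- tapply(y_true, bin, max)
  data.frame(bin = as.integer(names(agg)), lower = as.numeric(lo),
             upper = as.numeric(hi), n = as.integer(cnt),
             mse = as.numeric(agg))
}
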