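# RF and FFN models: determinism, uncertainty contracts, grid search,
# ensembling.

test_that("constant labels give constant predictions with zero spread", {
  mini <- fix_mini_fm()
  model <- train_rf(mini$fm, rep(3.5, nrow(mini$fm$values)),
                    rf_config(n_estimators = 30L, seed = 1L))
  pred <- rf_predict_uncertainty(model, mini$fm)
  expect_equal(pred$mean, rep(3.5, nrow(mini$fm$values)))
  expect_equal(pred$spread, rep(0, nrow(mini$fm$values)))
})

test_that("seed-fixed RF retraining is deterministic", {
  mini <- fix_mini_fm()
  cfg <- rf_config(n_estimators = 50L, seed = 21L)
  p1 <- rf_predict_uncertainty(train_rf(mini$fm, mini$y, cfg), mini$fm)
  p2 <- rf_predict_uncertainty(train_rf(mini$fm, mini$y, cfg), mini$fm)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$spread, p2$spread)
})

test_that("random forests overfit in the expected direction", {
  worse <- 0L
  for (seed in 1:5) {
    mini <- fix_mini_fm(n = 120L, seed = seed)
    tr <- 1:80; va <- 81:120
    fm_tr <- mini$fm; fm_tr$values <- fm_tr$values[tr, ]
    fm_tr$row_keys <- fm_tr$row_keys[tr, ]
    fm_va <- mini$fm; fm_va$values <- fm_va$values[va, ]
    fm_va$row_keys <- fm_va$row_keys[va, ]
    model <- train_rf(fm_tr, mini$y[tr], rf_config(100L, seed = seed))
    mse_tr <- mean((mini$y[tr] - rf_predict_uncertainty(model, fm_tr)$mean)^2)
    mse_va <- mean((mini$y[va] - rf_predict_uncertainty(model, fm_va)$mean)^2)
    if (mse_tr <= mse_va) worse <- worse + 1L
  }
  expect_gte(worse, 4L)
})

test_that("RF tree spread equals a recomputation from per-tree dumps", {
  mini <- fix_mini_fm()
  model <- train_rf(mini$fm, mini$y, rf_config(n_estimators = 200L, seed = 8L))
  pred <- rf_predict_uncertainty(model, mini$fm)
  per_tree <- pcmcp:::rf_per_tree_predictions(model, mini$fm)
  expect_equal(pred$mean, rowMeans(per_tree), tolerance = 1e-12)
  oracle_spread <- apply(per_tree, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_equal(pred$spread, oracle_spread, tolerance = 1e-10)
})

test_that("schema mismatches are rejected at predict time", {
  mini <- fix_mini_fm()
  model <- train_rf(mini$fm, mini$y, rf_config(20L, seed = 1L))
  other <- mini$fm
  colnames(other$values)[2] <- "fp_renamed"
  expect_error(rf_predict_uncertainty(model, other), "schema")
})

test_that("grid search evaluates every combination and returns the argmin", {
  mini <- fix_mini_fm(n = 120L)
  tr <- 1:80; va <- 81:120
  fm_tr <- mini$fm; fm_tr$values <- fm_tr$values[tr, ]; fm_tr$row_keys <- fm_tr$row_keys[tr, ]
  fm_va <- mini$fm; fm_va$values <- fm_va$values[va, ]; fm_va$row_keys <- fm_va$row_keys[va, ]
  grid <- list(n_estimators = c(10L, 25L, 50L),
               max_features = c("sqrt", "log2", "0.3", "0.5"),
               min_samples_leaf = c(1L, 3L, 5L, 10L, 25L))
  res <- grid_search_rf(grid, fm_tr, mini$y[tr], fm_va, mini$y[va], seed = 5L)
  expect_equal(nrow(res$table), 3L * 4L * 5L)
  expect_equal(res$best_mse, min(res$table$validation_mse))
  single <- grid_search_rf(list(n_estimators = 10L, max_features = "sqrt",
                                min_samples_leaf = 3L),
                           fm_tr, mini$y[tr], fm_va, mini$y[va], seed = 5L)
  expect_equal(single$best_config$min_samples_leaf, 3L)
  expect_equal(nrow(single$table), 1L)
})

test_that("FFN outputs stay inside the expanded label range", {
  mini <- fix_mini_fm(n = 100L)
  cfg <- ffn_config(hidden_sizes = c(16L, 8L), epochs = 3L, batch_size = 25L,
                    seed = 2L)
  model <- train_ffn(mini$fm, mini$y, cfg)
  pred <- predict_ffn(model, mini$fm)
  rng <- range(mini$y)
  mid <- mean(rng); half <- diff(rng) / 2 * 1.2
  expect_true(all(pred >= mid - half & pred <= mid + half))
})

test_that("FFN embedding tables have the architecture-contract shape", {
  mats <- fix_mats()
  cfg <- ffn_config(hidden_sizes = c(16L, 8L), epochs = 1L, batch_size = 64L,
                    embedding_dim_per_bit = 2L, seed = 3L)
  model <- train_ffn(mats$fm_train, mats$y_train, cfg)
  emb <- extract_bit_embeddings(model)
  expect_equal(dim(emb), c(4096L, 2L))
  expect_true(all(is.finite(emb)))
  expect_equal(dim(model$par$E0), c(4096L, 2L))
  # different init seeds move the embeddings
  model2 <- train_ffn(mats$fm_train, mats$y_train,
                      ffn_config(hidden_sizes = c(16L, 8L), epochs = 1L,
                                 batch_size = 64L, seed = 4L))
  expect_false(identical(extract_bit_embeddings(model2), emb))
})

test_that("FFN rejects a non-binary fingerprint block", {
  mini <- fix_mini_fm()
  mini$fm$values[1, 1] <- 0.5
  expect_error(train_ffn(mini$fm, mini$y, ffn_config(hidden_sizes = 8L,
                                                     epochs = 1L,
                                                     batch_size = 20L)),
               "binary")
})

test_that("MC-dropout spread is zero without dropout and nonnegative with it", {
  mini <- fix_mini_fm(n = 100L)
  cfg0 <- ffn_config(hidden_sizes = c(16L, 8L), dropout = 0,
                     embedding_dropout = 0, epochs = 2L, batch_size = 25L,
                     seed = 5L)
  m0 <- train_ffn(mini$fm, mini$y, cfg0)
  p0 <- mc_dropout_predict(m0, mini$fm, passes = 5L, seed = 1L)
  expect_identical(p0$spread, rep(0, 100L))
  cfg1 <- ffn_config(hidden_sizes = c(16L, 8L), dropout = 0.25, epochs = 2L,
                     batch_size = 25L, seed = 5L)
  m1 <- train_ffn(mini$fm, mini$y, cfg1)
  p1 <- mc_dropout_predict(m1, mini$fm, passes = 20L, seed = 1L)
  expect_true(all(p1$spread >= 0))
  expect_gt(max(p1$spread), 0)
  expect_error(mc_dropout_predict(m1, mini$fm, passes = 1L), "passes")
})

test_that("MC-dropout means are self-consistent across independent runs", {
  mini <- fix_mini_fm(n = 60L)
  cfg <- ffn_config(hidden_sizes = c(16L, 8L), dropout = 0.25, epochs = 2L,
                    batch_size = 20L, seed = 6L)
  model <- train_ffn(mini$fm, mini$y, cfg)
  pa <- mc_dropout_predict(model, mini$fm, passes = 400L, seed = 11L)
  pb <- mc_dropout_predict(model, mini$fm, passes = 400L, seed = 12L)
  se <- sqrt(pa$spread^2 + pb$spread^2) / sqrt(400)
  ok <- abs(pa$mean - pb$mean) <= 4 * se + 1e-8
  expect_gte(mean(ok), 0.97)
})

test_that("FFN learns the synthetic signal on a random split", {
  prep <- fix_ffn_prep()
  expect_gt(prep$pearson_r, 0.5)
})

test_that("ensemble averaging is the convex mean with the Jensen bound", {
  expect_equal(ensemble_average(0.2, 0.4), 0.3)
  x <- c(1.2, -0.5, 0.3)
  expect_equal(ensemble_average(x, x), x)
  withr::with_seed(3, {
    y <- rnorm(200)
    pa <- y + rnorm(200); pb <- y + rnorm(200)
    ens <- ensemble_average(pa, pb)
    expect_lte(mean((y - ens)^2),
               0.5 * (mean((y - pa)^2) + mean((y - pb)^2)) + 1e-12)
  })
  expect_error(ensemble_average(1:3, 1:4), "mismatch")
})
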