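# Feed-forward neural network with per-bit entity embeddings for the
# ECFP6 fingerprint block. Written directly on matrix algebra: each of the
# 4096 fingerprint bits is a two-category variable with its own learned
# embedding; embeddings are concatenated with the scaled continuous blocks
# and passed through three hidden layers (linear -> ReLU -> batch norm ->
# dropout), with a sigmoid-bounded output covering the expanded training
# label range. Optimized by Adam with decoupled weight decay under a
# one-cycle learning-rate schedule. Test-time dropout (Monte Carlo passes
# with batch norm in inference mode) provides the per-instance spread.

#' Feed-forward network configuration
#'
#' @param hidden_sizes hidden-layer widths.
#' @param dropout dropout rate after each hidden layer.
#' @param embedding_dropout dropout rate on the embedding outputs.
#' @param weight_decay decoupled weight-decay coefficient (dense weights
#'   and embeddings).
#' @param output_range_factor the scaled-label training range is expanded
#'   about its midpoint by this factor; the sigmoid output is mapped onto
#'   the expanded interval.
#' @param embedding_dim_per_bit embedding dimension per fingerprint bit.
#' @param mc_passes default number of Monte Carlo dropout passes.
#' @param epochs,batch_size,lr_max training-loop parameters (one-cycle
#'   schedule peaks at `lr_max`).
#' @param seed integer; controls weight init, batch order and dropout
#'   masks.
#' @return a `pcm_ffn_config` list.
#' @export
ffn_config <- function(hidden_sizes = c(2000L, 1000L, 500L), dropout = 0.25,
                       embedding_dropout = 0.01, weight_decay = 0.01,
                       output_range_factor = 1.2, embedding_dim_per_bit = 2L,
                       mc_passes = 100L, epochs = 20L, batch_size = 256L,
                       lr_max = 1e-2, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, embedding_dropout >= 0,
            embedding_dropout < 1, output_range_factor >= 1,
            embedding_dim_per_bit >= 1, mc_passes >= 2, epochs >= 1,
            batch_size >= 2, length(hidden_sizes) >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 embedding_dropout = embedding_dropout,
                 weight_decay = weight_decay,
                 output_range_factor = output_range_factor,
                 embedding_dim_per_bit = as.integer(embedding_dim_per_bit),
                 mc_passes = as.integer(mc_passes), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_max = lr_max,
                 seed = as.integer(seed)),
            class = "pcm_ffn_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Embedding layer forward: X binary n x 4096 -> n x (4096*d), bit-major
# interleaving (bit b occupies columns (b-1)*d + 1:d).
.emb_forward <- function(Xf, E0, E1) {
  n <- nrow(Xf); nb <- nrow(E0); d <- ncol(E0)
  out <- matrix(0, n, nb * d)
  for (k in seq_len(d)) {
    cols <- (seq_len(nb) - 1L) * d + k
    delta <- E1[, k] - E0[, k]
    out[, cols] <- sweep(Xf, 2, delta, "*")
    out[, cols] <- sweep(out[, cols], 2, E0[, k], "+")
  }
  out
}

# One forward pass. mode: "train" (batch-stat BN, dropout, updates running
# stats in env), "eval" (running-stat BN, no dropout), "mc" (running-stat
# BN, dropout active). Returns cache when `keep` for backprop.
.ffn_forward <- function(par, cfg, Xf, Xc, mode, keep = FALSE) {
  train <- mode == "train"
  drop_on <- mode %in% c("train", "mc")
  emb <- .emb_forward(Xf, par$E0, par$E1)
  if (drop_on && cfg$embedding_dropout > 0) {
    mask_e <- matrix(stats::rbinom(length(emb), 1L, 1 - cfg$embedding_dropout) /
                       (1 - cfg$embedding_dropout), nrow(emb))
    emb <- emb * mask_e
  } else mask_e <- NULL
  A <- cbind(emb, Xc)
  L <- length(cfg$hidden_sizes)
  cache <- if (keep) list(A0 = A, mask_e = mask_e) else NULL
  for (l in seq_len(L)) {
    Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    H <- pmax(Z, 0)
    if (train) {
      mu <- colMeans(H)
      v <- colMeans(H^2) - mu^2
      par$bn_mean[[l]] <- 0.9 * par$bn_mean[[l]] + 0.1 * mu
      par$bn_var[[l]] <- 0.9 * par$bn_var[[l]] + 0.1 * v
    } else {
      mu <- par$bn_mean[[l]]; v <- par$bn_var[[l]]
    }
    s <- sqrt(v + 1e-5)
    Hhat <- sweep(sweep(H, 2, mu), 2, s, "/")
    B <- sweep(sweep(Hhat, 2, par$gamma[[l]], "*"), 2, par$beta[[l]], "+")
    if (drop_on && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(B), 1L, 1 - cfg$dropout) /
                       (1 - cfg$dropout), nrow(B))
      B <- B * mask
    } else mask <- NULL
    if (keep) {
      cache[[paste0("Z", l)]] <- Z; cache[[paste0("H", l)]] <- H
      cache[[paste0("Hhat", l)]] <- Hhat; cache[[paste0("s", l)]] <- s
      cache[[paste0("mask", l)]] <- mask; cache[[paste0("A", l)]] <- B
    }
    A <- B
  }
  zout <- as.numeric(A %*% par$W[[L + 1L]] + par$b[[L + 1L]])
  sig <- .sigmoid(zout)
  yhat <- par$y_lo + sig * (par$y_hi - par$y_lo)
  if (keep) {
    cache$zout <- zout; cache$sig <- sig; cache$yhat <- yhat
    cache$Aout <- A
  }
  list(yhat = yhat, cache = cache, par = par)
}

.ffn_init <- function(cfg, n_bits, n_cont, y_lo, y_hi) {
  d <- cfg$embedding_dim_per_bit
  sizes <- c(n_bits * d + n_cont, cfg$hidden_sizes, 1L)
  W <- list(); b <- list(); gamma <- list(); beta <- list()
  bn_mean <- list(); bn_var <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / fan_in)), sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  for (l in seq_along(cfg$hidden_sizes)) {
    h <- cfg$hidden_sizes[l]
    gamma[[l]] <- rep(1, h); beta[[l]] <- rep(0, h)
    bn_mean[[l]] <- rep(0, h); bn_var[[l]] <- rep(1, h)
  }
  list(E0 = matrix(stats::rnorm(n_bits * d, 0, 0.01), n_bits),
       E1 = matrix(stats::rnorm(n_bits * d, 0, 0.01), n_bits),
       W = W, b = b, gamma = gamma, beta = beta,
       bn_mean = bn_mean, bn_var = bn_var, y_lo = y_lo, y_hi = y_hi)
}

# One-cycle schedule: cosine warmup lr_max/25 -> lr_max over the first 30%
# of steps, then cosine annealing to lr_max/1e4.
.one_cycle_lr <- function(step, total, lr_max) {
  pct <- step / total
  if (pct <= 0.3) {
    lo <- lr_max / 25
    lo + (lr_max - lo) * (1 - cos(pi * pct / 0.3)) / 2
  } else {
    lo <- lr_max / 1e4
    lo + (lr_max - lo) * (1 + cos(pi * (pct - 0.3) / 0.7)) / 2
  }
}

#' Train the entity-embedding feed-forward network
#'
#' @param fm training `pcm_features` matrix (fingerprint block must be
#'   binary).
#' @param labels scaled pIC50 labels.
#' @param config a [ffn_config()].
#' @return a `pcm_ffn` model.
#' @export
train_ffn <- function(fm, labels, config = ffn_config()) {
  stopifnot(inherits(fm, "pcm_features"), inherits(config, "pcm_ffn_config"))
  fp_cols <- fm$block_index$fingerprint
  Xf <- fm$values[, fp_cols, drop = FALSE]
  if (!all(Xf %in% c(0, 1))) stop("fingerprint block must be binary 0/1")
  Xc <- fm$values[, -fp_cols, drop = FALSE]
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(Xf))

  rng <- range(y)
  mid <- mean(rng); half <- diff(rng) / 2 * config$output_range_factor
  y_lo <- mid - half; y_hi <- mid + half

  .with_seed(config$seed, {
    par <- .ffn_init(config, ncol(Xf), ncol(Xc), y_lo, y_hi)
    adam <- list(m = rapply(par[c("E0", "E1", "W", "b", "gamma", "beta")],
                            function(x) x * 0, how = "replace"),
                 v = rapply(par[c("E0", "E1", "W", "b", "gamma", "beta")],
                            function(x) x * 0, how = "replace"))
    n <- nrow(Xf)
    steps_per_epoch <- max(1L, floor(n / config$batch_size))
    total_steps <- config$epochs * steps_per_epoch
    step <- 0L
    beta1 <- 0.9; beta2 <- 0.99; eps <- 1e-8
    L <- length(config$hidden_sizes)

    upd <- function(name, idx, grad, lr, decay) {
      g <- grad
      if (is.null(idx)) {
        m <- adam$m[[name]]; v <- adam$v[[name]]; p <- par[[name]]
      } else {
        m <- adam$m[[name]][[idx]]; v <- adam$v[[name]][[idx]]
        p <- par[[name]][[idx]]
      }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step); vhat <- v / (1 - beta2^step)
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
      if (is.null(idx)) {
        adam$m[[name]] <<- m; adam$v[[name]] <<- v; par[[name]] <<- p
      } else {
        adam$m[[name]][[idx]] <<- m; adam$v[[name]][[idx]] <<- v
        par[[name]][[idx]] <<- p
      }
    }

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (bi in seq_len(steps_per_epoch)) {
        step <- step + 1L
        lr <- .one_cycle_lr(step, total_steps, config$lr_max)
        rows <- ord[((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, n)]
        nb <- length(rows)
        fw <- .ffn_forward(par, config, Xf[rows, , drop = FALSE],
                           Xc[rows, , drop = FALSE], "train", keep = TRUE)
        par$bn_mean <- fw$par$bn_mean; par$bn_var <- fw$par$bn_var
        cache <- fw$cache
        resid <- fw$yhat - y[rows]
        # d loss / d zout through the bounded sigmoid output
        dz <- (2 / nb) * resid * (y_hi - y_lo) * cache$sig * (1 - cache$sig)
        dA <- matrix(dz, ncol = 1)
        for (l in (L + 1L):1L) {
          A_in <- if (l == 1L) cache$A0 else cache[[paste0("A", l - 1L)]]
          gW <- crossprod(A_in, dA)
          gb <- colSums(dA)
          dA_in <- dA %*% t(par$W[[l]])
          upd("W", l, gW, lr, config$weight_decay)
          upd("b", l, gb, lr, 0)
          if (l > 1L) {
            hl <- l - 1L
            dB <- dA_in
            if (!is.null(cache[[paste0("mask", hl)]])) {
              dB <- dB * cache[[paste0("mask", hl)]]
            }
            Hhat <- cache[[paste0("Hhat", hl)]]
            s <- cache[[paste0("s", hl)]]
            dgamma <- colSums(dB * Hhat)
            dbeta <- colSums(dB)
            dHhat <- sweep(dB, 2, par$gamma[[hl]], "*")
            dH <- sweep(dHhat -
                          matrix(colMeans(dHhat), nrow(dHhat), ncol(dHhat),
                                 byrow = TRUE) -
                          Hhat * matrix(colMeans(dHhat * Hhat), nrow(dHhat),
                                        ncol(dHhat), byrow = TRUE),
                        2, s, "/")
            dZ <- dH * (cache[[paste0("Z", hl)]] > 0)
            upd("gamma", hl, dgamma, lr, 0)
            upd("beta", hl, dbeta, lr, 0)
            dA <- dZ
          } else {
            d <- config$embedding_dim_per_bit
            nb_bits <- nrow(par$E0)
            g_emb <- dA_in[, seq_len(nb_bits * d), drop = FALSE]
            if (!is.null(cache$mask_e)) g_emb <- g_emb * cache$mask_e
            Xfb <- Xf[rows, , drop = FALSE]
            gE0 <- matrix(0, nb_bits, d); gE1 <- matrix(0, nb_bits, d)
            for (k in seq_len(d)) {
              cols <- (seq_len(nb_bits) - 1L) * d + k
              gk <- g_emb[, cols, drop = FALSE]
              gE1[, k] <- colSums(gk * Xfb)
              gE0[, k] <- colSums(gk) - gE1[, k]
            }
            upd("E0", NULL, gE0, lr, config$weight_decay)
            upd("E1", NULL, gE1, lr, config$weight_decay)
          }
        }
      }
    }
    structure(list(par = par, config = config, block_index = fm$block_index,
                   schema_hash = .schema_hash(fm), trained = TRUE),
              class = "pcm_ffn")
  })
}

.ffn_batched <- function(model, fm, mode) {
  fp_cols <- model$block_index$fingerprint
  Xf <- fm$values[, fp_cols, drop = FALSE]
  Xc <- fm$values[, -fp_cols, drop = FALSE]
  n <- nrow(Xf)
  out <- numeric(n)
  starts <- seq(1L, n, by = 1024L)
  for (s in starts) {
    rows <- s:min(s + 1023L, n)
    out[rows] <- .ffn_forward(model$par, model$config,
                              Xf[rows, , drop = FALSE],
                              Xc[rows, , drop = FALSE], mode)$yhat
  }
  out
}

#' Deterministic FFN predictions
#'
#' Forward pass with dropout disabled and batch norm in inference mode.
#'
#' @param model a trained `pcm_ffn`.
#' @param fm a `pcm_features` matrix.
#' @return numeric prediction vector.
#' @export
predict_ffn <- function(model, fm) {
  stopifnot(inherits(model, "pcm_ffn"))
  .check_schema(model, fm)
  .ffn_batched(model, fm, "eval")
}

#' Monte Carlo dropout predictions with uncertainty
#'
#' Runs `passes` stochastic forward passes with dropout active at
#' inference (batch norm stays in inference mode); returns the per-instance
#' mean and population standard deviation. With all dropout rates at zero
#' the passes are identical and the spread is exactly zero.
#'
#' @param model a trained `pcm_ffn`.
#' @param fm a `pcm_features` matrix.
#' @param passes number of stochastic passes (>= 2).
#' @param seed integer controlling the dropout masks.
#' @return a `pcm_uncertainty` list with `mean` and `spread`.
#' @export
mc_dropout_predict <- function(model, fm, passes = NULL, seed = 1L) {
  stopifnot(inherits(model, "pcm_ffn"))
  .check_schema(model, fm)
  if (is.null(passes)) passes <- model$config$mc_passes
  if (passes < 2) stop("mc_dropout_predict requires passes >= 2")
  if (model$config$dropout == 0 && model$config$embedding_dropout == 0) {
    # no stochasticity: every pass is identical, spread is exactly zero
    yh <- .ffn_batched(model, fm, "mc")
    return(structure(list(mean = yh, spread = rep(0, length(yh))),
                     class = "pcm_uncertainty"))
  }
  .with_seed(seed, {
    acc <- 0; acc2 <- 0
    for (p in seq_len(passes)) {
      yh <- .ffn_batched(model, fm, "mc")
      acc <- acc + yh; acc2 <- acc2 + yh^2
    }
    m <- acc / passes
    spread <- sqrt(pmax(0, acc2 / passes - m^2))
    structure(list(mean = m, spread = spread), class = "pcm_uncertainty")
  })
}

#' Extract the learned per-bit entity embeddings
#'
#' One row per fingerprint bit: the embedding of its "present" category.
#'
#' @param model a trained `pcm_ffn`.
#' @return numeric matrix, 4096 rows x `embedding_dim_per_bit` columns.
#' @export
extract_bit_embeddings <- function(model) {
  stopifnot(inherits(model, "pcm_ffn"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  E1 <- model$par$E1
  rownames(E1) <- paste0("fp_", seq_len(nrow(E1)))
  E1
}
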