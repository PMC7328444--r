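# Shared fixtures, built once per test run and cached. All data is
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

.fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) assign(name, build(), envir = .fixture_env)
  .fixture_env[[name]]
}

# Small clean synthetic data set + curated records + random-split matrices.
fix_dataset <- function() {
  .fixture("dataset", function() gen_dataset(synthetic_config(n_pairs = 250L,
                                                              seed = 4242L)))
}

fix_prep <- function() {
  .fixture("prep", function() prepare_dataset(fix_dataset()))
}

fix_mats <- function() {
  .fixture("mats", function() {
    prep <- fix_prep()
    sp <- random_split(prep$records, 0.8, seed = 7L)
    pcmcp:::.split_matrices(prep$records, prep$sequences, sp)
  })
}

# Hand-built miniature feature matrix (12 columns) with a linear label
# function; cheap enough for many model fits. Blocks mimic the real
# schema's names at toy scale.
fix_mini_fm <- function(n = 80L, seed = 1L, informative = c(7L, 9L)) {
  withr::with_seed(seed, {
    fp <- matrix(rbinom(n * 6L, 1L, 0.4), n)
    cont <- matrix(rnorm(n * 6L), n)
    X <- cbind(fp, cont)
    colnames(X) <- c(paste0("fp_", 1:6), "mw", "logp", paste0("aac_", 1:4))
    fm <- structure(list(
      values = X,
      block_index = list(fingerprint = 1:6, physchem = 7:8, protein = 9:12),
      scaler = list(columns = 7:12, center = rep(0, 6), scale = rep(1, 6)),
      row_keys = data.frame(record_id = sprintf("R%03d", seq_len(n)),
                            canonical_smiles = sprintf("M%03d", seq_len(n)),
                            uniprot_id = "Q00001",
                            stringsAsFactors = FALSE)
    ), class = "pcm_features")
    y <- as.numeric(X[, informative, drop = FALSE] %*% rep(2, length(informative)) +
                      rnorm(n, 0, 0.1))
    list(fm = fm, y = y)
  })
}

# Independent brute-force CTD oracle: plain position-by-position loops,
# no vectorized shortcuts shared with the implementation.
oracle_ctd <- function(sequence) {
  groups_tab <- pcmcp:::.ctd_tables()
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (attr_name in names(groups_tab)) {
    g <- groups_tab[[attr_name]]
    lab <- integer(L)
    for (i in seq_len(L)) {
      for (k in 1:3) if (chars[i] %in% g[[k]]) lab[i] <- k
    }
    comp <- c(0, 0, 0)
    for (i in seq_len(L)) comp[lab[i]] <- comp[lab[i]] + 1
    comp <- comp / L
    tr <- c(0, 0, 0)
    pair_list <- list(c(1, 2), c(1, 3), c(2, 3))
    for (i in seq_len(L - 1)) {
      for (p in seq_along(pair_list)) {
        pp <- pair_list[[p]]
        if ((lab[i] == pp[1] && lab[i + 1] == pp[2]) ||
            (lab[i] == pp[2] && lab[i + 1] == pp[1])) tr[p] <- tr[p] + 1
      }
    }
    tr <- tr / (L - 1)
    distr <- numeric(0)
    for (k in 1:3) {
      occ <- integer(0)
      for (i in seq_len(L)) if (lab[i] == k) occ <- c(occ, i)
      if (length(occ) == 0) {
        distr <- c(distr, rep(0, 5))
      } else {
        vals <- numeric(5)
        targets <- c(1, ceiling(0.25 * length(occ)), ceiling(0.5 * length(occ)),
                     ceiling(0.75 * length(occ)), length(occ))
        for (j in 1:5) vals[j] <- 100 * occ[targets[j]] / L
        distr <- c(distr, vals)
      }
    }
    out <- c(out, comp, tr, distr)
  }
  out
}

# Brute-force Kendall tau-b over all pairs, with tie handling.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      if (a == 0 && b == 0) next
      if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (a == b) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# FFN trained once on a default-sized synthetic random split; reused by
# the signal-recovery check.
fix_ffn_prep <- function() {
  .fixture("ffn_prep", function() {
    ds <- gen_dataset(synthetic_config(seed = 2024L))
    prep <- prepare_dataset(ds)
    sp <- random_split(prep$records, 0.8, seed = 2024L)
    mats <- pcmcp:::.split_matrices(prep$records, prep$sequences, sp)
    cfg <- ffn_config(hidden_sizes = c(64L, 32L, 16L), epochs = 10L,
                      batch_size = 128L, seed = 2024L)
    model <- train_ffn(mats$fm_train, mats$y_train, cfg)
    pred <- predict_ffn(model, mats$fm_valid)
    list(pearson_r = stats::cor(mats$y_valid, pred), model = model,
         mats = mats)
  })
}

# Random valid SMILES drawn from the generator grammar (for idempotence /
# property checks).
fix_library <- function() {
  .fixture("library", function() {
    gen_ligand_library(synthetic_config(n_scaffolds = 10L, n_rgroups = 3L,
                                        seed = 99L))
  })
}
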