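#!/usr/bin/env Rscript
# Deeper evaluation of the scaffold-split models from 04: per-protein
# metric breakdown, impurity-based feature importance (which descriptor
# blocks carry the signal), permutation importance for the FFN on a
# feature subsample, and the error-vs-label profile.

suppressMessages(library(pcmcp))

if (!file.exists("results/models_scaffold.rds")) {
  stop("run analysis/04_train_models.R first")
}
st <- readRDS("results/models_scaffold.rds")
mats <- st$mats

groups <- mats$fm_valid$row_keys$uniprot_id
pg <- per_group_metrics(mats$y_valid, st$rf_pred$mean, groups, min_n = 10L)
message(sprintf("per-protein (n > 10): %d proteins, mean MSE %.3f (sd %.3f)",
                pg$n_groups, pg$mean[["mse"]], pg$sd[["mse"]]))

imp <- rf_impurity_importance(st$rf)
top_decile <- imp[seq_len(ceiling(nrow(imp) / 10)), ]
block_share <- prop.table(table(top_decile$block))
message("top-decile importance by block: ",
        paste(names(block_share), round(block_share, 3), collapse = ", "))

# FFN permutation importance on the continuous blocks + a fingerprint
# subsample (full 4671-column permutation is out of desk scale)
set.seed(20260927L)
probe_cols <- c(4097:4111, sample(1:4096, 30))
ffn_imp <- permutation_importance(st$ffn, mats$fm_valid, mats$y_valid,
                                  features = probe_cols, seed = 1L)

prof <- error_vs_label_profile(mats$y_valid, st$rf_pred$mean, n_bins = 8L)
print(prof, digits = 3)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(pg$table, "results/tables/per_protein_metrics.csv",
                 row.names = FALSE)
utils::write.csv(imp[1:200, ], "results/tables/rf_importance_top200.csv",
                 row.names = FALSE)
utils::write.csv(ffn_imp, "results/tables/ffn_permutation_importance.csv",
                 row.names = FALSE)
utils::write.csv(prof, "results/tables/error_vs_label_profile.csv",
                 row.names = FALSE)

emb <- extract_bit_embeddings(st$ffn)
active_bits <- which(colSums(mats$fm_train$values[, 1:4096]) > 0)
utils::write.csv(data.frame(bit = active_bits, emb[active_bits, , drop = FALSE]),
                 "results/tables/ffn_bit_embeddings_active.csv",
                 row.names = FALSE)
message(sprintf("wrote entity embeddings for %d active fingerprint bits",
                length(active_bits)))
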