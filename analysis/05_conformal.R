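#!/usr/bin/env Rscript
# Conformal prediction on top of the trained models: carve a random 80/20
# calibration set out of the scaffold-split training records, retrain,
# calibrate the spread-normalized nonconformity scores, and evaluate
# validity (coverage) and efficiency (interval width) of the prediction
# intervals on the held-out scaffold validation set across confidence
# levels. Writes the calibration-curve and efficiency tables.

suppressMessages(library(pcmcp))

seed <- 20260927L
records <- utils::read.csv("results/data/clean/activity.csv",
                           stringsAsFactors = FALSE)
sequences <- read_fasta("results/data/clean/sequences.fasta")
rec <- curate_table(records)$records

sp <- scaffold_split(rec, 0.8, seed = seed)
sp <- calibration_split(sp, 0.8, seed = seed + 1L)
mats <- pcmcp:::.split_matrices(rec, sequences, sp)

rf_model <- train_rf(mats$fm_train, mats$y_train,
                     rf_config(n_estimators = 500L, seed = seed))
cal_pred <- rf_predict_uncertainty(rf_model, mats$fm_cal)
val_pred <- rf_predict_uncertainty(rf_model, mats$fm_valid)
calib <- conformal_calibrator(mats$y_cal, cal_pred$mean, cal_pred$spread)

eps_grid <- c(0.05, 0.1, 0.2, 0.32)
rows <- lapply(eps_grid, function(eps) {
  iv <- predict_interval(val_pred$mean, val_pred$spread, calib, eps)
  eff <- efficiency(iv)
  data.frame(confidence = 1 - eps, coverage = validity(iv, mats$y_valid),
             median_width = eff$median, q1_width = eff$q1,
             q3_width = eff$q3, n_unbounded = eff$n_unbounded)
})
tab <- do.call(rbind, rows)
print(tab, digits = 3)

cc <- calibration_curve(calib, val_pred$mean, val_pred$spread, mats$y_valid,
                        epsilon_grid = seq(0.05, 0.5, by = 0.05))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(tab, "results/tables/conformal_validity_efficiency.csv",
                 row.names = FALSE)
utils::write.csv(cc, "results/tables/conformal_calibration_curve.csv",
                 row.names = FALSE)
iv95 <- predict_interval(val_pred$mean, val_pred$spread, calib, 0.05)
utils::write.csv(cbind(record_id = sp$valid_ids, y_hat = val_pred$mean,
                       spread = val_pred$spread, iv95),
                 "results/tables/predictions_intervals_95.csv",
                 row.names = FALSE)
message(sprintf("95%% intervals: coverage %.3f on the scaffold validation set",
                validity(iv95, mats$y_valid)))
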