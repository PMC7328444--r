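#!/usr/bin/env Rscript
# Generate the reference synthetic PCM data sets: a clean table under the
# default experimental conditions (20 proteins in 4 families, ~120-ligand library
# over 10 scaffold classes, 1600 protein-ligand pairs, pIC50 ~ sparse
# linear latent function + 0.5 log-unit noise, publication-bias location
# 6.5 / scale 1.3) and a contaminated variant exercising every curation
# rule. Writes CSV + FASTA + ground-truth manifests under results/data/.

suppressMessages(library(pcmcp))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

clean_cfg <- synthetic_config(seed = 20260927L)
clean <- gen_dataset(clean_cfg)
write_dataset(clean, file.path(out_dir, "clean"))

dirty_cfg <- synthetic_config(
  seed = 20260927L,
  contamination_rates = list(wrong_units = 0.04, low_confidence = 0.05,
                             inconclusive = 0.02, duplicate_flag = 0.03,
                             replicate = 0.08, pains = 0.03, mw_out = 0.02))
dirty <- gen_dataset(dirty_cfg)
write_dataset(dirty, file.path(out_dir, "contaminated"))

y <- to_pic50(clean$records$standard_value)
message(sprintf("clean: %d records, %d ligands, %d proteins", nrow(clean$records),
                length(clean$ligands), length(clean$proteins$sequences)))
message(sprintf("pIC50 mean %.3f sd %.3f (targets 6.5 / sqrt(1.3^2+0.5^2)=1.39)",
                mean(y), sd(y)))
message(sprintf("contaminated: %d records (%d clean pairs expected after curation)",
                nrow(dirty$records), dirty$truth$expected_post_curation_count))
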