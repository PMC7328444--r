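#!/usr/bin/env Rscript
# Build the splits used downstream: an 80/20 generic Bemis-Murcko scaffold
# split of the clean curated records (no scaffold spans both sides), the
# nested random 80/20 training/calibration split for conformal prediction,
# and a protein-held-out split for comparison. Persists assignments as CSV.

suppressMessages(library(pcmcp))

if (!file.exists("results/data/clean/activity.csv")) {
  stop("run analysis/01_simulate.R first")
}
records <- utils::read.csv("results/data/clean/activity.csv",
                           stringsAsFactors = FALSE)
cur <- curate_table(records)
rec <- cur$records

seed <- 20260927L
sc <- scaffold_split(rec, fraction = 0.8, seed = seed)
print(sc)
cal <- calibration_split(sc, fraction = 0.8, seed = seed + 1L)
print(cal)
pr <- protein_split(rec, fraction = 0.8, seed = seed)
print(pr)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
dump_split <- function(sp, path) {
  subsets <- c(rep("train", length(sp$train_ids)),
               rep("valid", length(sp$valid_ids)),
               rep("calibration", length(sp$calibration_ids)))
  ids <- c(sp$train_ids, sp$valid_ids, sp$calibration_ids)
  utils::write.csv(data.frame(record_id = ids, subset = subsets,
                              group_key = unname(sp$group_key[ids])),
                   path, row.names = FALSE)
}
dump_split(cal, "results/tables/split_scaffold_calibration.csv")
dump_split(pr, "results/tables/split_protein.csv")

message(sprintf("scaffold split: %d train / %d valid records, %d scaffold classes held out",
                length(sc$train_ids), length(sc$valid_ids),
                length(unique(sc$group_key[sc$valid_ids]))))
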