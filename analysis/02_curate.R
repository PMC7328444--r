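#!/usr/bin/env Rscript
# Curate the contaminated activity table: structure standardization, the
# unit/duplicate/confidence/comment/MW/PAINS filters, median aggregation
# of replicates and pIC50 conversion. Verifies the retained count against
# the generator's ground-truth manifest and writes the curated table plus
# the per-rule removal audit.

suppressMessages(library(pcmcp))

if (!file.exists("results/data/contaminated/activity.csv")) {
  stop("run analysis/01_simulate.R first")
}
records <- utils::read.csv("results/data/contaminated/activity.csv",
                           stringsAsFactors = FALSE)
manifest <- jsonlite::read_json("results/data/contaminated/ground_truth.json")

cur <- curate_table(records)
print(cur$audit)
expected <- manifest$expected_post_curation_count
message(sprintf("retained %d records; ground truth expects %d (%s)",
                nrow(cur$records), expected,
                if (nrow(cur$records) == expected) "exact match" else "MISMATCH"))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(cur$records, "results/tables/curated_activity.csv",
                 row.names = FALSE)
audit_df <- data.frame(rule = names(cur$audit$removed),
                       removed = as.integer(cur$audit$removed))
utils::write.csv(audit_df, "results/tables/curation_audit.csv",
                 row.names = FALSE)
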