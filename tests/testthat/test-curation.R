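# Curation filters, audit bookkeeping, aggregation, pIC50 conversion and
# label scaling.

make_records <- function(...) {
  rows <- list(...)
  n <- max(1L, length(rows))
  base <- data.frame(record_id = sprintf("R%02d", seq_len(n)),
                     canonical_smiles = "Cc1ccccc1", uniprot_id = "Q00001",
                     standard_type = "IC50", standard_value = 1000,
                     standard_units = "nM", confidence_score = 9L,
                     activity_comment = "", potential_duplicate = 0L,
                     stringsAsFactors = FALSE)
  for (i in seq_along(rows)) for (nm in names(rows[[i]])) {
    base[i, nm] <- rows[[i]][[nm]]
  }
  if (length(rows) == 0L) base <- base[0, ]
  base
}

test_that("empty input produces an empty output with zero counts", {
  out <- apply_filters(make_records())
  expect_equal(nrow(out$records), 0L)
  expect_equal(sum(out$audit$removed), 0L)
})

test_that("each filter rule removes its records and the audit balances", {
  recs <- make_records(
    list(),                                        # clean
    list(standard_units = "ug/mL"),                # unit rule
    list(potential_duplicate = 1L),                # duplicate flag
    list(confidence_score = 7L),                   # confidence
    list(activity_comment = "inconclusive"),       # comment
    list(canonical_smiles = "C"),                  # MW 16 < 75
    list(canonical_smiles = "O=C1C=CC(=O)C=C1"),   # PAINS quinone
    list(canonical_smiles = "C1CC")                # unparseable
  )
  out <- apply_filters(recs)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$records$record_id, "R01")
  a <- out$audit
  expect_equal(a$input_n, a$output_n + sum(a$removed))
  expect_equal(unname(a$removed[c("units", "potential_duplicate", "confidence",
                                  "comment", "mw_range", "pains",
                                  "unparseable_structure")]),
               rep(1L, 7))
})

test_that("the retained set is rule-order independent", {
  ds <- gen_dataset(synthetic_config(
    n_pairs = 120L, seed = 55L,
    contamination_rates = list(wrong_units = 0.1, low_confidence = 0.1,
                               inconclusive = 0.05, duplicate_flag = 0.05,
                               pains = 0.05, mw_out = 0.05)))
  out <- apply_filters(ds$records)
  # oracle: evaluate every predicate independently of application order
  std <- vapply(ds$records$canonical_smiles, standardize_structure, character(1))
  keep <- !is.na(std) &
    ds$records$standard_units == "nM" &
    ds$records$potential_duplicate == 0 &
    ds$records$confidence_score >= 9 &
    tolower(trimws(ds$records$activity_comment)) != "inconclusive"
  mw <- rep(NA_real_, nrow(ds$records))
  mw[keep] <- vapply(std[keep], function(s) physchem(s)[["mw"]], numeric(1))
  keep[keep] <- mw[keep] >= 75 & mw[keep] <= 800
  keep[keep] <- !vapply(std[keep], pains_match, logical(1))
  expect_setequal(out$records$record_id, ds$records$record_id[keep])
})

test_that("missing columns are rejected by name", {
  recs <- make_records(list())
  recs$confidence_score <- NULL
  expect_error(apply_filters(recs), "confidence_score")
})

test_that("median aggregation collapses pairs with the even-count convention", {
  recs <- make_records(list(standard_value = 100), list(standard_value = 200),
                       list(standard_value = 400))
  agg <- aggregate_median(recs)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$standard_value, 200)
  expect_equal(agg$n_measurements, 3L)

  recs2 <- make_records(list(standard_value = 100), list(standard_value = 200))
  expect_equal(aggregate_median(recs2)$standard_value, 150)

  single <- make_records(list(standard_value = 123))
  expect_equal(aggregate_median(single)$standard_value, 123)

  # no pair appears twice downstream
  mixed <- make_records(list(), list(), list(canonical_smiles = "CCC"))
  agg3 <- aggregate_median(mixed)
  expect_equal(anyDuplicated(paste(agg3$canonical_smiles, agg3$uniprot_id)), 0L)
})

test_that("pIC50 conversion and round-trip", {
  expect_equal(to_pic50(1000), 6)
  expect_equal(to_pic50(1), 9)
  expect_equal(to_pic50(50), 9 - log10(50))
  p <- c(4.2, 6.5, 9.1)
  expect_equal(to_pic50(10^(9 - p)), p, tolerance = 1e-10)
  expect_error(to_pic50(-1), "nonpositive")
})

test_that("label scaler standardizes and round-trips", {
  sc <- fit_label_scaler(c(0, 2))
  expect_equal(apply_label_scaler(sc, 2), 1)
  y <- c(5.1, 6.2, 7.9, 4.4)
  sc2 <- fit_label_scaler(y)
  z <- apply_label_scaler(sc2, y)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-8)
  expect_equal(invert_label_scaler(sc2, z), y, tolerance = 1e-10)
  expect_error(fit_label_scaler(c(3, 3, 3)), "zero spread")
})

test_that("curate_table removes nonpositive activities and reports audit", {
  recs <- make_records(list(), list(standard_value = -5))
  out <- curate_table(recs)
  expect_equal(nrow(out$records), 1L)
  expect_equal(unname(out$audit$removed[["nonpositive_value"]]), 1L)
  expect_equal(out$records$pic50, 6)
})
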