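# Split construction: partition property, leakage guarantees, greedy
# fraction accuracy.

fake_records <- function(n, smiles = "CCO", uniprot = "Q00001") {
  data.frame(record_id = sprintf("R%04d", seq_len(n)),
             canonical_smiles = rep_len(smiles, n),
             uniprot_id = rep_len(uniprot, n), stringsAsFactors = FALSE)
}

check_partition <- function(sp, records) {
  ids <- c(sp$train_ids, sp$valid_ids, sp$calibration_ids)
  expect_setequal(ids, records$record_id)
  expect_equal(anyDuplicated(ids), 0L)
}

test_that("uniform scaffold groups split 80/20 by records", {
  # 10 scaffold classes x 10 records each, built from the template grammar
  lib <- gen_ligand_library(synthetic_config(n_scaffolds = 10L,
                                             n_rgroups = 4L, seed = 99L))
  keys <- vapply(lib, generic_scaffold, character(1))
  by_key <- split(lib, keys)
  expect_gte(length(by_key), 10L)
  smiles <- unlist(lapply(by_key[1:10], function(s) rep_len(s, 10)))
  rec <- fake_records(100, smiles = smiles)
  sp <- scaffold_split(rec, fraction = 0.8, seed = 3L)
  expect_equal(length(sp$train_ids), 80L)
  expect_equal(length(sp$valid_ids), 20L)
  check_partition(sp, rec)
})

test_that("scaffold splits never leak a scaffold across sets", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_pairs = 120L, seed = seed)
    ds <- gen_dataset(cfg)
    rec <- ds$records
    sp <- scaffold_split(rec, 0.8, seed)
    check_partition(sp, rec)
    expect_length(intersect(unique(sp$group_key[sp$train_ids]),
                            unique(sp$group_key[sp$valid_ids])), 0L)
  }
})

test_that("single-group scaffold input is rejected", {
  rec <- fake_records(10, smiles = c("Cc1ccccc1", "CCc1ccccc1"))
  expect_error(scaffold_split(rec, 0.8, 1L), "leakage")
})

test_that("random splits are sized, reproducible and seed-sensitive", {
  rec <- fake_records(100)
  sp <- random_split(rec, 0.8, seed = 5L)
  expect_length(sp$train_ids, 80L)
  expect_length(sp$valid_ids, 20L)
  check_partition(sp, rec)
  expect_identical(random_split(rec, 0.8, seed = 5L)$train_ids, sp$train_ids)
  expect_false(identical(random_split(rec, 0.8, seed = 6L)$train_ids,
                         sp$train_ids))
})

test_that("protein splits hold every protein out of one side", {
  rec <- fake_records(100, uniprot = rep(sprintf("Q%05d", 1:5), each = 20))
  sp <- protein_split(rec, 0.8, seed = 2L)
  check_partition(sp, rec)
  tr_prot <- unique(sp$group_key[sp$train_ids])
  va_prot <- unique(sp$group_key[sp$valid_ids])
  expect_length(intersect(tr_prot, va_prot), 0L)
  expect_length(tr_prot, 4L)
  expect_error(protein_split(fake_records(10), 0.8, 1L), "leakage")
})

test_that("held-out protein feature blocks are absent from training rows", {
  prep <- fix_prep()
  sp <- protein_split(prep$records, 0.8, seed = 11L)
  mats <- pcmcp:::.split_matrices(prep$records, prep$sequences, sp)
  prot_cols <- mats$fm_train$block_index$protein
  tr_rows <- unique(round(mats$fm_train$values[, prot_cols], 10))
  va_rows <- unique(round(mats$fm_valid$values[, prot_cols], 10))
  shared <- sum(duplicated(rbind(tr_rows, va_rows)))
  expect_equal(shared, 0L)
})

test_that("calibration split nests inside the training set", {
  rec <- fake_records(125)
  base <- random_split(rec, 0.8, seed = 9L) # 100 train / 25 valid
  sp <- calibration_split(base, 0.8, seed = 10L)
  expect_length(sp$train_ids, 80L)
  expect_length(sp$calibration_ids, 20L)
  expect_identical(sp$valid_ids, base$valid_ids)
  expect_length(intersect(sp$calibration_ids, sp$valid_ids), 0L)
  check_partition(sp, rec)
  expect_error(calibration_split(base, 1, seed = 1L), "empty")
})

test_that("greedy grouped assignment tracks the target fraction", {
  # skewed group sizes 60/30/10
  rec <- fake_records(100, uniprot = rep(c("Q00001", "Q00002", "Q00003"),
                                         times = c(60, 30, 10)))
  sp <- protein_split(rec, 0.8, seed = 4L)
  sizes <- c(60, 30, 10)
  largest <- max(sizes) / 100
  expect_lte(abs(sp$achieved_fraction - 0.8), largest)
  # brute-force oracle: the best achievable deviation over all assignments
  best <- min(vapply(1:(2^3 - 2), function(mask) {
    on <- as.logical(bitwAnd(mask, 2^(0:2)))
    abs(sum(sizes[on]) / 100 - 0.8)
  }, numeric(1)))
  expect_lte(abs(sp$achieved_fraction - 0.8), best + largest)
})
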