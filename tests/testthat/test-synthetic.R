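# Synthetic-data generator: families, ligand grammar, activity tables and
# their ground-truth manifests.

test_that("zero mutation rate reproduces the family root exactly", {
  cfg <- synthetic_config(n_families = 2L, members_per_family = 3L,
                          mutation_rate = 0, seq_len_range = c(50L, 60L),
                          seed = 5L)
  fam <- gen_protein_family_set(cfg)
  expect_length(fam$sequences, 6L)
  expect_length(unique(names(fam$sequences)), 6L)
  for (id in names(fam$sequences)) {
    expect_identical(fam$sequences[[id]], fam$roots[[fam$family[[id]]]])
  }
})

test_that("within-family Hamming distance follows the binomial model", {
  cfg <- synthetic_config(n_families = 1L, members_per_family = 30L,
                          mutation_rate = 0.1, seq_len_range = c(300L, 300L),
                          seed = 17L)
  fam <- gen_protein_family_set(cfg)
  root <- strsplit(fam$roots[[1]], "")[[1]]
  dists <- vapply(fam$sequences, function(s) {
    sum(strsplit(s, "")[[1]] != root)
  }, numeric(1))
  # per-member bound: 30 +/- 3*sqrt(300*0.1*0.9)
  expect_true(all(abs(dists - 30) <= 3 * sqrt(300 * 0.1 * 0.9)))
  # and the mean should be much tighter
  expect_lt(abs(mean(dists) - 30), 3 * sqrt(300 * 0.1 * 0.9 / 30))
})

test_that("sequence generation rejects a degenerate length range", {
  expect_error(synthetic_config(seq_len_range = c(100L, 50L)), "degenerate")
})

test_that("ligand library size, scaffold diversity and rejection rules hold", {
  lib1 <- gen_ligand_library(synthetic_config(n_scaffolds = 1L, n_rgroups = 1L,
                                              seed = 2L))
  expect_length(lib1, 1L)
  lib5 <- gen_ligand_library(synthetic_config(n_scaffolds = 5L, n_rgroups = 3L,
                                              seed = 2L))
  keys <- vapply(lib5, generic_scaffold, character(1))
  expect_gte(length(unique(keys)), 5L)
  expect_error(gen_ligand_library(synthetic_config(n_scaffolds = 99L)),
               "template grammar ships")
  expect_error(gen_ligand_library(synthetic_config(n_rgroups = 99L)),
               "fragment set ships")
})

test_that("noise-free tables reproduce the noiseless labels exactly", {
  cfg <- synthetic_config(n_pairs = 150L, noise_sd = 0, seed = 31L)
  ds <- gen_dataset(cfg)
  key <- paste(ds$records$canonical_smiles, ds$records$uniprot_id, sep = "|")
  expect_equal(to_pic50(ds$records$standard_value),
               unname(ds$truth$noiseless_labels[key]), tolerance = 1e-9)
  expect_identical(ds$truth$expected_post_curation_count, 150L)
  expect_true(all(is.finite(ds$truth$noiseless_labels)))
})

test_that("the label distribution is centred on the publication-bias mean", {
  ds <- fix_dataset() # defaults: target_mean 6.5, target_sd 1.3, noise 0.5
  y <- to_pic50(ds$records$standard_value)
  n <- length(y)
  # affine scaling pins the noiseless sample mean at 6.5; noise adds
  # 0.5/sqrt(n) CLT wobble
  expect_lt(abs(mean(y) - 6.5), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(y) - sqrt(1.3^2 + 0.5^2)), 0.2)
})

test_that("identical configs generate byte-identical data sets", {
  cfg <- synthetic_config(n_pairs = 100L, seed = 77L,
                          contamination_rates = list(replicate = 0.1,
                                                     pains = 0.05))
  d1 <- gen_dataset(cfg)
  d2 <- gen_dataset(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$noiseless_labels, d2$truth$noiseless_labels)
  expect_identical(d1$proteins$sequences, d2$proteins$sequences)
})

test_that("replicate noise calibrates to the configured variance", {
  cfg <- synthetic_config(n_pairs = 700L, seed = 13L,
                          contamination_rates = list(replicate = 0.9))
  ds <- gen_dataset(cfg)
  y <- to_pic50(ds$records$standard_value)
  key <- paste(ds$records$canonical_smiles, ds$records$uniprot_id, sep = "|")
  truth <- ds$truth$noiseless_labels[key]
  # every clean/replicate record deviates from its pair's noiseless label
  # by an independent Normal(0, 0.5) draw
  dev <- y - truth
  expect_gte(length(dev), 500L)
  expect_lt(abs(mean(dev^2) - 0.25), 0.2 * 0.25)
})

test_that("generated tables round-trip through disk", {
  ds <- gen_dataset(synthetic_config(n_pairs = 60L, seed = 3L))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- utils::read.csv(file.path(dir, "activity.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(ds$records))
  expect_equal(back$standard_value, ds$records$standard_value)
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_identical(seqs, ds$proteins$sequences)
  man <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(man$expected_post_curation_count, 60L)
})
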