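# Synthetic-data generator: protein families, ligand libraries from a
# template grammar, and ChEMBL-style activity tables with a known sparse
# latent label function, heterogeneous noise, publication-bias location and
# injectable curation contaminants. Every downstream stage of the pipeline
# is testable against the ground-truth manifest emitted here.

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Scaffold template grammar: topologically distinct ring frameworks with
# two substitution sites, plus acyclic substituent fragments. R-groups are
# acyclic so the generic Bemis-Murcko scaffold of every product equals its
# template's framework, and none can form a PAINS motif.
.scaffold_templates <- c(
  benzene          = "c1cc(%s)ccc1%s",
  cyclopentane     = "C1CC(%s)CC1%s",
  cyclobutane      = "C1C(%s)CC1%s",
  cycloheptane     = "C1CCC(%s)CCC1%s",
  naphthalene      = "c1ccc2cc(%s)ccc2c1%s",
  indane           = "C1(%s)Cc2ccc(%s)cc2C1",
  biphenyl         = "c1ccc(-c2ccc(%s)cc2)cc1%s",
  phenylcyclopentane = "C1CC(%s)CC1c1ccc(%s)cc1",
  diphenylmethane  = "c1cc(%s)ccc1Cc1ccc(%s)cc1",
  bibenzyl         = "c1cc(%s)ccc1CCc1ccc(%s)cc1",
  benzylcyclopentane = "C1CC(%s)CC1Cc1ccc(%s)cc1",
  bicyclopentyl    = "C1CC(%s)CC1C1CC(%s)CC1",
  terphenyl        = "c1cc(%s)ccc1-c1cccc(-c2ccc(%s)cc2)c1",
  cyclooctane      = "C1CCCC(%s)CCC1%s"
)

.rgroup_fragments <- c("C", "CC", "CCC", "C(C)C", "O", "N", "F", "Cl",
                       "OC", "CO", "C#N", "C(=O)O")

# PAINS-bearing contaminant molecules, each matching a pattern in the
# shipped catalog (quinones, rhodanine, hydrazone, thiourea,
# isothiazolone) and inside the 75-800 Da window.
.pains_molecules <- c(
  "CC1=CC(=O)C=CC1=O", "CCC1=CC(=O)C=CC1=O", "CCCC1=CC(=O)C=CC1=O",
  "OC1=CC(=O)C=CC1=O", "O=C1C(=O)C=CC(C)=C1",
  "O=C1CSC(=S)N1", "CC1SC(=S)NC1=O",
  "c1ccccc1C=NN", "NC(=S)Nc1ccccc1", "O=C1C=CSN1"
)

# Out-of-MW-range contaminant molecule (methane, 16 Da < 75 Da).
.mw_out_molecule <- "C"

.contaminant_kinds <- c("wrong_units", "low_confidence", "inconclusive",
                        "duplicate_flag", "replicate", "pains", "mw_out")

#' Configuration for the synthetic bioactivity generator
#'
#' Defaults define the reference experimental conditions: a small kinome-like
#' panel of related protein families, a ligand library spanning ten
#' scaffold classes, pIC50 labels from a sparse linear latent function over
#' the real computed descriptors with ~0.5 log-unit experimental noise, and
#' a publication-bias location/scale of 6.5 / 1.3 pIC50 units.
#'
#' @param n_families number of protein families.
#' @param members_per_family sequences per family, derived from a common
#'   root by per-residue substitution.
#' @param mutation_rate per-residue substitution probability within a family.
#' @param seq_len_range integer interval for root sequence lengths.
#' @param n_scaffolds number of scaffold templates drawn from the shipped
#'   grammar (max 14).
#' @param n_rgroups number of substituent fragments drawn from the shipped
#'   set (max 12); the library enumerates scaffold x rgroup^2 products.
#' @param n_pairs number of unique protein-ligand pairs sampled for the
#'   activity table.
#' @param noise_sd experimental noise on pIC50 labels (log units).
#' @param target_mean,target_sd publication-bias location and scale of the
#'   pIC50 distribution.
#' @param contamination_rates named probabilities for the contaminant kinds
#'   `wrong_units`, `low_confidence`, `inconclusive`, `duplicate_flag`,
#'   `replicate`, `pains`, `mw_out`; missing kinds default to 0.
#' @param sparsity fraction of the 4671 descriptor columns with nonzero
#'   true weight.
#' @param scaffold_effect fraction of the latent (noiseless) label
#'   variance carried by per-scaffold potency offsets — chemical-series
#'   effects that make held-out-scaffold prediction genuinely harder than
#'   random-split prediction.
#' @param seed integer; identical configs (incl. seed) generate identical
#'   output.
#' @return a `pcm_synth_config` list.
#' @export
synthetic_config <- function(n_families = 4L, members_per_family = 5L,
                             mutation_rate = 0.05,
                             seq_len_range = c(180L, 240L),
                             n_scaffolds = 10L, n_rgroups = 4L,
                             n_pairs = 1600L,
                             noise_sd = 0.5, target_mean = 6.5,
                             target_sd = 1.3,
                             contamination_rates = list(),
                             sparsity = 0.02, scaffold_effect = 0.25,
                             seed = 1L) {
  rates <- stats::setNames(rep(0, length(.contaminant_kinds)), .contaminant_kinds)
  if (length(contamination_rates) > 0) {
    bad <- setdiff(names(contamination_rates), .contaminant_kinds)
    if (length(bad) > 0) stop("unknown contaminant kind(s): ", paste(bad, collapse = ", "))
    rates[names(contamination_rates)] <- unlist(contamination_rates)
  }
  stopifnot(
    n_families >= 1, members_per_family >= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    length(seq_len_range) == 2, all(seq_len_range > 0),
    n_scaffolds >= 1, n_rgroups >= 1, n_pairs >= 1,
    noise_sd >= 0, target_sd > 0, sparsity > 0, sparsity <= 1,
    scaffold_effect >= 0, scaffold_effect < 1,
    all(rates >= 0), all(rates <= 1)
  )
  if (seq_len_range[1] > seq_len_range[2]) {
    stop("degenerate seq_len_range: min exceeds max")
  }
  structure(list(
    n_families = as.integer(n_families),
    members_per_family = as.integer(members_per_family),
    mutation_rate = mutation_rate,
    seq_len_range = as.integer(seq_len_range),
    n_scaffolds = as.integer(n_scaffolds),
    n_rgroups = as.integer(n_rgroups),
    n_pairs = as.integer(n_pairs),
    noise_sd = noise_sd, target_mean = target_mean, target_sd = target_sd,
    contamination_rates = as.list(rates),
    sparsity = sparsity, scaffold_effect = scaffold_effect,
    seed = as.integer(seed)
  ), class = "pcm_synth_config")
}

#' Generate a set of related protein families
#'
#' Each family has a random root sequence; members are derived from the
#' root by independent per-residue substitution at `mutation_rate` (always
#' to a different residue, so Hamming distance to the root is
#' Binomial(L, rate)).
#'
#' @param config a [synthetic_config()].
#' @return list with `sequences` (named character vector, UniProt-style
#'   IDs), `family` (named family label per ID) and `roots` (root sequence
#'   per family).
#' @export
gen_protein_family_set <- function(config) {
  stopifnot(inherits(config, "pcm_synth_config"))
  .with_seed(config$seed + 101L, {
    seqs <- character(0); fam <- character(0); roots <- character(0)
    idc <- 0L
    for (f in seq_len(config$n_families)) {
      lens <- config$seq_len_range[1]:config$seq_len_range[2]
      L <- lens[sample.int(length(lens), 1L)]
      root <- sample(AA_ALPHABET, L, replace = TRUE)
      roots[paste0("FAM", f)] <- paste(root, collapse = "")
      for (m in seq_len(config$members_per_family)) {
        member <- root
        mut <- stats::runif(L) < config$mutation_rate
        if (any(mut)) {
          member[mut] <- vapply(root[mut], function(r) {
            sample(setdiff(AA_ALPHABET, r), 1L)
          }, character(1))
        }
        idc <- idc + 1L
        id <- sprintf("Q%05d", idc)
        seqs[id] <- paste(member, collapse = "")
        fam[id] <- paste0("FAM", f)
      }
    }
    list(sequences = seqs, family = fam, roots = roots)
  })
}

#' Generate a ligand library from the shipped template grammar
#'
#' Enumerates `n_scaffolds` ring-scaffold templates crossed with
#' `n_rgroups`^2 substituent combinations, canonicalizes and deduplicates.
#' Templates are topologically distinct frameworks, so the library spans at
#' least `n_scaffolds` distinct generic Bemis-Murcko scaffolds.
#'
#' @param config a [synthetic_config()].
#' @return character vector of canonical SMILES.
#' @export
gen_ligand_library <- function(config) {
  stopifnot(inherits(config, "pcm_synth_config"))
  if (config$n_scaffolds > length(.scaffold_templates)) {
    stop("requested ", config$n_scaffolds, " scaffolds but the template grammar ships ",
         length(.scaffold_templates))
  }
  if (config$n_rgroups > length(.rgroup_fragments)) {
    stop("requested ", config$n_rgroups, " R-groups but the fragment set ships ",
         length(.rgroup_fragments))
  }
  .with_seed(config$seed + 202L, {
    tpl <- .scaffold_templates[sample(length(.scaffold_templates))][seq_len(config$n_scaffolds)]
    rg <- .rgroup_fragments[sample(length(.rgroup_fragments))][seq_len(config$n_rgroups)]
    smiles <- character(0)
    for (t in tpl) for (r1 in rg) for (r2 in rg) {
      smiles <- c(smiles, sprintf(t, r1, r2))
    }
    can <- vapply(smiles, canonical_smiles, character(1), USE.NAMES = FALSE)
    if (anyNA(can)) stop("internal: template grammar produced unparseable SMILES")
    unique(can)
  })
}

# Pair-level raw descriptor matrix (unscaled), used by the label model.
.pair_descriptor_matrix <- function(smiles, uniprot_ids, sequences) {
  ulig <- unique(smiles)
  lig_feat <- do.call(rbind, lapply(ulig, function(s) c(ecfp6(s), physchem(s))))
  rownames(lig_feat) <- ulig
  uprot <- unique(uniprot_ids)
  prot_feat <- do.call(rbind, lapply(uprot, function(p) protein_vector(sequences[[p]])))
  rownames(prot_feat) <- uprot
  X <- cbind(lig_feat[smiles, , drop = FALSE], prot_feat[uniprot_ids, , drop = FALSE])
  colnames(X) <- c(paste0("fp_", seq_len(4096L)), colnames(lig_feat)[4097:4104],
                   colnames(prot_feat))
  X
}

#' Generate a ChEMBL-style activity table with known ground truth
#'
#' Samples unique protein-ligand pairs, computes their true concatenated
#' descriptors (4096 fingerprint + 8 physicochemical + 567 protein), and
#' draws noiseless pIC50 labels from a sparse linear score over the
#' column-standardized descriptors plus sparse protein-x-ligand interaction
#' terms, affinely shifted/scaled to `target_mean`/`target_sd`. Observed
#' labels add Normal(0, noise_sd) and are emitted as IC50 nM records with
#' ChEMBL-style metadata. Contaminant records (wrong units, low confidence,
#' inconclusive comments, flagged duplicates, replicates, PAINS-bearing and
#' out-of-MW-range molecules) are appended at the configured rates; the
#' ground-truth manifest records what a correct curation must retain.
#'
#' @param proteins output of [gen_protein_family_set()].
#' @param ligands character vector of canonical SMILES.
#' @param config a [synthetic_config()].
#' @return list with `records` (data frame) and `truth` (ground-truth
#'   manifest, class `pcm_ground_truth`).
#' @export
gen_activity_table <- function(proteins, ligands, config) {
  stopifnot(inherits(config, "pcm_synth_config"))
  if (length(ligands) == 0 || length(proteins$sequences) == 0) {
    stop("empty protein or ligand set")
  }
  n_possible <- length(ligands) * length(proteins$sequences)
  if (config$n_pairs > n_possible) {
    stop("n_pairs (", config$n_pairs, ") exceeds available unique pairs (",
         n_possible, ")")
  }
  .with_seed(config$seed + 303L, {
    prot_ids <- names(proteins$sequences)
    pair_idx <- sample.int(n_possible, config$n_pairs)
    lig_i <- ((pair_idx - 1L) %% length(ligands)) + 1L
    prot_i <- ((pair_idx - 1L) %/% length(ligands)) + 1L
    smiles <- ligands[lig_i]
    upid <- prot_ids[prot_i]

    X <- .pair_descriptor_matrix(smiles, upid, proteins$sequences)
    mu <- colMeans(X)
    sdv <- sqrt(pmax(0, colMeans(X^2) - mu^2))
    sdv[sdv == 0] <- 1
    Xz <- sweep(sweep(X, 2, mu), 2, sdv, "/")

    p <- ncol(X)
    nnz <- max(1L, round(config$sparsity * p))
    w_idx <- sort(sample.int(p, nnz))
    w <- stats::rnorm(nnz)
    raw <- as.numeric(Xz[, w_idx, drop = FALSE] %*% w)

    n_int <- max(1L, round(0.05 * config$n_pairs))
    int_pick <- sample.int(config$n_pairs, n_int)
    int_w <- stats::rnorm(n_int)
    raw[int_pick] <- raw[int_pick] + int_w

    # per-scaffold potency offsets (chemical-series effects): a configured
    # fraction of the latent variance comes from the ligand's generic
    # scaffold, so held-out-scaffold prediction is structurally harder
    scaf_of_lig <- vapply(unique(smiles), generic_scaffold, character(1))
    scaf_levels <- unique(scaf_of_lig)
    scaf_offset <- stats::setNames(stats::rnorm(length(scaf_levels)),
                                   scaf_levels)
    z_scaf_raw <- unname(scaf_offset[scaf_of_lig[smiles]])
    z_desc <- (raw - mean(raw)) / stats::sd(raw)
    z_scaf <- if (stats::sd(z_scaf_raw) > 0) {
      (z_scaf_raw - mean(z_scaf_raw)) / stats::sd(z_scaf_raw)
    } else rep(0, length(z_scaf_raw))
    fe <- if (all(z_scaf == 0)) 0 else config$scaffold_effect
    z <- sqrt(1 - fe) * z_desc + sqrt(fe) * z_scaf

    a <- config$target_sd / stats::sd(z)
    b <- config$target_mean - a * mean(z)
    noiseless <- a * z + b
    pair_key <- paste(smiles, upid, sep = "|")
    names(noiseless) <- pair_key

    y <- noiseless + stats::rnorm(config$n_pairs, 0, config$noise_sd)
    rec <- data.frame(
      canonical_smiles = smiles, uniprot_id = upid,
      standard_type = "IC50", standard_value = 10^(9 - y),
      standard_units = "nM", confidence_score = 9L,
      activity_comment = "", potential_duplicate = 0L,
      stringsAsFactors = FALSE
    )

    rates <- config$contamination_rates
    extra <- list()
    pick_pairs <- function(k) sample.int(config$n_pairs, k, replace = TRUE)
    n_of <- function(kind) stats::rbinom(1L, config$n_pairs, rates[[kind]])

    k <- n_of("wrong_units")
    if (k > 0) {
      i <- pick_pairs(k)
      e <- rec[i, ]; e$standard_units <- "ug/mL"
      extra <- c(extra, list(e))
    }
    k <- n_of("low_confidence")
    if (k > 0) {
      i <- pick_pairs(k)
      e <- rec[i, ]; e$confidence_score <- sample(0:8, k, replace = TRUE)
      extra <- c(extra, list(e))
    }
    k <- n_of("inconclusive")
    if (k > 0) {
      i <- pick_pairs(k)
      e <- rec[i, ]; e$activity_comment <- "inconclusive"
      extra <- c(extra, list(e))
    }
    k <- n_of("duplicate_flag")
    if (k > 0) {
      i <- pick_pairs(k)
      e <- rec[i, ]; e$potential_duplicate <- 1L
      extra <- c(extra, list(e))
    }
    k <- n_of("replicate")
    if (k > 0) {
      i <- pick_pairs(k)
      e <- rec[i, ]
      yrep <- noiseless[i] + stats::rnorm(k, 0, config$noise_sd)
      e$standard_value <- 10^(9 - yrep)
      extra <- c(extra, list(e))
    }
    k <- n_of("pains")
    if (k > 0) {
      pains_smi <- vapply(
        .pains_molecules[sample.int(length(.pains_molecules), k, replace = TRUE)],
        canonical_smiles, character(1), USE.NAMES = FALSE)
      ybad <- stats::rnorm(k, config$target_mean, config$target_sd)
      e <- data.frame(
        canonical_smiles = pains_smi,
        uniprot_id = prot_ids[sample.int(length(prot_ids), k, replace = TRUE)],
        standard_type = "IC50", standard_value = 10^(9 - ybad),
        standard_units = "nM", confidence_score = 9L,
        activity_comment = "", potential_duplicate = 0L,
        stringsAsFactors = FALSE
      )
      extra <- c(extra, list(e))
    }
    k <- n_of("mw_out")
    if (k > 0) {
      ybad <- stats::rnorm(k, config$target_mean, config$target_sd)
      e <- data.frame(
        canonical_smiles = canonical_smiles(.mw_out_molecule),
        uniprot_id = prot_ids[sample.int(length(prot_ids), k, replace = TRUE)],
        standard_type = "IC50", standard_value = 10^(9 - ybad),
        standard_units = "nM", confidence_score = 9L,
        activity_comment = "", potential_duplicate = 0L,
        stringsAsFactors = FALSE
      )
      extra <- c(extra, list(e))
    }

    records <- rbind(rec, do.call(rbind, extra))
    records <- records[sample.int(nrow(records)), , drop = FALSE]
    records$record_id <- sprintf("SYN%06d", seq_len(nrow(records)))
    rownames(records) <- NULL
    records <- records[, c("record_id", "canonical_smiles", "uniprot_id",
                           "standard_type", "standard_value", "standard_units",
                           "confidence_score", "activity_comment",
                           "potential_duplicate")]

    truth <- structure(list(
      true_weights = data.frame(index = w_idx, feature = colnames(X)[w_idx],
                                weight = w, stringsAsFactors = FALSE),
      interaction_weights = data.frame(
        canonical_smiles = smiles[int_pick], uniprot_id = upid[int_pick],
        weight = int_w, stringsAsFactors = FALSE),
      noiseless_labels = noiseless,
      scaffold_offsets = scaf_offset,
      expected_post_curation_count = config$n_pairs,
      affine = c(scale = a, shift = b),
      descriptor_center = mu, descriptor_scale = sdv
    ), class = "pcm_ground_truth")

    list(records = records, truth = truth)
  })
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper: proteins, ligand library and activity table from
#' one config.
#'
#' @param config a [synthetic_config()].
#' @return list with `records`, `truth`, `proteins`, `ligands`, `config`.
#' @export
gen_dataset <- function(config) {
  proteins <- gen_protein_family_set(config)
  ligands <- gen_ligand_library(config)
  tab <- gen_activity_table(proteins, ligands, config)
  list(records = tab$records, truth = tab$truth, proteins = proteins,
       ligands = ligands, config = config)
}

#' Write a synthetic data set to disk
#'
#' Activity table as CSV, sequences as FASTA, ground truth as a JSON
#' manifest.
#'
#' @param dataset output of [gen_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$records, file.path(dir, "activity.csv"),
                   row.names = FALSE)
  write_fasta(dataset$proteins$sequences, file.path(dir, "sequences.fasta"))
  tr <- dataset$truth
  manifest <- list(
    expected_post_curation_count = tr$expected_post_curation_count,
    affine = as.list(tr$affine),
    true_weights = tr$true_weights,
    interaction_weights = tr$interaction_weights,
    noiseless_labels = as.list(tr$noiseless_labels)
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
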