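# Record partitioning: generic Bemis-Murcko scaffold splits, random
# splits, protein-held-out splits, and the nested training/calibration
# split used for inductive conformal prediction.

.new_split <- function(train_ids, valid_ids, calibration_ids = character(0),
                       method, group_key, seed, target_fraction) {
  structure(list(
    train_ids = train_ids, valid_ids = valid_ids,
    calibration_ids = calibration_ids, method = method,
    group_key = group_key, seed = as.integer(seed),
    target_fraction = target_fraction,
    achieved_fraction = length(train_ids) /
      (length(train_ids) + length(valid_ids) + length(calibration_ids))
  ), class = "pcm_split")
}

#' @export
print.pcm_split <- function(x, ...) {
  cat(sprintf("pcm_split [%s]: %d train / %d valid / %d calibration (target %.2f, achieved %.3f)\n",
              x$method, length(x$train_ids), length(x$valid_ids),
              length(x$calibration_ids), x$target_fraction,
              x$achieved_fraction))
  invisible(x)
}

# Greedy shuffled-group assignment: groups enter training in seeded random
# order until the record-count target is reached; the crossing group is
# included. Fraction error is bounded by the largest group.
.grouped_split <- function(records, groups, fraction, seed, method) {
  stopifnot(is.data.frame(records), nrow(records) >= 2,
            fraction > 0, fraction < 1)
  if (length(unique(groups)) < 2) {
    stop("split impossible without leakage: only one ", method, " group")
  }
  .with_seed(seed, {
    ug <- sample(unique(groups))
    target <- fraction * nrow(records)
    train_groups <- character(0)
    n_train <- 0
    for (g in ug) {
      if (n_train >= target) break
      train_groups <- c(train_groups, g)
      n_train <- n_train + sum(groups == g)
    }
    if (length(train_groups) == length(ug)) {
      train_groups <- train_groups[-length(train_groups)]
    }
    in_train <- groups %in% train_groups
    .new_split(records$record_id[in_train], records$record_id[!in_train],
               method = method,
               group_key = stats::setNames(groups, records$record_id),
               seed = seed, target_fraction = fraction)
  })
}

#' Generic Bemis-Murcko scaffold split
#'
#' Groups records by the generic scaffold key of their ligand
#' ([generic_scaffold()]); scaffold groups are shuffled by seed and
#' greedily assigned to training until the record-count fraction is
#' reached. No scaffold spans both sets; all acyclic molecules share the
#' reserved empty key and move together.
#'
#' @param records curated data frame with `record_id` and
#'   `canonical_smiles`.
#' @param fraction target training fraction (of records).
#' @param seed integer.
#' @return a `pcm_split`.
#' @export
scaffold_split <- function(records, fraction = 0.8, seed = 1L) {
  usm <- unique(records$canonical_smiles)
  key_map <- vapply(usm, generic_scaffold, character(1))
  groups <- unname(key_map[records$canonical_smiles])
  .grouped_split(records, groups, fraction, seed, "scaffold")
}

#' Random record-level split
#'
#' @param records data frame with `record_id`.
#' @param fraction target training fraction.
#' @param seed integer.
#' @return a `pcm_split`.
#' @export
random_split <- function(records, fraction = 0.8, seed = 1L) {
  stopifnot(nrow(records) >= 2, fraction > 0, fraction < 1)
  .with_seed(seed, {
    n <- nrow(records)
    n_train <- round(fraction * n)
    idx <- sample.int(n, n_train)
    in_train <- seq_len(n) %in% idx
    .new_split(records$record_id[in_train], records$record_id[!in_train],
               method = "random",
               group_key = stats::setNames(records$record_id, records$record_id),
               seed = seed, target_fraction = fraction)
  })
}

#' Protein-held-out split
#'
#' Groups records by UniProt ID; no protein spans both sets.
#'
#' @param records data frame with `record_id` and `uniprot_id`.
#' @param fraction target training fraction (of records).
#' @param seed integer.
#' @return a `pcm_split`.
#' @export
protein_split <- function(records, fraction = 0.8, seed = 1L) {
  .grouped_split(records, records$uniprot_id, fraction, seed, "protein")
}

#' Carve a calibration set out of an existing training set
#'
#' Random record-level split of the parent's training IDs into a proper
#' training set and a calibration set; the validation set is untouched.
#'
#' @param assignment a `pcm_split`.
#' @param fraction fraction of the parent training set kept for proper
#'   training.
#' @param seed integer.
#' @return a `pcm_split` with method `"calibration"`.
#' @export
calibration_split <- function(assignment, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(assignment, "pcm_split"),
            length(assignment$train_ids) > 0)
  .with_seed(seed, {
    ids <- assignment$train_ids
    n_train <- round(fraction * length(ids))
    if (n_train >= length(ids)) {
      stop("calibration set would be empty")
    }
    keep <- sample.int(length(ids), n_train)
    .new_split(ids[sort(keep)], assignment$valid_ids,
               calibration_ids = ids[sort(setdiff(seq_along(ids), keep))],
               method = "calibration", group_key = assignment$group_key,
               seed = seed, target_fraction = fraction)
  })
}
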