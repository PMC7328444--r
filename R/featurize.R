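# Pair-level feature assembly: ECFP6 fingerprint block (binary, unscaled),
# physicochemical block (8) and protein block (567), the latter two
# standard-scaled with parameters fitted on the training matrix only.

#' Assemble the pair-level feature matrix
#'
#' One row per record: `[ecfp6 (4096) | physchem (8) | protein (567)]` =
#' 4671 columns. The fingerprint block stays binary; the remaining columns
#' are standard-scaled. Pass `scaler = NULL` for the training matrix (the
#' scaler is fitted and returned) and the fitted scaler for
#' validation/calibration/test matrices.
#'
#' @param records curated data frame with `canonical_smiles` and
#'   `uniprot_id` columns.
#' @param sequences named character vector of protein sequences.
#' @param scaler `NULL` to fit, or the `scaler` element of a previously
#'   assembled training matrix.
#' @return a `pcm_features` list: `values` (dense matrix), `block_index`
#'   (named column ranges), `scaler` (per-column center/scale), `row_keys`.
#' @export
assemble_matrix <- function(records, sequences, scaler = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  missing_prot <- setdiff(unique(records$uniprot_id), names(sequences))
  if (length(missing_prot) > 0) {
    stop("no sequence for protein ID(s): ", paste(missing_prot, collapse = ", "))
  }
  ulig <- unique(records$canonical_smiles)
  lig_feat <- do.call(rbind, lapply(ulig, function(s) c(ecfp6(s), physchem(s))))
  rownames(lig_feat) <- ulig
  uprot <- unique(records$uniprot_id)
  prot_feat <- do.call(rbind, lapply(uprot, function(p) protein_vector(sequences[[p]])))
  rownames(prot_feat) <- uprot

  X <- cbind(lig_feat[records$canonical_smiles, , drop = FALSE],
             prot_feat[records$uniprot_id, , drop = FALSE])
  colnames(X) <- c(paste0("fp_", seq_len(4096L)),
                   colnames(lig_feat)[4097:4104],
                   colnames(prot_feat))
  rownames(X) <- NULL
  block_index <- list(fingerprint = 1:4096, physchem = 4097:4104,
                      protein = 4105:4671)

  scale_cols <- c(block_index$physchem, block_index$protein)
  if (is.null(scaler)) {
    mu <- colMeans(X[, scale_cols, drop = FALSE])
    sdv <- sqrt(pmax(0, colMeans(X[, scale_cols, drop = FALSE]^2) - mu^2))
    sdv[sdv == 0] <- 1
    scaler <- list(columns = scale_cols, center = mu, scale = sdv)
  } else {
    stopifnot(identical(scaler$columns, scale_cols))
  }
  X[, scale_cols] <- sweep(sweep(X[, scale_cols, drop = FALSE], 2, scaler$center),
                           2, scaler$scale, "/")

  structure(list(values = X, block_index = block_index, scaler = scaler,
                 row_keys = data.frame(
                   record_id = records$record_id,
                   canonical_smiles = records$canonical_smiles,
                   uniprot_id = records$uniprot_id,
                   stringsAsFactors = FALSE)),
            class = "pcm_features")
}

# Stable hash of the column schema, embedded in trained models so a
# predict-time mismatch fails fast.
.schema_hash <- function(fm) {
  s <- paste(c(colnames(fm$values), vapply(fm$block_index, function(i)
    paste(range(i), collapse = "-"), character(1))), collapse = ";")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 977)) %% 2147483647
}

#' Persist a feature matrix
#'
#' Writes the dense values as a columnar Feather/Arrow file next to a
#' JSON header carrying the block index, scaler parameters and row keys.
#'
#' @param fm a `pcm_features` object.
#' @param prefix output path prefix; writes `<prefix>.feather` and
#'   `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
save_features <- function(fm, prefix) {
  stopifnot(inherits(fm, "pcm_features"))
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("feature-matrix persistence requires the 'arrow' package")
  }
  arrow::write_feather(as.data.frame(fm$values), paste0(prefix, ".feather"))
  hdr <- list(block_index = lapply(fm$block_index, range),
              scaler = list(columns = fm$scaler$columns,
                            center = as.list(fm$scaler$center),
                            scale = as.list(fm$scaler$scale)),
              row_keys = fm$row_keys)
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Load a persisted feature matrix
#'
#' @param prefix path prefix used in [save_features()].
#' @return a `pcm_features` object.
#' @export
load_features <- function(prefix) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("feature-matrix persistence requires the 'arrow' package")
  }
  values <- as.matrix(arrow::read_feather(paste0(prefix, ".feather")))
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  block_index <- lapply(hdr$block_index, function(r) r[1]:r[2])
  scaler <- list(columns = as.integer(hdr$scaler$columns),
                 center = unlist(hdr$scaler$center),
                 scale = unlist(hdr$scaler$scale))
  structure(list(values = values, block_index = block_index,
                 scaler = scaler, row_keys = hdr$row_keys),
            class = "pcm_features")
}

#' Subset a feature matrix by record IDs
#'
#' @param fm a `pcm_features` object.
#' @param record_ids IDs to keep (row order follows `record_ids`).
#' @return a `pcm_features` object with the selected rows.
#' @export
subset_features <- function(fm, record_ids) {
  stopifnot(inherits(fm, "pcm_features"))
  idx <- match(record_ids, fm$row_keys$record_id)
  if (anyNA(idx)) stop("unknown record ID(s) in subset")
  structure(list(values = fm$values[idx, , drop = FALSE],
                 block_index = fm$block_index, scaler = fm$scaler,
                 row_keys = fm$row_keys[idx, , drop = FALSE]),
            class = "pcm_features")
}
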