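# Record curation: structure standardization, rule-based filtering with an
# auditable removal ledger, median aggregation of replicate measurements,
# pIC50 conversion and label scaling.

#' Curation rules
#'
#' @param required_units accepted `standard_units` value.
#' @param required_confidence minimum (and required) confidence score.
#' @param forbidden_comment records whose `activity_comment` equals this
#'   (case-insensitive) are removed.
#' @param mw_min,mw_max molecular-weight window in Da.
#' @param pains_enabled flag; when `FALSE` the PAINS filter is skipped.
#' @return a `pcm_curation_rules` list.
#' @export
curation_rules <- function(required_units = "nM", required_confidence = 9L,
                           forbidden_comment = "inconclusive",
                           mw_min = 75, mw_max = 800, pains_enabled = TRUE) {
  stopifnot(mw_min < mw_max)
  structure(list(required_units = required_units,
                 required_confidence = as.integer(required_confidence),
                 forbidden_comment = forbidden_comment,
                 mw_min = mw_min, mw_max = mw_max,
                 pains_enabled = isTRUE(pains_enabled)),
            class = "pcm_curation_rules")
}

.required_columns <- c("record_id", "canonical_smiles", "uniprot_id",
                       "standard_type", "standard_value", "standard_units",
                       "confidence_score", "activity_comment",
                       "potential_duplicate")

#' Apply the record-level curation filters
#'
#' Retained records satisfy every rule: parseable (standardizable)
#' structure, required units, not flagged as a potential duplicate,
#' required confidence score, comment not forbidden, molecular weight
#' inside the window, and PAINS-free. Each removed record is attributed to
#' the first rule (in that order) that rejects it; the audit satisfies
#' input = output + sum(removals).
#'
#' @param records activity data frame (columns as written by
#'   [write_dataset()]).
#' @param rules a [curation_rules()].
#' @return list with `records` (retained rows, `canonical_smiles` replaced
#'   by the standardized form) and `audit` (class `pcm_curation_audit`).
#' @export
apply_filters <- function(records, rules = curation_rules()) {
  stopifnot(inherits(rules, "pcm_curation_rules"), is.data.frame(records))
  missing_cols <- setdiff(.required_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  rule_names <- c("unparseable_structure", "units", "potential_duplicate",
                  "confidence", "comment", "mw_range", "pains")
  removed <- stats::setNames(integer(length(rule_names)), rule_names)
  n_in <- nrow(records)
  if (n_in == 0) {
    audit <- structure(list(input_n = 0L, output_n = 0L, removed = removed),
                       class = "pcm_curation_audit")
    return(list(records = records, audit = audit))
  }

  usm <- unique(records$canonical_smiles)
  std_map <- vapply(usm, standardize_structure, character(1))
  std <- unname(std_map[records$canonical_smiles])
  alive <- rep(TRUE, n_in)

  drop_rule <- function(alive, bad, rule) {
    bad <- alive & bad
    removed[rule] <<- removed[rule] + sum(bad)
    alive & !bad
  }
  # metadata NA handling: a missing comment is benign (CSV round-trips ""
  # as NA); missing units/confidence/duplicate-flag fail their rule
  cmt <- records$activity_comment
  cmt[is.na(cmt)] <- ""
  alive <- drop_rule(alive, is.na(std), "unparseable_structure")
  alive <- drop_rule(alive, is.na(records$standard_units) |
                       records$standard_units != rules$required_units, "units")
  alive <- drop_rule(alive, is.na(records$potential_duplicate) |
                       records$potential_duplicate != 0, "potential_duplicate")
  alive <- drop_rule(alive, is.na(records$confidence_score) |
                       records$confidence_score < rules$required_confidence,
                     "confidence")
  alive <- drop_rule(alive, tolower(trimws(cmt)) ==
                       tolower(rules$forbidden_comment), "comment")

  # structure-dependent rules on the survivors' unique standardized SMILES
  alive_smiles <- unique(std[alive])
  if (length(alive_smiles) > 0) {
    mw_map <- vapply(alive_smiles, function(s) physchem(s)[["mw"]], numeric(1))
    mw <- unname(mw_map[std]); mw[is.na(std)] <- NA
    alive <- drop_rule(alive, !is.na(mw) & (mw < rules$mw_min | mw > rules$mw_max),
                       "mw_range")
    if (rules$pains_enabled) {
      alive_smiles <- unique(std[alive])
      pains_map <- vapply(alive_smiles, pains_match, logical(1))
      hit <- unname(pains_map[std]); hit[is.na(std)] <- FALSE
      alive <- drop_rule(alive, !is.na(hit) & hit, "pains")
    }
  }

  out <- records[alive, , drop = FALSE]
  out$canonical_smiles <- std[alive]
  rownames(out) <- NULL
  audit <- structure(list(input_n = n_in, output_n = nrow(out),
                          removed = removed),
                     class = "pcm_curation_audit")
  list(records = out, audit = audit)
}

#' @export
print.pcm_curation_audit <- function(x, ...) {
  cat("Curation audit:", x$input_n, "->", x$output_n, "records\n")
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat("  removed by", r, ":", x$removed[[r]], "\n")
  }
  invisible(x)
}

#' Aggregate replicate measurements by the median
#'
#' Collapses records sharing (standardized SMILES, protein ID) into one
#' record whose `standard_value` is the group median (even-sized groups:
#' mean of the two middle values); `n_measurements` records the group size.
#'
#' @param records filtered activity data frame.
#' @return aggregated data frame, one row per pair.
#' @export
aggregate_median <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records$n_measurements <- integer(0)
    return(records)
  }
  key <- paste(records$canonical_smiles, records$uniprot_id, sep = "|")
  ord <- order(match(key, unique(key)))
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  med <- tapply(records$standard_value, factor(key, levels = unique(key)),
                stats::median)
  nmeas <- tapply(rep(1L, nrow(records)), factor(key, levels = unique(key)), sum)
  out <- records[first, , drop = FALSE]
  out$standard_value <- as.numeric(med)
  out$n_measurements <- as.integer(nmeas)
  rownames(out) <- NULL
  out
}

#' Convert IC50 (nM) to pIC50
#'
#' pIC50 = 9 - log10(IC50 in nM).
#'
#' @param ic50_nm positive numeric vector of IC50 values in nM.
#' @return pIC50 vector.
#' @export
to_pic50 <- function(ic50_nm) {
  stopifnot(is.numeric(ic50_nm))
  if (any(!is.na(ic50_nm) & ic50_nm <= 0)) {
    stop("nonpositive IC50 value; remove before conversion")
  }
  9 - log10(ic50_nm)
}

#' Full curation pipeline
#'
#' Filters, aggregates by median, converts to pIC50. Records with
#' nonpositive activity values are removed (audited) before conversion.
#'
#' @param records raw activity data frame.
#' @param rules a [curation_rules()].
#' @return list with `records` (curated rows with a `pic50` column) and
#'   `audit`.
#' @export
curate_table <- function(records, rules = curation_rules()) {
  bad_value <- !is.finite(records$standard_value) | records$standard_value <= 0
  n_bad <- sum(bad_value)
  records <- records[!bad_value, , drop = FALSE]
  f <- apply_filters(records, rules)
  agg <- aggregate_median(f$records)
  agg$pic50 <- to_pic50(agg$standard_value)
  audit <- f$audit
  audit$removed <- c(nonpositive_value = n_bad, audit$removed)
  audit$input_n <- audit$input_n + n_bad
  audit$n_aggregated <- sum(agg$n_measurements > 1L)
  audit$output_n_aggregated <- nrow(agg)
  list(records = agg, audit = audit)
}

# --- label scaling -----------------------------------------------------

#' Fit a standard scaler on training labels
#'
#' @param train_pic50 numeric vector of training labels (length >= 2,
#'   nonzero spread).
#' @return a `pcm_label_scaler` with population mean and SD.
#' @export
fit_label_scaler <- function(train_pic50) {
  stopifnot(is.numeric(train_pic50), length(train_pic50) >= 2)
  mu <- mean(train_pic50)
  sigma <- sqrt(mean((train_pic50 - mu)^2))
  if (sigma == 0) stop("zero spread in training labels; cannot scale")
  structure(list(mu = mu, sigma = sigma), class = "pcm_label_scaler")
}

#' Apply a fitted label scaler
#' @param scaler a [fit_label_scaler()] result.
#' @param y labels.
#' @return scaled labels (y - mu)/sigma.
#' @export
apply_label_scaler <- function(scaler, y) {
  stopifnot(inherits(scaler, "pcm_label_scaler"))
  (y - scaler$mu) / scaler$sigma
}

#' Invert a fitted label scaler
#' @param scaler a [fit_label_scaler()] result.
#' @param y_scaled scaled labels.
#' @return labels on the original scale.
#' @export
invert_label_scaler <- function(scaler, y_scaled) {
  stopifnot(inherits(scaler, "pcm_label_scaler"))
  y_scaled * scaler$sigma + scaler$mu
}
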