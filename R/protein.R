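# Protein sequence descriptors: amino-acid composition (AAC, 20),
# dipeptide composition (DPC, 400) and composition-transition-distribution
# (CTD, 7 attributes x 21 = 147). Concatenated: the 567-dimensional
# protein block of the pair-level feature vector.

#' Canonical amino-acid alphabet (fixed descriptor order)
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1])
  }
  chars
}

#' Amino-acid composition (AAC)
#'
#' Per-residue frequencies over the fixed alphabet ACDEFGHIKLMNPQRSTVWY.
#'
#' @param sequence amino-acid string (canonical residues only).
#' @return named numeric vector of length 20 summing to 1.
#' @export
aac <- function(sequence) {
  chars <- .check_sequence(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("aac_", AA_ALPHABET)
  out
}

#' Dipeptide composition (DPC)
#'
#' Overlapping-dipeptide frequencies, counts/(L-1), in row-major order over
#' the fixed alphabet.
#'
#' @param sequence amino-acid string of length >= 2.
#' @return named numeric vector of length 400 summing to 1.
#' @export
dpc <- function(sequence) {
  chars <- .check_sequence(sequence)
  L <- length(chars)
  if (L < 2L) stop("dpc requires sequence length >= 2")
  pairs <- paste0(chars[-L], chars[-1L])
  lv <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- table(factor(pairs, levels = lv))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- paste0("dpc_", lv)
  out
}

.ctd_tables <- function() {
  if (!is.null(.pcmcp_cache[["ctd_tables"]])) return(.pcmcp_cache[["ctd_tables"]])
  path <- system.file("extdata", "ctd_groups.tsv", package = "pcmcp")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  groups <- lapply(seq_len(nrow(tab)), function(i) {
    g <- lapply(tab[i, c("group1", "group2", "group3")], function(s) strsplit(s, "")[[1]])
    all_res <- sort(unname(unlist(g)))
    if (!identical(all_res, sort(AA_ALPHABET))) {
      stop("CTD table integrity: attribute '", tab$attribute[i],
           "' is not a partition of the 20 residues")
    }
    g
  })
  names(groups) <- tab$attribute
  assign("ctd_tables", groups, envir = .pcmcp_cache)
  groups
}

#' Composition-transition-distribution (CTD) descriptors
#'
#' For each of seven physicochemical attributes, residues are mapped into
#' three groups (shipped partition tables) and 21 values are computed:
#' composition (3 group fractions), transition (3 adjacent-pair rates
#' T(i,j) = (N_ij + N_ji)/(L-1) for pairs 12, 13, 23) and distribution
#' (per group, the sequence-position percentiles 100*pos/L of the first,
#' 25%, 50%, 75% and 100% occurrences, with the k% occurrence taken as the
#' ceiling(k/100 * n_g)-th; an absent group contributes five zeros).
#'
#' @param sequence amino-acid string of length >= 2.
#' @return named numeric vector of length 147 (7 x 21), attribute-major.
#' @export
ctd <- function(sequence) {
  chars <- .check_sequence(sequence)
  L <- length(chars)
  if (L < 2L) stop("ctd requires sequence length >= 2")
  tabs <- .ctd_tables()
  out <- numeric(0)
  for (attr_name in names(tabs)) {
    g <- tabs[[attr_name]]
    grp <- integer(L)
    for (k in 1:3) grp[chars %in% g[[k]]] <- k
    comp <- as.numeric(table(factor(grp, levels = 1:3))) / L
    adj <- cbind(grp[-L], grp[-1L])
    trans <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
      sum((adj[, 1] == p[1] & adj[, 2] == p[2]) |
            (adj[, 1] == p[2] & adj[, 2] == p[1])) / (L - 1L)
    }, numeric(1))
    distr <- numeric(0)
    for (k in 1:3) {
      pos <- which(grp == k)
      n_g <- length(pos)
      if (n_g == 0L) {
        d <- rep(0, 5)
      } else {
        idx <- c(1L, ceiling(c(0.25, 0.50, 0.75, 1.00) * n_g))
        d <- 100 * pos[idx] / L
      }
      distr <- c(distr, d)
    }
    block <- c(comp, trans, distr)
    names(block) <- paste0("ctd_", attr_name, "_",
                           c(paste0("c", 1:3),
                             c("t12", "t13", "t23"),
                             paste0("d", rep(1:3, each = 5), "_",
                                    rep(c("first", "p25", "p50", "p75", "p100"), 3))))
    out <- c(out, block)
  }
  out
}

#' Full protein descriptor vector
#'
#' Concatenation `[aac | dpc | ctd]` = 20 + 400 + 147 = 567 values, the
#' protein block of the pair-level feature vector.
#'
#' @param sequence amino-acid string.
#' @return named numeric vector of length 567.
#' @export
protein_vector <- function(sequence) {
  .memo(paste0("prot|", sequence), function() {
    c(aac(sequence), dpc(sequence), ctd(sequence))
  })
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file; record IDs are taken as the first whitespace
#'   token of each header.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
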