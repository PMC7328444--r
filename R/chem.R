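# Ligand chemistry: SMILES standardization, descriptors, fingerprints,
# PAINS substructure flags and generic Bemis-Murcko scaffold keys.
# All structure handling goes through OpenBabel (ChemmineOB / ChemmineR);
# graph-level operations (rings, frameworks) work on the connection table.

# Per-session memo cache: descriptor functions are pure, so results are
# keyed by their input string. Speeds up repeated featurization of the
# same library across seeds.
.pcmcp_cache <- new.env(parent = emptyenv())

.memo <- function(key, fn) {
  if (!is.null(.pcmcp_cache[[key]])) return(.pcmcp_cache[[key]])
  val <- fn()
  assign(key, val, envir = .pcmcp_cache)
  val
}

.ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Canonicalize a SMILES string
#'
#' Round-trips the structure through OpenBabel's canonical SMILES writer.
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES, or `NA_character_` if the input is unparseable.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .memo(paste0("can|", smiles), function() {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
      error = function(e) ""
    )
    out <- sub("[\t\n].*$", "", out)
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  })
}

# Rule-based charge neutralization on the SMILES text. Protonates anionic
# O/S/N and strips protons from protonated amines; quaternary centres with
# no H to remove are left as-is (no chemically valid neutral form).
.neutralize_smiles <- function(smiles) {
  s <- smiles
  s <- gsub("[O-]",   "O",    s, fixed = TRUE)
  s <- gsub("[S-]",   "S",    s, fixed = TRUE)
  s <- gsub("[N-]",   "N",    s, fixed = TRUE)
  s <- gsub("[NH3+]", "N",    s, fixed = TRUE)
  s <- gsub("[NH2+]", "N",    s, fixed = TRUE)
  s <- gsub("[NH+]",  "N",    s, fixed = TRUE)
  s <- gsub("[nH+]",  "[nH]", s, fixed = TRUE)
  s
}

.count_carbons <- function(frag) {
  # heavy-atom proxy used only to rank fragments: count element symbols
  nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", frag)))
}

#' Standardize a ligand structure
#'
#' Keeps the largest organic fragment (salt stripping), neutralizes charges
#' where a valid neutral form exists, and emits canonical SMILES. The
#' operation is idempotent.
#'
#' @param smiles a single SMILES string.
#' @return canonical standardized SMILES, or `NA_character_` when the input
#'   cannot be parsed.
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .memo(paste0("std|", smiles), function() {
    can <- canonical_smiles(smiles)
    if (is.na(can)) return(NA_character_)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1L) {
      organic <- grepl("[cC]", frags)
      if (any(organic)) frags <- frags[organic]
      frags <- frags[order(-vapply(frags, .count_carbons, numeric(1)))]
      can <- frags[[1]]
    }
    can <- .neutralize_smiles(can)
    canonical_smiles(can)
  })
}

# Heavy-atom count from a molecular formula string (e.g. "C8H10O" -> 9).
.formula_heavy_atoms <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  total <- 0L
  for (t in toks) {
    el <- gsub("\\d", "", t)
    cnt <- gsub("\\D", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (el != "H") total <- total + cnt
  }
  total
}

# Connection table (heavy atoms only) as element vector + bond data frame.
# ChemmineR's SDF round-trip fails for bond-less molecules (single heavy
# atom); those fall back to the OpenBabel formula.
.mol_graph <- function(smiles) {
  .memo(paste0("graph|", smiles), function() {
    empty_bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                              order = integer(0))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (nrow(ab) == 0L || !all(grepl("^[A-Za-z]+_\\d+$", rownames(ab)))) {
      # bond-less molecules (single heavy atom) break the SDF round-trip
      pr <- ChemmineOB::prop_OB(.ob_mol(smiles))
      n <- .formula_heavy_atoms(as.character(pr$formula))
      if (n > 1L) stop("cannot build connection table for: ", smiles)
      return(list(elements = gsub("[^A-Za-z]", "", smiles), bonds = empty_bonds,
                  n = n))
    }
    elements <- sub("_.*$", "", rownames(ab))
    n <- length(elements)
    if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
      bonds <- empty_bonds
    } else {
      bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
    }
    list(elements = elements, bonds = bonds, n = n)
  })
}

# Flags each bond as ring / non-ring via bridge detection.
.ring_bonds <- function(g) {
  if (nrow(g$bonds) == 0L) return(logical(0))
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$a1, g$bonds$a2), directed = FALSE)
  br <- igraph::bridges(ig)
  inring <- rep(TRUE, nrow(g$bonds))
  inring[as.integer(br)] <- FALSE
  inring
}

#' Ligand physicochemical descriptor vector
#'
#' The eight descriptors, in fixed order: molecular weight (Da), topological
#' polar surface area, H-bond donor count, H-bond acceptor count, logP,
#' heavy-atom count, rotatable-bond count, ring count. MW/TPSA/HBD/HBA/logP
#' come from OpenBabel; heavy atoms, rotatable bonds (acyclic single bonds
#' between non-terminal heavy atoms) and ring count (cyclomatic number) are
#' computed on the connection table.
#'
#' @param smiles standardized SMILES string.
#' @return named numeric vector of length 8.
#' @export
physchem <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .memo(paste0("pc|", smiles), function() {
    mol <- tryCatch(.ob_mol(smiles), error = function(e) NULL)
    if (is.null(mol)) stop("unparseable SMILES: ", smiles)
    pr <- ChemmineOB::prop_OB(mol)
    g <- .mol_graph(smiles)
    deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = g$n)
    inring <- .ring_bonds(g)
    rot <- if (nrow(g$bonds) == 0L) 0L else {
      sum(g$bonds$order == 1L & !inring &
            deg[g$bonds$a1] >= 2L & deg[g$bonds$a2] >= 2L)
    }
    ncomp <- if (g$n == 0L) 0L else {
      ig <- igraph::graph_from_edgelist(cbind(g$bonds$a1, g$bonds$a2),
                                        directed = FALSE)
      ig <- igraph::add_vertices(ig, max(0L, g$n - igraph::vcount(ig)))
      igraph::count_components(ig)
    }
    rings <- nrow(g$bonds) - g$n + ncomp
    c(mw = as.numeric(pr$MW), tpsa = as.numeric(pr$TPSA),
      hbd = as.numeric(pr$HBD), hba = as.numeric(pr$HBA1),
      logp = as.numeric(pr$logP), heavy_atoms = as.numeric(g$n),
      rotatable_bonds = as.numeric(rot), ring_count = as.numeric(rings))
  })
}

#' ECFP6 circular fingerprint
#'
#' Extended-connectivity fingerprint of radius 3 (diameter 6) folded to a
#' fixed-length binary vector, invariant to the input atom ordering of the
#' same molecule.
#'
#' @param smiles standardized SMILES string.
#' @param n_bits fingerprint length; the native fold is 4096 bits and
#'   smaller powers of two are obtained by OR-folding.
#' @return numeric 0/1 vector of length `n_bits`.
#' @export
ecfp6 <- function(smiles, n_bits = 4096L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, n_bits >= 1)
  if (n_bits > 4096L) stop("n_bits above the native 4096-bit fold is not supported")
  base <- .memo(paste0("fp|", smiles), function() {
    mol <- tryCatch(.ob_mol(smiles), error = function(e) NULL)
    fp <- tryCatch(ChemmineOB::fingerprint_OB(mol, "ECFP6"),
                   error = function(e) NULL)
    if (is.null(fp)) stop("unparseable SMILES for fingerprinting: ", smiles)
    as.numeric(fp)
  })
  if (n_bits == 4096L) return(base)
  idx <- (seq_along(base) - 1L) %% n_bits
  as.numeric(tapply(base, idx, max)[as.character(0:(n_bits - 1L))])
}

# --- PAINS -------------------------------------------------------------

#' Load the shipped PAINS SMARTS catalog
#'
#' A pinned plain-text subset of the published pan-assay interference
#' (PAINS) substructure families, limited to patterns expressible in
#' OpenBabel SMARTS. Every pattern is validated at load time against a
#' probe molecule; an unparseable pattern aborts with the offending name.
#'
#' @return data frame with columns `name` and `smarts`.
#' @export
pains_catalog <- function() {
  if (!is.null(.pcmcp_cache[["pains_catalog"]])) {
    return(.pcmcp_cache[["pains_catalog"]])
  }
  path <- system.file("extdata", "pains_smarts.tsv", package = "pcmcp")
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  probe <- .ob_mol("CCO")
  for (i in seq_len(nrow(cat_df))) {
    ok <- tryCatch({
      suppressWarnings(ChemmineOB::smartsSearch_OB(probe, cat_df$smarts[i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("PAINS catalog integrity: pattern '", cat_df$name[i],
                  "' does not parse")
  }
  assign("pains_catalog", cat_df, envir = .pcmcp_cache)
  cat_df
}

#' Match a molecule against the PAINS catalog
#'
#' @param smiles standardized SMILES string.
#' @param enabled when `FALSE` the match is skipped and `FALSE` returned.
#' @return `TRUE` iff any catalog pattern matches.
#' @export
pains_match <- function(smiles, enabled = TRUE) {
  if (!enabled) return(FALSE)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .memo(paste0("pains|", smiles), function() {
    cat_df <- pains_catalog()
    mol <- tryCatch(.ob_mol(smiles), error = function(e) NULL)
    if (is.null(mol)) stop("unparseable SMILES: ", smiles)
    for (sm in cat_df$smarts) {
      hits <- suppressWarnings(ChemmineOB::smartsSearch_OB(mol, sm))
      if (as.numeric(hits) > 0) return(TRUE)
    }
    FALSE
  })
}

# --- generic Bemis-Murcko scaffold ------------------------------------

# Writes a SMILES string for an all-carbon, all-single-bond skeleton given
# an adjacency list; DFS with ring-closure digits.
.carbon_graph_smiles <- function(adj) {
  n <- length(adj)
  if (n == 0L) return("")
  visited <- rep(FALSE, n)
  closure_id <- 0L
  open_closures <- vector("list", n) # per-atom closure digits
  for (i in seq_len(n)) open_closures[[i]] <- integer(0)
  # find back edges via DFS, assign closure numbers
  parent <- rep(NA_integer_, n)
  order_visited <- integer(0)
  tree_children <- vector("list", n)
  for (i in seq_len(n)) tree_children[[i]] <- integer(0)
  seen_edge <- new.env(parent = emptyenv())
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_visited <- c(order_visited, v)
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        tree_children[[v]] <- c(tree_children[[v]], w)
        stack <- c(stack, w)
      } else {
        key <- paste(sort(c(v, w)), collapse = "-")
        if (w != parent[v] %||% -1L && is.null(seen_edge[[key]])) {
          assign(key, TRUE, envir = seen_edge)
          closure_id <- closure_id + 1L
          open_closures[[v]] <- c(open_closures[[v]], closure_id)
          open_closures[[w]] <- c(open_closures[[w]], closure_id)
        }
      }
    }
  }
  fmt_closure <- function(k) if (k < 10) as.character(k) else sprintf("%%%02d", k)
  emit <- function(v) {
    s <- paste0("C", paste0(vapply(open_closures[[v]], fmt_closure, ""),
                            collapse = ""))
    kids <- tree_children[[v]]
    if (length(kids) > 0L) {
      sub <- vapply(kids, emit, character(1))
      s <- paste0(s, paste0("(", sub[-length(sub)], ")", collapse = ""),
                  sub[length(sub)])
    }
    s
  }
  emit(1L)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Generic Bemis-Murcko scaffold key
#'
#' Reduces a molecule to its ring systems plus linkers (iterative removal of
#' terminal atoms), then genericizes the framework — every atom becomes
#' carbon, every bond single — and emits the canonical SMILES of that
#' skeleton. Acyclic molecules map to the reserved empty key `""`.
#'
#' @param smiles standardized SMILES string.
#' @return scaffold key (canonical SMILES of the generic framework, or `""`).
#' @export
generic_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .memo(paste0("scaf|", smiles), function() {
    g <- .mol_graph(smiles)
    if (g$n == 0L || nrow(g$bonds) == 0L) return("")
    keep <- rep(TRUE, g$n)
    repeat {
      deg <- rep(0L, g$n)
      for (k in seq_len(nrow(g$bonds))) {
        a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
        if (keep[a] && keep[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
      }
      term <- keep & deg <= 1L
      if (!any(term)) break
      keep[term] <- FALSE
      if (!any(keep)) return("")
    }
    idx <- which(keep)
    remap <- match(seq_len(g$n), idx)
    adj <- vector("list", length(idx))
    for (i in seq_along(idx)) adj[[i]] <- integer(0)
    for (k in seq_len(nrow(g$bonds))) {
      a <- remap[g$bonds$a1[k]]; b <- remap[g$bonds$a2[k]]
      if (!is.na(a) && !is.na(b)) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
    smi <- .carbon_graph_smiles(adj)
    key <- canonical_smiles(smi)
    if (is.na(key)) stop("internal: framework SMILES failed to canonicalize for ", smiles)
    key
  })
}
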