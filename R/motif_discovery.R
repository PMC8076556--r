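# Recursive V-gene-coherent motif extraction from UPGMA dendrograms,
# progressive alignment of members, rule-based regex construction, matching
# and established-motif exclusion.

#' Discover motif candidates in a dendrogram
#'
#' Walks the dendrogram from the root towards the leaves.  A node is emitted
#' as a motif candidate when its merge height does not exceed `cutoff`
#' (inclusive), all of its leaf clonotypes use the same V gene (allele
#' disregarded; the same V subgroup when `v_mode = "subgroup"`; for a paired
#' set both chains must each be coherent) and it covers at least
#' `min_leaves` clonotypes.  The search does not descend below an emitted
#' node, so the candidates of one run share no clonotypes.
#'
#' For every emitted node the member CDR3s (full, untrimmed) are aligned in
#' subtree leaf order and a per-chain anchored regular expression is built
#' with [build_regex()].
#'
#' @param tree `tcr_dendrogram` built from the matching clustering set.
#' @param set The clustering set the tree was built from
#'   ([prepare_clustering_set()]).
#' @param cutoff Levenshtein cut-off height (inclusive).
#' @param v_mode `"gene"` or `"subgroup"`.
#' @param min_leaves Minimum leaf clonotypes per candidate (default 5).
#' @return A `tcr_motifs` tibble: one row per candidate with patterns, V
#'   constraints, node height and list-columns of member ids and MSAs.
#' @export
discover_motifs <- function(tree, set, cutoff,
                            v_mode = c("gene", "subgroup"),
                            min_leaves = 5L) {
  v_mode <- match.arg(v_mode)
  stopifnot(inherits(tree, "tcr_dendrogram"))
  chain_mode <- attr(set, "chain_mode")
  if (is.null(chain_mode)) {
    chain_mode <- if (all(c("trimmed_alpha", "trimmed_beta") %in% names(set)))
      "paired" else if ("trimmed_beta" %in% names(set)) "beta" else "alpha"
  }
  idx <- match(tree$labels, set$clonotype_id)
  if (anyNA(idx)) abort("tree labels not found in the clustering set")

  vcol <- function(chain) {
    nm <- if (v_mode == "gene") paste0("v_", chain) else
      paste0("v_", chain, "_subgroup")
    set[[nm]][idx]
  }
  v_alpha <- if (chain_mode != "beta") vcol("alpha")
  v_beta <- if (chain_mode != "alpha") vcol("beta")
  coherent <- function(leaves) {
    okb <- is.null(v_beta) || length(unique(v_beta[leaves])) == 1L
    oka <- is.null(v_alpha) || length(unique(v_alpha[leaves])) == 1L
    okb && oka
  }

  sets <- dendro_leaf_sets(tree$merge)
  emitted <- list()
  stack <- nrow(tree$merge)                # root node
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0L) next                    # single leaves cannot qualify
    leaves <- sets[[node]]
    if (tree$height[node] <= cutoff && length(leaves) >= min_leaves &&
        coherent(leaves)) {
      emitted[[length(emitted) + 1L]] <- node
    } else {
      stack <- c(stack, tree$merge[node, 1L], tree$merge[node, 2L])
    }
  }

  rows <- purrr::map(emitted, function(node) {
    leaves <- dendro_subtree_order(tree$merge, node)
    ids <- tree$labels[leaves]
    r <- list(chain_mode = chain_mode, node = node,
              node_height = tree$height[node], n_members = length(ids),
              v_match = v_mode, members = list(ids))
    if (chain_mode != "alpha") {
      msa <- align_members(set$cdr3_beta[idx[leaves]])
      r$v_beta <- unique(v_beta[leaves])
      r$pattern_beta <- build_regex(msa)
      r$msa_beta <- list(msa)
    }
    if (chain_mode != "beta") {
      msa <- align_members(set$cdr3_alpha[idx[leaves]])
      r$v_alpha <- unique(v_alpha[leaves])
      r$pattern_alpha <- build_regex(msa)
      r$msa_alpha <- list(msa)
    }
    r
  })
  out <- if (length(rows) == 0L) motif_prototype(chain_mode) else
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (nrow(out) > 0L) {
    out <- arrange(out, dplyr::desc(.data$n_members), .data$node_height)
    out$motif_id <- sprintf("%s_%s_%g_M%03d",
                            toupper(substr(chain_mode, 1, 1)), v_mode,
                            cutoff, seq_len(nrow(out)))
    out <- select(out, "motif_id", dplyr::everything())
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- c("tcr_motifs", class(out))
  out
}

# leaves of a subtree in left-to-right dendrogram order
dendro_subtree_order <- function(merge, node) {
  stack <- node
  out <- integer(0)
  while (length(stack) > 0L) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (k < 0L) out <- c(out, -k) else
      stack <- c(stack, merge[k, 2L], merge[k, 1L])
  }
  out
}

motif_prototype <- function(chain_mode) {
  out <- tibble::tibble(motif_id = character(), chain_mode = character(),
                        node = integer(), node_height = numeric(),
                        n_members = integer(), v_match = character(),
                        members = list())
  if (chain_mode != "alpha") {
    out$v_beta <- character()
    out$pattern_beta <- character()
    out$msa_beta <- list()
  }
  if (chain_mode != "beta") {
    out$v_alpha <- character()
    out$pattern_alpha <- character()
    out$msa_alpha <- list()
  }
  out
}

#' Progressive multiple alignment of motif members
#'
#' Aligns near-identical CDR3s progressively in the given order: each
#' sequence is aligned to the running profile by dynamic programming with
#' identity scoring (match 1, mismatch 0, gap -1); profile columns score a
#' new residue by its mean identity to the column.  Removing the gaps from
#' row *i* recovers input *i*.
#'
#' @param seqs Character vector (at least one sequence; two or more for a
#'   meaningful alignment).
#' @return Character vector of equal-length aligned rows (`-` gaps).
#' @export
#' @examples
#' align_members(c("SIRATDTQ", "SIRTDTQ"))
align_members <- function(seqs) {
  if (length(seqs) == 0L) {
    abort("align_members() needs at least one sequence",
          class = "tcrmotifs_degenerate_input")
  }
  prof <- matrix(strsplit(seqs[1L], "")[[1]], nrow = 1L)
  for (s in seqs[-1L]) prof <- align_to_profile(prof, strsplit(s, "")[[1]])
  apply(prof, 1L, paste, collapse = "")
}

# Needleman-Wunsch of one sequence against a character-matrix profile
align_to_profile <- function(prof, s) {
  gap <- -1
  nc <- ncol(prof)
  ns <- length(s)
  # column score: mean identity of s-char to profile column (gaps score 0);
  # tabulated once so the DP only does lookups
  chars <- unique(s)
  ci <- match(s, chars)
  freq <- vapply(seq_len(nc), function(j) {
    tabulate(match(prof[, j], chars), nbins = length(chars)) / nrow(prof)
  }, numeric(length(chars)))
  freq <- matrix(freq, nrow = length(chars))   # share of char in column
  colscore <- function(j, k) freq[ci[k], j]
  M <- matrix(0, nc + 1L, ns + 1L)
  M[, 1L] <- gap * (0:nc)
  M[1L, ] <- gap * (0:ns)
  tb <- matrix(0L, nc + 1L, ns + 1L)  # 1 diag, 2 up (gap in seq), 3 left
  tb[, 1L] <- 2L
  tb[1L, ] <- 3L
  tb[1L, 1L] <- 0L
  for (i in seq_len(nc)) {
    for (j in seq_len(ns)) {
      d <- M[i, j] + colscore(i, j)
      u <- M[i, j + 1L] + gap
      l <- M[i + 1L, j] + gap
      best <- max(d, u, l)
      M[i + 1L, j + 1L] <- best
      tb[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  # traceback
  cols <- list()
  i <- nc + 1L
  j <- ns + 1L
  while (i > 1L || j > 1L) {
    mv <- tb[i, j]
    if (mv == 1L) {
      cols[[length(cols) + 1L]] <- c(prof[, i - 1L], s[j - 1L])
      i <- i - 1L
      j <- j - 1L
    } else if (mv == 2L) {
      cols[[length(cols) + 1L]] <- c(prof[, i - 1L], "-")
      i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(rep("-", nrow(prof)), s[j - 1L])
      j <- j - 1L
    }
  }
  do.call(cbind, rev(cols))
}

#' Build an anchored regular expression from an MSA
#'
#' Column rules: identical non-gap residues give the literal character;
#' distinct residues jointly contained in one amino-acid group (see
#' [amino_acid_groups()]) give the full character class of that group, e.g.
#' `[KRED]`; residues spanning more than one group give the unrestricted
#' wildcard `.`; any gap in a column makes the column's token optional
#' (`?`).  When residues fit several of the overlapping groups the fixed
#' priority charged > polar > amphipathic > hydrophobic decides.  The
#' pattern is matched anchored at both ends (see [match_motif()]).
#'
#' @param msa Character vector of equal-length aligned rows.
#' @return Regular-expression string (unanchored; anchoring is applied at
#'   match time).
#' @export
#' @examples
#' build_regex(c("ARDT", "AKDT"))
build_regex <- function(msa) {
  stopifnot(length(unique(nchar(msa))) == 1L)
  grp <- amino_acid_groups()
  mat <- do.call(rbind, strsplit(msa, ""))
  tokens <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- unique(col[col != "-"])
    if (length(res) == 0L) return("")
    tok <- if (length(res) == 1L) {
      res
    } else {
      hit <- NULL
      for (g in names(grp)) {
        if (all(res %in% grp[[g]])) {
          hit <- g
          break
        }
      }
      if (is.null(hit)) "." else paste0("[", paste(grp[[hit]], collapse = ""),
                                        "]")
    }
    if (any(col == "-")) paste0(tok, "?") else tok
  }, "")
  paste(tokens, collapse = "")
}

#' Match a motif against clonotypes or chain records
#'
#' A subject matches a single-chain motif when its full (untrimmed) CDR3
#' matches the anchored pattern and its V gene satisfies the motif's V
#' constraint (V subgroup for subgroup-mode candidates; either alpha of a
#' dual-alpha subject may satisfy the alpha side).  Paired motifs require
#' both chains to match.  A motif side with a V constraint but no pattern
#' (the paired R-motif's alpha side) tests the V constraint alone.  J-gene
#' constraints carried by established motifs are stored but only enforced
#' with `enforce_j = TRUE`.
#'
#' @param motif One-row motif (a `tcr_motifs` row or a row of
#'   [established_motifs()]).
#' @param subjects Clonotype tibble ([define_clonotypes()]) or any table
#'   with the same chain columns.
#' @param enforce_j Also require J-gene identity (default `FALSE`).
#' @return Logical vector, one element per subject row.
#' @export
match_motif <- function(motif, subjects, enforce_j = FALSE) {
  motif <- as.list(motif[1, , drop = FALSE])
  motif <- lapply(motif, function(x) if (is.list(x)) x[[1]] else x)
  v_match <- motif$v_match %||% "gene"

  side <- function(pattern, v_constraint, j_constraint, cdr3, v, v_sub, j) {
    ok <- rep(TRUE, length(cdr3))
    if (!is.null(pattern) && !is.na(pattern)) {
      ok <- ok & !is.na(cdr3) &
        grepl(paste0("^", pattern, "$"), cdr3)
    }
    if (!is.null(v_constraint) && !is.na(v_constraint)) {
      allowed <- stringr::str_trim(strsplit(v_constraint, ",")[[1]])
      vv <- if (identical(v_match, "subgroup")) v_sub else v
      ok <- ok & !is.na(vv) & vv %in% allowed
    }
    if (enforce_j && !is.null(j_constraint) && !is.na(j_constraint)) {
      allowed <- stringr::str_trim(strsplit(j_constraint, ",")[[1]])
      ok <- ok & !is.na(j) & j %in% allowed
    }
    ok
  }

  chain <- motif$chain_mode %||% motif$chain
  n <- nrow(subjects)
  ok_beta <- rep(TRUE, n)
  ok_alpha <- rep(TRUE, n)
  if (chain %in% c("beta", "paired")) {
    ok_beta <- side(motif$pattern_beta, motif$v_beta, motif$j_beta,
                    subjects$cdr3_aa_beta, subjects$v_beta,
                    subjects$v_beta_subgroup, subjects$j_beta)
  }
  if (chain %in% c("alpha", "paired")) {
    a1 <- side(motif$pattern_alpha, motif$v_alpha, motif$j_alpha,
               subjects$cdr3_aa_alpha, subjects$v_alpha,
               subjects$v_alpha_subgroup, subjects$j_alpha)
    ok_alpha <- a1
    if ("cdr3_aa_alpha2" %in% names(subjects)) {
      a2 <- side(motif$pattern_alpha, motif$v_alpha, motif$j_alpha,
                 subjects$cdr3_aa_alpha2, subjects$v_alpha2,
                 subjects$v_alpha2_subgroup, subjects$j_alpha2)
      a2[is.na(subjects$cdr3_aa_alpha2)] <- FALSE
      ok_alpha <- a1 | a2
    }
  }
  switch(chain, beta = ok_beta, alpha = ok_alpha, paired = ok_beta & ok_alpha)
}

#' Established celiac-disease CDR3 motifs
#'
#' The package ships the canonical celiac-relevant motif library (R-motif,
#' extended R-motif, NDYKLS and the paired R-motif) as plain-text data.
#' Patterns use regular-expression syntax where `.` is any single character
#' and `.*` any characters including none; V constraints list the allowed
#' genes comma-separated.
#'
#' @return Tibble with one row per motif.
#' @export
established_motifs <- function() {
  path <- system.file("extdata", "established_motifs.tsv",
                      package = "tcrmotifs", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE) %>%
    mutate(v_match = "gene")
}

#' Remove candidates matching established motifs
#'
#' A candidate is removed when at least `overlap_threshold` of its member
#' clonotypes match any established motif (pattern plus V constraint, on the
#' established motif's chain).  Removed candidates and the motif responsible
#' are recorded in the `"excluded"` attribute of the result.
#'
#' @param motifs `tcr_motifs` table from [discover_motifs()].
#' @param clonotypes Clonotype tibble carrying the members.
#' @param established Established-motif table (default
#'   [established_motifs()]).
#' @param overlap_threshold Member fraction triggering removal (default 0.5).
#' @return Filtered `tcr_motifs` with an `"excluded"` attribute.
#' @export
exclude_established <- function(motifs, clonotypes,
                                established = established_motifs(),
                                overlap_threshold = 0.5) {
  if (nrow(motifs) == 0L) {
    attr(motifs, "excluded") <- tibble::tibble(motif_id = character(),
                                               excluded_by = character(),
                                               overlap = numeric())
    return(motifs)
  }
  log <- list()
  drop <- rep(FALSE, nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    members <- dplyr::filter(clonotypes,
                             .data$clonotype_id %in% motifs$members[[i]])
    for (k in seq_len(nrow(established))) {
      frac <- mean(match_motif(established[k, ], members))
      if (frac >= overlap_threshold) {
        drop[i] <- TRUE
        log[[length(log) + 1L]] <- tibble::tibble(
          motif_id = motifs$motif_id[i],
          excluded_by = established$name[k], overlap = frac)
        break
      }
    }
  }
  out <- motifs[!drop, , drop = FALSE]
  attr(out, "cutoff") <- attr(motifs, "cutoff")
  attr(out, "excluded") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(motif_id = character(), excluded_by = character(),
                   overlap = numeric())
  class(out) <- class(motifs)
  out
}

#' Motif frequency in a clonotype set
#'
#' @param motifs Motif table (`tcr_motifs` or [established_motifs()] rows).
#' @param clonotypes Clonotype tibble.
#' @return Tibble (`motif`, `count`, `fraction`): clonotypes with at least
#'   one matching chain or pair, and the fraction of the set.
#' @export
motif_frequency <- function(motifs, clonotypes) {
  if (nrow(clonotypes) == 0L) {
    abort("motif_frequency() needs a non-empty clonotype set",
          class = "tcrmotifs_degenerate_input")
  }
  name_col <- if ("motif_id" %in% names(motifs)) "motif_id" else "name"
  purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    hits <- match_motif(motifs[i, ], clonotypes)
    tibble::tibble(motif = motifs[[name_col]][i], count = sum(hits),
                   fraction = sum(hits) / nrow(clonotypes))
  })
}

#' Text sequence logo of a motif alignment
#'
#' Per-column residue counts of an MSA rendered as plain text, one line per
#' observed residue, most frequent first.
#'
#' @param msa Character vector of aligned rows.
#' @return Character vector of lines (also printed with `cat()` when
#'   interactive use is intended).
#' @export
text_logo <- function(msa) {
  mat <- do.call(rbind, strsplit(msa, ""))
  lines <- vapply(seq_len(ncol(mat)), function(j) {
    tb <- sort(table(mat[, j]), decreasing = TRUE)
    paste0(sprintf("%2d ", j),
           paste(sprintf("%s:%d", names(tb), as.integer(tb)),
                 collapse = " "))
  }, "")
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
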