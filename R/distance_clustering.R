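# Levenshtein distance matrices and unweighted average-linkage (UPGMA)
# dendrograms.

#' Levenshtein edit distance
#'
#' Minimal number of single-character substitutions, insertions and deletions
#' (unit costs) converting `a` into `b`, computed element-wise over the
#' longer of the two vectors (the shorter is recycled).
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("SIRATDTQ", "SLRSTDTQ")
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- adist(a[i], b[i])[1, 1]
  out
}

#' Pairwise CDR3 distance matrix
#'
#' For a single-chain clustering set the distance is the Levenshtein distance
#' between trimmed CDR3s; for a paired set it is the sum of the alpha and
#' beta Levenshtein distances (a metric, being a sum of metrics).
#'
#' @param set Clustering set from [prepare_clustering_set()], or a character
#'   vector of sequences.
#' @return A `tcr_dist` object: ids, dense symmetric matrix and metric name.
#' @export
cdr3_distances <- function(set) {
  if (is.character(set)) {
    if (length(set) < 2L) {
      abort("need at least two sequences to build a distance matrix",
            class = "tcrmotifs_degenerate_input")
    }
    ids <- names(set)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_along(set))
    d <- levenshtein_matrix(unname(set))
    return(new_tcr_dist(ids, d, "levenshtein"))
  }
  mode <- attr(set, "chain_mode")
  if (is.null(mode)) {
    mode <- if (all(c("trimmed_alpha", "trimmed_beta") %in% names(set)))
      "paired" else if ("trimmed_beta" %in% names(set)) "beta" else "alpha"
  }
  if (nrow(set) < 2L) {
    abort("need at least two sequences to build a distance matrix",
          class = "tcrmotifs_degenerate_input")
  }
  d <- switch(mode,
    beta   = levenshtein_matrix(set$trimmed_beta),
    alpha  = levenshtein_matrix(set$trimmed_alpha),
    paired = levenshtein_matrix(set$trimmed_alpha) +
      levenshtein_matrix(set$trimmed_beta)
  )
  metric <- if (mode == "paired") "paired_sum" else "levenshtein"
  new_tcr_dist(set$clonotype_id, d, metric)
}

new_tcr_dist <- function(ids, d, metric) {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, metric = metric), class = "tcr_dist")
}

#' @export
print.tcr_dist <- function(x, ...) {
  cat(sprintf("<tcr_dist> %d items, metric = %s\n", length(x$ids), x$metric))
  invisible(x)
}

#' @export
as.dist.tcr_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' UPGMA hierarchical clustering
#'
#' Unweighted average linkage: at each step the pair of clusters with the
#' minimal average inter-cluster distance is merged, the merge height being
#' that average.  Averages are computed from exact sums of the original
#' distances, so for integer (Levenshtein) inputs heights are exact and the
#' tree is invariant under input permutation up to leaf relabeling.  Ties
#' are broken deterministically in favour of the candidate pair whose
#' clusters contain the smallest leaf indices (smallest `(min id, max id)`).
#'
#' @param x A `tcr_dist` object, a `dist`, or a square numeric matrix.
#' @return A `tcr_dendrogram`: hclust-style `merge` matrix (negative entries
#'   are leaves), `height` vector and `labels`.
#' @export
upgma <- function(x) {
  if (inherits(x, "tcr_dist")) {
    m <- x$d
    labels <- x$ids
  } else if (inherits(x, "dist")) {
    m <- as.matrix(x)
    labels <- attr(x, "Labels")
  } else {
    m <- as.matrix(x)
    labels <- rownames(m)
  }
  n <- nrow(m)
  if (is.null(labels)) labels <- sprintf("L%04d", seq_len(n))
  if (n < 2L) {
    abort("upgma() needs at least two items",
          class = "tcrmotifs_degenerate_input")
  }
  if (!all(is.finite(m))) {
    abort("distance matrix contains non-finite values",
          class = "tcrmotifs_validation_error")
  }
  # tie-breaks follow label order so the tree is invariant under input
  # permutation (up to relabeling) even when averages tie
  leaf_rank <- rank(labels, ties.method = "first")
  eng <- upgma_engine(m, as.integer(leaf_rank))
  structure(list(merge = eng$merge, height = as.numeric(eng$height),
                 labels = labels, method = "upgma"),
            class = "tcr_dendrogram")
}

#' @export
print.tcr_dendrogram <- function(x, ...) {
  cat(sprintf("<tcr_dendrogram> %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.tcr_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendro_leaf_order(x$merge),
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "levenshtein"),
            class = "hclust")
}

# left-to-right leaf order of an hclust-style merge matrix (iterative DFS)
dendro_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- nrow(merge)
  out <- integer(0)
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0L) {
      out <- c(out, -node)
    } else {
      # push right child first so the left child is visited first
      stack <- c(stack, merge[node, 2L], merge[node, 1L])
    }
  }
  out
}

# leaf index sets under every internal node, bottom-up
dendro_leaf_sets <- function(merge) {
  k <- nrow(merge)
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    l <- merge[i, 1L]
    r <- merge[i, 2L]
    sets[[i]] <- c(if (l < 0L) -l else sets[[l]],
                   if (r < 0L) -r else sets[[r]])
  }
  sets
}

#' Cut a dendrogram at a height
#'
#' Clusters are the maximal subtrees whose merge height does not exceed the
#' cut height; singletons are allowed and the clusters partition the leaves.
#' Because UPGMA heights are monotone, partitions are nested: cutting lower
#' refines cutting higher.
#'
#' @param tree A `tcr_dendrogram`.
#' @param height Non-negative cut height; membership uses `<=` with no
#'   tolerance (inputs are integer distances and exact averages thereof).
#' @return Tibble (`id`, `cluster`); clusters numbered by first appearance
#'   in label order.
#' @export
cut_tree <- function(tree, height) {
  stopifnot(inherits(tree, "tcr_dendrogram"), height >= 0)
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sets <- dendro_leaf_sets(tree$merge)
  for (k in seq_along(tree$height)) {
    if (tree$height[k] <= height) {
      members <- sets[[k]]
      r <- find(members[1L])
      for (m in members[-1L]) parent[find(m)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  cluster <- match(roots, unique(roots))
  tibble::tibble(id = tree$labels, cluster = cluster)
}

#' Serialize a dendrogram to Newick
#'
#' Converts the tree to `hclust`/`phylo` form and writes Newick text with
#' ape's ultrametric branch-length convention (node depths are half the
#' merge heights).
#'
#' @param tree A `tcr_dendrogram`.
#' @param file Optional path; when omitted the Newick string is returned.
#' @return Newick string, invisibly when written to file.
#' @export
to_newick <- function(tree, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("to_newick() requires the 'ape' package")
  }
  phy <- ape::as.phylo(as.hclust(tree))
  txt <- ape::write.tree(phy, file = "")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
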