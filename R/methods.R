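# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
print.tcr_motifs <- function(x, ...) {
  cat(sprintf("<tcr_motifs> %d candidate(s)", nrow(x)))
  co <- attr(x, "cutoff")
  if (!is.null(co)) cat(sprintf(" at cut-off %g", co))
  cat("\n")
  if (nrow(x) > 0L) print(tidy(x), ...)
  invisible(x)
}

#' Tidy a motif candidate table
#'
#' Drops the list-columns (members, alignments) and returns one flat row per
#' candidate: identifier, chain mode, anchored patterns, V constraints, node
#' height and member count.
#'
#' @param x A `tcr_motifs` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.tcr_motifs <- function(x, ...) {
  keep <- !vapply(x, is.list, TRUE)
  out <- tibble::as_tibble(unclass(x)[keep])
  out
}

#' Summarise a motif discovery run
#'
#' @param x A `tcr_motifs` object.
#' @param ... Unused.
#' @return One-row tibble: number of candidates, clonotypes covered, largest
#'   candidate and cut-off used.
#' @export
glance.tcr_motifs <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 n_clonotypes_covered = length(unique(unlist(x$members))),
                 largest = if (nrow(x)) max(x$n_members) else 0L,
                 cutoff = attr(x, "cutoff") %||% NA_real_)
}

#' Tidy a dendrogram into its merge table
#'
#' @param x A `tcr_dendrogram`.
#' @param ... Unused.
#' @return Tibble with one row per merge (`step`, `left`, `right`,
#'   `height`, `n_leaves`).
#' @export
tidy.tcr_dendrogram <- function(x, ...) {
  sets <- dendro_leaf_sets(x$merge)
  tibble::tibble(step = seq_along(x$height),
                 left = x$merge[, 1L], right = x$merge[, 2L],
                 height = x$height,
                 n_leaves = vapply(sets, length, 1L))
}

#' @export
glance.tcr_dendrogram <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), root_height = max(x$height))
}

#' Plot the cluster-size profile of a dendrogram cut
#'
#' Bar chart of cluster sizes (largest first) at a given cut height, the
#' standard way to show how dominant the largest CDR3 cluster is.
#'
#' @param object A `tcr_dendrogram`.
#' @param height Cut height.
#' @param min_size Hide clusters smaller than this (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_dendrogram <- function(object, height, min_size = 2L, ...) {
  cl <- cut_tree(object, height) %>%
    count(.data$cluster, name = "size") %>%
    filter(.data$size >= min_size) %>%
    arrange(dplyr::desc(.data$size)) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (by size)", y = "clonotypes",
                  title = sprintf("clusters at cut height %g", height)) +
    ggplot2::theme_minimal()
}

#' Plot motif candidate sizes
#'
#' @param object A `tcr_motifs` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_motifs <- function(object, ...) {
  if (nrow(object) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no motif candidates"))
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$motif_id, .data$n_members),
    y = .data$n_members)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "member clonotypes") +
    ggplot2::theme_minimal()
}

#' Plot V-gene usage frequencies
#'
#' @param usage Output of [vgene_usage()].
#' @param top Show at most this many genes (default 25).
#' @return A ggplot object.
#' @export
plot_vgene_usage <- function(usage, top = 25L) {
  df <- head(usage, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$freq), y = .data$freq)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = NULL, y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot per-patient public sharing
#'
#' Scatter of the fraction of a patient's clonotypes involving public
#' chains against the patient's clonotype count, with the cohort median.
#'
#' @param shared Output of [shared_fraction_per_patient()].
#' @return A ggplot object.
#' @export
plot_shared_fractions <- function(shared) {
  med <- attr(shared, "median")
  ggplot2::ggplot(shared, ggplot2::aes(x = .data$n_clonotypes,
                                       y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = med, linetype = "dashed") +
    ggplot2::labs(x = "clonotypes in patient",
                  y = "fraction with public chain",
                  subtitle = sprintf("median %.2f", med)) +
    ggplot2::theme_minimal()
}
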