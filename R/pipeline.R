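# End-to-end orchestration: ingestion -> filtering -> clonotypes ->
# clustering -> motif discovery -> repertoire statistics, with a TSV/JSON
# report bundle and a run manifest.

#' Run the full repertoire analysis
#'
#' Executes the pipeline stages in order and (optionally) writes a report
#' bundle: the clonotype table, cluster assignments per chain mode and
#' cut-off, motif candidate tables per (mode, cut-off, V mode) with
#' established-motif exclusion, established-motif frequencies, public
#' sequence records and per-patient shared fractions, V-usage tables,
#' epitope annotations and a public-vs-private generation-probability
#' comparison, plus a JSON manifest with the configuration and per-stage row
#' counts.  Patients below `min_clonotypes_for_clustering` clonotypes are
#' excluded from clustering and motif discovery but retained in the public
#' sharing analysis.  Fully deterministic given `seed`.
#'
#' @param rearrangements Rearrangement table (tibble or TSV path).
#' @param reference_clones Optional reference clone table (tibble or path)
#'   for epitope annotation.
#' @param irgp Optional surrogate generation-probability table (tibble or
#'   path) keyed by patient and beta chain
#'   (`patient_id`,`v_beta`,`j_beta`,`cdr3_nt_beta`,`p_alpha`,`p_beta`).
#' @param out_dir Optional output directory for the report bundle.
#' @param dialect Input dialect ([rearrangement_dialect()]).
#' @param min_reads,dual_min_fraction Chain filter parameters.
#' @param min_trimmed_len Minimum trimmed CDR3 length for clustering.
#' @param min_clonotypes_for_clustering Patient inclusion threshold
#'   (default 20).
#' @param cutoffs Named list of cut-off vectors per run:
#'   `alpha`, `beta`, `paired` (gene-coherent) and `paired_subgroup`.
#' @param min_leaves Minimum candidate size (default 5).
#' @param seed Seed for the dual-alpha selection.
#' @return A `tcr_pipeline` list of all stage artifacts (invisibly writes
#'   the bundle when `out_dir` is given).
#' @export
run_pipeline <- function(rearrangements, reference_clones = NULL,
                         irgp = NULL, out_dir = NULL,
                         dialect = rearrangement_dialect(),
                         min_reads = 50, dual_min_fraction = 0.10,
                         min_trimmed_len = 8L,
                         min_clonotypes_for_clustering = 20L,
                         cutoffs = list(alpha = c(1, 2), beta = c(1, 2),
                                        paired = c(2, 4),
                                        paired_subgroup = 8),
                         min_leaves = 5L, seed = 1L) {
  read_maybe <- function(x) {
    if (is.null(x) || is.data.frame(x)) return(x)
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  records <- read_rearrangements(read_maybe(rearrangements), dialect)
  rejects <- rearrangement_rejects(records)
  chains <- filter_chains(records, min_reads, dual_min_fraction)
  cells <- call_valid_cells(chains)
  clonotypes <- define_clonotypes(chains, cells)

  keep_patients <- clonotypes %>%
    count(.data$patient_id) %>%
    filter(.data$n >= min_clonotypes_for_clustering) %>%
    pull(.data$patient_id)
  cluster_ct <- dplyr::filter(clonotypes, .data$patient_id %in% keep_patients)

  runs <- list()
  clusters <- list()
  trees <- list()
  for (mode in c("alpha", "beta", "paired")) {
    set <- prepare_clustering_set(cluster_ct, mode,
                                  min_trimmed_len = min_trimmed_len,
                                  seed = seed)
    if (nrow(set) < 2L) next
    tree <- upgma(cdr3_distances(set))
    trees[[mode]] <- tree
    v_runs <- if (mode == "paired") {
      c(lapply(cutoffs$paired, function(co) list(cutoff = co,
                                                 v_mode = "gene")),
        lapply(cutoffs$paired_subgroup,
               function(co) list(cutoff = co, v_mode = "subgroup")))
    } else {
      lapply(cutoffs[[mode]], function(co) list(cutoff = co,
                                                v_mode = "gene"))
    }
    for (vr in v_runs) {
      cand <- discover_motifs(tree, set, vr$cutoff, vr$v_mode, min_leaves)
      kept <- exclude_established(cand, cluster_ct)
      tag <- sprintf("%s_cut%g_%s", mode, vr$cutoff, vr$v_mode)
      runs[[tag]] <- list(mode = mode, cutoff = vr$cutoff,
                          v_mode = vr$v_mode, candidates = cand,
                          kept = kept)
      clusters[[tag]] <- cut_tree(tree, vr$cutoff)
    }
  }

  established_freq <- if (nrow(cluster_ct) > 0L) {
    motif_frequency(established_motifs(), cluster_ct)
  }

  public <- dplyr::bind_rows(find_public_sequences(clonotypes, "alpha"),
                             find_public_sequences(clonotypes, "beta"))
  public_paired <- find_public_sequences(clonotypes, "paired")
  shared <- shared_fraction_per_patient(clonotypes, public,
                                        bins = c(0, 100, 200))

  usage <- list(TRAV = vgene_usage(clonotypes, "TRAV"),
                TRBV = vgene_usage(clonotypes, "TRBV"),
                paired = vgene_usage(clonotypes, "paired"))

  reference_clones <- read_maybe(reference_clones)
  epitopes <- NULL
  if (!is.null(reference_clones)) {
    ann <- purrr::imap(runs, function(run, tag) {
      a <- annotate_epitopes(run$kept, reference_clones)
      if (nrow(a) > 0L) dplyr::mutate(a, run = tag)
    })
    pub_pa <- dplyr::filter(public_paired, .data$public)
    ann$public <- if (nrow(pub_pa) > 0L) {
      a <- annotate_epitopes(pub_pa, reference_clones)
      if (nrow(a) > 0L) dplyr::mutate(a, run = "public_paired")
    }
    epitopes <- dplyr::bind_rows(ann)
  }

  irgp <- read_maybe(irgp)
  irgp_comparison <- NULL
  if (!is.null(irgp)) {
    joined <- clonotypes %>%
      left_join(irgp, by = c("patient_id", "v_beta", "j_beta",
                             "cdr3_nt_beta")) %>%
      filter(!is.na(.data$p_alpha), !is.na(.data$p_beta)) %>%
      mutate(p_paired = paired_generation_probability(.data$p_alpha,
                                                      .data$p_beta))
    pub_ids <- list(
      alpha = unique(unlist(public$clonotype_ids[public$public &
                                                   public$mode == "alpha"])),
      beta = unique(unlist(public$clonotype_ids[public$public &
                                                  public$mode == "beta"])),
      paired = unique(unlist(
        public_paired$clonotype_ids[public_paired$public])))
    cmp_one <- function(values, ids, label) {
      is_pub <- joined$clonotype_id %in% ids
      if (sum(is_pub) == 0L || sum(!is_pub) == 0L) return(NULL)
      compare_public_private(values[is_pub], values[!is_pub]) %>%
        mutate(sample = label,
               mean_public = mean(values[is_pub]),
               mean_private = mean(values[!is_pub]))
    }
    irgp_comparison <- dplyr::bind_rows(
      cmp_one(joined$p_alpha, pub_ids$alpha, "TCRa"),
      cmp_one(joined$p_beta, pub_ids$beta, "TCRb"),
      cmp_one(joined$p_paired, pub_ids$paired, "paired"))
  }

  manifest <- list(
    parameters = list(min_reads = min_reads,
                      dual_min_fraction = dual_min_fraction,
                      min_trimmed_len = min_trimmed_len,
                      min_clonotypes_for_clustering =
                        min_clonotypes_for_clustering,
                      cutoffs = cutoffs, min_leaves = min_leaves,
                      seed = seed),
    counts = list(
      input_rows = nrow(records) + nrow(rejects),
      rejected_rows = nrow(rejects),
      chain_records = nrow(records),
      chains_after_filter = nrow(chains),
      cells = nrow(cells), valid_cells = sum(cells$valid),
      chains_in_valid_cells =
        sum(chains$cell_id %in% cells$cell_id[cells$valid]),
      clonotypes = nrow(clonotypes),
      patients = dplyr::n_distinct(clonotypes$patient_id),
      clustering_patients = length(keep_patients),
      clustering_clonotypes = nrow(cluster_ct),
      motif_candidates = vapply(runs, function(r) nrow(r$candidates), 0L),
      motif_candidates_kept = vapply(runs, function(r) nrow(r$kept), 0L),
      public_records = sum(public$public),
      public_paired_records = sum(public_paired$public)))

  out <- structure(list(records = records, rejects = rejects,
                        chains = chains, cells = cells,
                        clonotypes = clonotypes,
                        clustering_clonotypes = cluster_ct, trees = trees,
                        clusters = clusters, motif_runs = runs,
                        established_frequencies = established_freq,
                        public = public, public_paired = public_paired,
                        shared_fractions = shared, vgene_usage = usage,
                        epitopes = epitopes,
                        irgp_comparison = irgp_comparison,
                        manifest = manifest),
                   class = "tcr_pipeline")
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir)
  out
}

#' @export
print.tcr_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<tcr_pipeline>\n")
  cat(sprintf("  %d chain records -> %d valid cells -> %d clonotypes (%d patients)\n",
              cnt$chain_records, cnt$valid_cells, cnt$clonotypes,
              cnt$patients))
  cat(sprintf("  clustering: %d clonotypes from %d patients\n",
              cnt$clustering_clonotypes, cnt$clustering_patients))
  cat(sprintf("  motif runs: %d; public records: %d (+%d paired)\n",
              length(x$motif_runs), cnt$public_records,
              cnt$public_paired_records))
  invisible(x)
}

# serialise every report table; list-columns are flattened to
# comma-separated strings so the bundle is plain TSV
flatten_lists <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) {
        paste(unlist(x), collapse = ",")
      }, "")
    }
  }
  df
}

write_pipeline_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L && is.null(names(df))) return()
    readr::write_tsv(flatten_lists(tibble::as_tibble(df)),
                     file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  w(x$clonotypes, "clonotypes")
  w(x$rejects, "rejected_rows")
  for (tag in names(x$clusters)) w(x$clusters[[tag]],
                                   paste0("clusters_", tag))
  for (tag in names(x$motif_runs)) {
    run <- x$motif_runs[[tag]]
    drop_msa <- function(df) {
      df[, !grepl("^msa_", names(df)), drop = FALSE]
    }
    w(drop_msa(run$candidates), paste0("motifs_", tag))
    w(drop_msa(run$kept), paste0("motifs_kept_", tag))
  }
  w(x$established_frequencies, "established_motif_frequencies")
  w(x$public, "public_records")
  w(x$public_paired, "public_paired_records")
  w(x$shared_fractions, "shared_fractions")
  w(x$vgene_usage$TRAV, "vusage_trav")
  w(x$vgene_usage$TRBV, "vusage_trbv")
  w(x$vgene_usage$paired, "vusage_paired")
  if (!is.null(x$epitopes)) w(x$epitopes, "epitope_annotations")
  if (!is.null(x$irgp_comparison)) w(x$irgp_comparison, "irgp_comparison")
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
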