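# V-gene usage, public/private sharing, epitope annotation, external
# database searches and generation-probability comparison.

#' V-gene usage frequencies
#'
#' Counts gene (or gene-pair) usage over clonotypes.  Chains with ambiguous
#' V calls are excluded; dual-alpha clonotypes contribute 0.5 to each
#' alternative gene (or gene pair), so the included mass always sums to 1.
#' With `collapse_min` set, genes observed in fewer clonotypes are pooled
#' into `"other"` (a reporting device only).
#'
#' @param clonotypes Clonotype tibble.
#' @param mode `"TRAV"`, `"TRBV"` or `"paired"`.
#' @param collapse_min Optional minimum number of contributing clonotypes
#'   before a gene is reported on its own (the field convention is 2).
#' @return Tibble (`gene`, `weight`, `n_clonotypes`, `freq`) sorted by
#'   decreasing frequency.
#' @export
vgene_usage <- function(clonotypes, mode = c("TRAV", "TRBV", "paired"),
                        collapse_min = NULL) {
  mode <- match.arg(mode)
  if (nrow(clonotypes) == 0L) {
    abort("vgene_usage() needs a non-empty clonotype set",
          class = "tcrmotifs_degenerate_input")
  }
  x <- clonotypes
  alpha_rows <- function(gene_fun) {
    w1 <- ifelse(x$dual_alpha, 0.5, 1)
    r1 <- tibble::tibble(clonotype_id = x$clonotype_id,
                         gene = gene_fun(x$v_alpha, x$v_beta), weight = w1,
                         ambiguous = x$v_alpha_ambiguous)
    r2 <- tibble::tibble(clonotype_id = x$clonotype_id,
                         gene = gene_fun(x$v_alpha2, x$v_beta), weight = 0.5,
                         ambiguous = x$v_alpha2_ambiguous)[x$dual_alpha, ]
    dplyr::bind_rows(r1, r2)
  }
  rows <- switch(mode,
    TRBV = tibble::tibble(clonotype_id = x$clonotype_id, gene = x$v_beta,
                          weight = 1, ambiguous = x$v_beta_ambiguous),
    TRAV = alpha_rows(function(a, b) a),
    paired = alpha_rows(function(a, b) paste0(a, ":", b)))
  if (mode == "paired") {
    # a pair is ambiguous when either of its chains is
    amb_beta <- setNames(x$v_beta_ambiguous, x$clonotype_id)
    rows$ambiguous <- rows$ambiguous | unname(amb_beta[rows$clonotype_id])
  }
  rows <- dplyr::filter(rows, !is.na(.data$gene), !.data$ambiguous)
  out <- rows %>%
    group_by(.data$gene) %>%
    summarise(weight = sum(.data$weight),
              n_clonotypes = dplyr::n_distinct(.data$clonotype_id),
              .groups = "drop")
  if (!is.null(collapse_min)) {
    small <- out$n_clonotypes < collapse_min
    if (any(small)) {
      pooled <- tibble::tibble(gene = "other",
                               weight = sum(out$weight[small]),
                               n_clonotypes = sum(out$n_clonotypes[small]))
      out <- dplyr::bind_rows(out[!small, ], pooled)
    }
  }
  out %>%
    mutate(freq = .data$weight / sum(.data$weight)) %>%
    arrange(dplyr::desc(.data$freq), .data$gene)
}

#' Find public chain identities across patients
#'
#' Groups clonotype chains (or chain pairs) by identity and flags as public
#' the identities observed in at least two distinct patients.  The default
#' identity key is (V gene, J gene, CDR3 amino acids) per chain; set
#' `key = "cdr3"` to use the CDR3 alone.  Every accepted chain is keyed:
#' dual-alpha clonotypes contribute both alphas (and, in paired mode, both
#' alpha:beta pairs).  Within-patient repeats count once toward the patient
#' set.
#'
#' @param clonotypes Clonotype tibble spanning two or more patients.
#' @param mode `"alpha"`, `"beta"` or `"paired"`.
#' @param key `"vj_cdr3"` (default) or `"cdr3"`.
#' @return Tibble of identity records with `n_patients`, `patients`
#'   (list-column), `n_clonotypes` and `public`.
#' @export
find_public_sequences <- function(clonotypes,
                                  mode = c("alpha", "beta", "paired"),
                                  key = c("vj_cdr3", "cdr3")) {
  mode <- match.arg(mode)
  key <- match.arg(key)
  x <- clonotypes

  beta_id <- tibble::tibble(clonotype_id = x$clonotype_id,
                            patient_id = x$patient_id,
                            v_beta = x$v_beta, j_beta = x$j_beta,
                            cdr3_aa_beta = x$cdr3_aa_beta)
  alpha_id <- dplyr::bind_rows(
    tibble::tibble(clonotype_id = x$clonotype_id, patient_id = x$patient_id,
                   v_alpha = x$v_alpha, j_alpha = x$j_alpha,
                   cdr3_aa_alpha = x$cdr3_aa_alpha),
    tibble::tibble(clonotype_id = x$clonotype_id, patient_id = x$patient_id,
                   v_alpha = x$v_alpha2, j_alpha = x$j_alpha2,
                   cdr3_aa_alpha = x$cdr3_aa_alpha2)[x$dual_alpha, ])

  recs <- switch(mode,
    beta = beta_id,
    alpha = dplyr::filter(alpha_id, !is.na(.data$cdr3_aa_alpha)),
    paired = alpha_id %>%
      filter(!is.na(.data$cdr3_aa_alpha)) %>%
      left_join(beta_id, by = c("clonotype_id", "patient_id")))

  key_cols <- switch(mode,
    beta = c("v_beta", "j_beta", "cdr3_aa_beta"),
    alpha = c("v_alpha", "j_alpha", "cdr3_aa_alpha"),
    paired = c("v_alpha", "j_alpha", "cdr3_aa_alpha",
               "v_beta", "j_beta", "cdr3_aa_beta"))
  if (key == "cdr3") {
    key_cols <- grep("^cdr3", key_cols, value = TRUE)
  }

  recs %>%
    distinct(dplyr::across(dplyr::all_of(c(key_cols, "patient_id",
                                           "clonotype_id")))) %>%
    group_by(dplyr::across(dplyr::all_of(key_cols))) %>%
    summarise(mode = mode,
              n_patients = dplyr::n_distinct(.data$patient_id),
              patients = list(sort(unique(.data$patient_id))),
              n_clonotypes = dplyr::n_distinct(.data$clonotype_id),
              clonotype_ids = list(sort(unique(.data$clonotype_id))),
              .groups = "drop") %>%
    mutate(public = .data$n_patients >= 2L) %>%
    arrange(dplyr::desc(.data$n_patients))
}

#' Per-patient fraction of clonotypes involving public chains
#'
#' For each patient, the fraction of clonotypes whose alpha or beta identity
#' is public (shared with at least one other patient).  The cohort median is
#' attached as the `"median"` attribute.  With `bins` supplied, patients are
#' also grouped by clonotype count (e.g. `c(0, 100, 200)`).
#'
#' @param clonotypes Clonotype tibble.
#' @param public Optional combined public-record table (rows of
#'   [find_public_sequences()] in alpha and beta modes); computed when
#'   missing.
#' @param key Identity key, as in [find_public_sequences()].
#' @param bins Optional numeric cut points for patient grouping.
#' @return Tibble (`patient_id`, `n_clonotypes`, `n_public`, `fraction`,
#'   optionally `bin`) with attribute `"median"`.
#' @export
shared_fraction_per_patient <- function(clonotypes, public = NULL,
                                        key = c("vj_cdr3", "cdr3"),
                                        bins = NULL) {
  key <- match.arg(key)
  if (is.null(public)) {
    public <- dplyr::bind_rows(
      find_public_sequences(clonotypes, "alpha", key),
      find_public_sequences(clonotypes, "beta", key))
  }
  pub_ids <- unique(unlist(public$clonotype_ids[public$public]))
  out <- clonotypes %>%
    group_by(.data$patient_id) %>%
    summarise(n_clonotypes = dplyr::n(),
              n_public = sum(.data$clonotype_id %in% pub_ids),
              .groups = "drop") %>%
    mutate(fraction = .data$n_public / .data$n_clonotypes)
  if (!is.null(bins)) {
    out$bin <- cut(out$n_clonotypes, breaks = c(bins, Inf),
                   include.lowest = TRUE)
  }
  attr(out, "median") <- median(out$fraction)
  out
}

#' Annotate motifs or public pairs with epitope specificity
#'
#' Compares targets against a reference table of clones with known epitope
#' specificity.  For motifs, a reference clone supports an epitope when it
#' matches the motif ([match_motif()] semantics; evidence `clone_exact`).
#' For public paired records, exact V/J/CDR3 identity on both chains gives
#' evidence `clone_exact`, while equal V genes with a total CDR3 Levenshtein
#' distance (summed over chains) of at most `max_mismatch` gives
#' `clone_similar`.  A target matched by clones of several epitopes keeps
#' all of them (cross-reactivity).
#'
#' @param targets A `tcr_motifs` table or a paired public-record table from
#'   [find_public_sequences()].
#' @param reference_clones Tibble with `epitope` and per-chain
#'   `v_alpha`/`j_alpha`/`cdr3_aa_alpha`, `v_beta`/`j_beta`/`cdr3_aa_beta`.
#' @param max_mismatch Total CDR3 amino-acid difference tolerated for
#'   `clone_similar` (default 1).
#' @return Tibble (`target_id`, `epitope`, `evidence`, `n_support`).
#' @export
annotate_epitopes <- function(targets, reference_clones, max_mismatch = 1L) {
  if (!"epitope" %in% names(reference_clones)) {
    abort("reference clone table is missing the 'epitope' column",
          class = "tcrmotifs_format_error")
  }
  ref <- reference_clones %>%
    mutate(v_alpha_subgroup = v_subgroup_of(.data$v_alpha),
           v_beta_subgroup = v_subgroup_of(.data$v_beta))

  if (inherits(targets, "tcr_motifs")) {
    return(purrr::map_dfr(seq_len(nrow(targets)), function(i) {
      hits <- match_motif(targets[i, ], ref)
      if (!any(hits)) return(tibble::tibble())
      ref[hits, ] %>%
        count(.data$epitope, name = "n_support") %>%
        mutate(target_id = targets$motif_id[i], evidence = "clone_exact") %>%
        select("target_id", "epitope", "evidence", "n_support")
    }))
  }

  # paired public records
  stopifnot(all(c("cdr3_aa_alpha", "cdr3_aa_beta") %in% names(targets)))
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    same_v <- ref$v_alpha == t$v_alpha & ref$v_beta == t$v_beta
    exact <- same_v & ref$j_alpha == t$j_alpha & ref$j_beta == t$j_beta &
      ref$cdr3_aa_alpha == t$cdr3_aa_alpha & ref$cdr3_aa_beta == t$cdr3_aa_beta
    dist <- levenshtein(ref$cdr3_aa_alpha, t$cdr3_aa_alpha) +
      levenshtein(ref$cdr3_aa_beta, t$cdr3_aa_beta)
    similar <- same_v & !exact & dist <= max_mismatch
    id <- paste(t$v_alpha, t$cdr3_aa_alpha, t$v_beta, t$cdr3_aa_beta,
                sep = "|")
    dplyr::bind_rows(
      if (any(exact)) ref[exact, ] %>%
        count(.data$epitope, name = "n_support") %>%
        mutate(target_id = id, evidence = "clone_exact"),
      if (any(similar)) ref[similar, ] %>%
        count(.data$epitope, name = "n_support") %>%
        mutate(target_id = id, evidence = "clone_similar")) %>%
      select(dplyr::any_of(c("target_id", "epitope", "evidence",
                             "n_support")))
  })
}

#' Search motifs in an external TCR database
#'
#' Counts database rows matching each motif (anchored pattern plus identical
#' V gene).  Rows whose epitope/antigen/pathology annotation matches any
#' exclusion keyword are removed before counting, so that disease-related
#' entries do not inflate the search.  Long-format databases (one chain per
#' row: columns `chain`, `cdr3_aa`, `v_gene`) support single-chain motifs;
#' paired motifs additionally require per-row `cdr3_aa_alpha`/`cdr3_aa_beta`
#' (and `v_alpha`/`v_beta`) columns and count 0 when the database has none.
#'
#' @param motifs Motif table (`tcr_motifs` or [established_motifs()]).
#' @param db Database tibble.
#' @param exclusion_keywords Case-insensitive keywords matched against the
#'   `epitope`, `antigen` and `pathology` columns (those present).
#' @return Tibble (`motif`, `n_matches`).
#' @export
search_external_db <- function(motifs, db,
                               exclusion_keywords = c("celiac", "gluten",
                                                      "gliadin", "coeliac")) {
  label_cols <- intersect(c("epitope", "antigen", "pathology", "disease"),
                          names(db))
  if (length(label_cols) > 0L && length(exclusion_keywords) > 0L) {
    pat <- paste(exclusion_keywords, collapse = "|")
    hit <- Reduce(`|`, lapply(label_cols, function(cl) {
      grepl(pat, db[[cl]], ignore.case = TRUE) & !is.na(db[[cl]])
    }))
    db <- db[!hit, , drop = FALSE]
  }
  name_col <- if ("motif_id" %in% names(motifs)) "motif_id" else "name"
  has_long <- all(c("chain", "cdr3_aa", "v_gene") %in% names(db))
  has_wide <- all(c("cdr3_aa_alpha", "cdr3_aa_beta") %in% names(db))

  purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    m <- motifs[i, ]
    chain <- if ("chain_mode" %in% names(m)) m$chain_mode[[1]] else
      m$chain[[1]]
    n <- if (chain %in% c("alpha", "beta") && has_long) {
      rows <- db[db$chain %in% c(chain,
                                 ifelse(chain == "alpha", "TRA", "TRB")), ]
      subj <- tibble::tibble(cdr3_aa_beta = NA_character_,
                             v_beta = NA_character_,
                             v_beta_subgroup = NA_character_,
                             j_beta = NA_character_,
                             cdr3_aa_alpha = NA_character_,
                             v_alpha = NA_character_,
                             v_alpha_subgroup = NA_character_,
                             j_alpha = NA_character_,
                             .rows = nrow(rows))
      g <- strip_allele(rows$v_gene)
      if (chain == "beta") {
        subj$cdr3_aa_beta <- rows$cdr3_aa
        subj$v_beta <- g
        subj$v_beta_subgroup <- v_subgroup_of(rows$v_gene)
      } else {
        subj$cdr3_aa_alpha <- rows$cdr3_aa
        subj$v_alpha <- g
        subj$v_alpha_subgroup <- v_subgroup_of(rows$v_gene)
      }
      sum(match_motif(m, subj))
    } else if (chain == "paired" && has_wide) {
      subj <- tibble::tibble(
        cdr3_aa_alpha = db$cdr3_aa_alpha,
        v_alpha = strip_allele(db$v_alpha),
        v_alpha_subgroup = v_subgroup_of(db$v_alpha),
        j_alpha = NA_character_,
        cdr3_aa_beta = db$cdr3_aa_beta,
        v_beta = strip_allele(db$v_beta),
        v_beta_subgroup = v_subgroup_of(db$v_beta),
        j_beta = NA_character_)
      sum(match_motif(m, subj))
    } else {
      0L
    }
    tibble::tibble(motif = m[[name_col]][[1]], n_matches = as.integer(n))
  })
}

#' Paired generation probability
#'
#' The generation probability of a paired receptor is the product of the
#' per-chain generation probabilities (chains rearrange independently).
#'
#' @param p_alpha,p_beta Probabilities in `[0, 1]` (vectorised).
#' @return `p_alpha * p_beta`.
#' @export
paired_generation_probability <- function(p_alpha, p_beta) {
  if (any(is.na(p_alpha)) || any(is.na(p_beta)) ||
      any(p_alpha < 0 | p_alpha > 1) || any(p_beta < 0 | p_beta > 1)) {
    abort("generation probabilities must lie in [0, 1]",
          class = "tcrmotifs_validation_error")
  }
  p_alpha * p_beta
}

#' One-sided rank-sum comparison of public vs private values
#'
#' Mann-Whitney U test that public sequences have larger values (e.g.
#' generation probabilities) than private ones.  For combined sample sizes
#' up to `exact_max_n` the p-value is computed by exhaustive enumeration of
#' all group labelings (exact even under ties); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param public,private Non-empty numeric vectors.
#' @param alternative `"greater"` (public larger; default), `"less"` or
#'   `"two.sided"`.
#' @param exact_max_n Largest combined sample size for the exact path
#'   (default 20).
#' @return One-row tibble (`statistic` = U for the public sample,
#'   `p.value`, `n_public`, `n_private`, `method`, `alternative`).
#' @export
compare_public_private <- function(public, private,
                                   alternative = c("greater", "less",
                                                   "two.sided"),
                                   exact_max_n = 20L) {
  alternative <- match.arg(alternative)
  if (length(public) == 0L || length(private) == 0L) {
    abort("both samples must be non-empty",
          class = "tcrmotifs_degenerate_input")
  }
  n1 <- length(public)
  n2 <- length(private)
  all_v <- c(public, private)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= exact_max_n) {
    idx <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      greater = mean(Us >= U - 1e-9),
      less = mean(Us <= U + 1e-9),
      two.sided = min(1, 2 * min(mean(Us >= U - 1e-9),
                                 mean(Us <= U + 1e-9))))
    method <- "exact permutation"
  } else {
    N <- n1 + n2
    ties <- table(all_v)
    mu <- n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z <- switch(alternative,
      greater = (U - mu - 0.5) / sigma,
      less = (U - mu + 0.5) / sigma,
      two.sided = (U - mu - sign(U - mu) * 0.5) / sigma)
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two.sided = min(1, 2 * pnorm(abs(z), lower.tail = FALSE)))
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(statistic = U, p.value = p, n_public = n1, n_private = n2,
                 method = method, alternative = alternative)
}
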