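# Ingestion of annotated rearrangement tables, chain/cell filtering and
# clonotype calling.
#
# The CDR3 convention throughout the package is IMGT positions 105-117: the
# junction minus the conserved C104 and F/W118 anchors.  Inputs that provide
# full junctions are converted by setting `junction_is_full = TRUE` in the
# dialect.

#' Column dialect for rearrangement tables
#'
#' Describes how the columns of an AIRR-style rearrangement TSV map onto the
#' fields the package needs.  `read_count` may list several aliases
#' (`duplicate_count`, `consensus_count`); the first one present is used.
#'
#' @param cell_id,patient_id,locus,v_call,j_call,junction,junction_aa,productive
#'   Column names in the input file.
#' @param read_count Character vector of candidate column names for the
#'   per-chain read support.
#' @param junction_is_full If `TRUE`, the junction columns include the
#'   conserved C104 and F/W118 anchors, which are stripped (first/last amino
#'   acid, first/last codon) on input.
#' @return A named list used by [read_rearrangements()].
#' @export
rearrangement_dialect <- function(cell_id = "cell_id",
                                  patient_id = "patient_id",
                                  locus = "locus",
                                  v_call = "v_call",
                                  j_call = "j_call",
                                  junction = "junction",
                                  junction_aa = "junction_aa",
                                  read_count = c("duplicate_count",
                                                 "consensus_count"),
                                  productive = "productive",
                                  junction_is_full = FALSE) {
  list(cell_id = cell_id, patient_id = patient_id, locus = locus,
       v_call = v_call, j_call = j_call, junction = junction,
       junction_aa = junction_aa, read_count = read_count,
       productive = productive, junction_is_full = junction_is_full)
}

#' Read an annotated rearrangement table
#'
#' Reads an AIRR-style TSV of single-cell TCR chains and returns one chain
#' record per well-formed row.  Rows with missing V/J calls, unparseable
#' CDR3s, inconsistent nucleotide/amino-acid lengths or (for productive
#' chains) a junction that does not translate to the reported amino acids are
#' set aside as rejects, retrievable with [rearrangement_rejects()].
#'
#' V and J calls are reduced to gene level (allele suffixes such as `*01`
#' dropped); when a call lists several genes the first is used and the chain
#' is flagged `v_ambiguous`.
#'
#' @param path Path to a TSV file, or a data frame already in the dialect's
#'   column layout.
#' @param dialect Column mapping from [rearrangement_dialect()].
#' @param patient_map Optional data frame (`cell_id`, `patient_id`) used when
#'   the table itself has no patient column.
#' @return A tibble of chain records (`cell_id`, `patient_id`, `chain`,
#'   `v_gene`, `v_subgroup`, `v_ambiguous`, `j_gene`, `cdr3_nt`, `cdr3_aa`,
#'   `read_count`, `productive`) with a `"rejects"` attribute.
#' @export
read_rearrangements <- function(path, dialect = rearrangement_dialect(),
                                patient_map = NULL) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  if (nrow(raw) == 0L) {
    empty <- chain_record_prototype()
    attr(empty, "rejects") <- reject_prototype()
    return(empty)
  }

  need <- c("cell_id", "locus", "v_call", "j_call", "junction",
            "junction_aa", "productive")
  for (f in need) {
    if (!dialect[[f]] %in% names(raw)) {
      abort(sprintf("rearrangement table is missing mandatory column '%s'",
                    dialect[[f]]), class = "tcrmotifs_format_error")
    }
  }
  rc_col <- intersect(dialect$read_count, names(raw))[1]
  if (is.na(rc_col)) {
    abort(sprintf("rearrangement table is missing a read-count column (%s)",
                  paste(dialect$read_count, collapse = " or ")),
          class = "tcrmotifs_format_error")
  }

  patient <- if (dialect$patient_id %in% names(raw)) {
    as.character(raw[[dialect$patient_id]])
  } else if (!is.null(patient_map)) {
    pm <- setNames(as.character(patient_map$patient_id),
                   as.character(patient_map$cell_id))
    unname(pm[as.character(raw[[dialect$cell_id]])])
  } else {
    abort("no patient_id column and no patient_map supplied",
          class = "tcrmotifs_format_error")
  }

  rec <- tibble::tibble(
    row        = seq_len(nrow(raw)),
    cell_id    = as.character(raw[[dialect$cell_id]]),
    patient_id = patient,
    locus      = toupper(as.character(raw[[dialect$locus]])),
    v_call     = as.character(raw[[dialect$v_call]]),
    j_call     = as.character(raw[[dialect$j_call]]),
    cdr3_nt    = toupper(as.character(raw[[dialect$junction]])),
    cdr3_aa    = toupper(as.character(raw[[dialect$junction_aa]])),
    read_count = suppressWarnings(as.numeric(raw[[rc_col]])),
    productive = parse_flag(raw[[dialect$productive]])
  )
  rec$chain <- dplyr::case_when(
    rec$locus %in% c("TRA", "ALPHA") ~ "alpha",
    rec$locus %in% c("TRB", "BETA") ~ "beta",
    TRUE ~ NA_character_
  )
  if (isTRUE(dialect$junction_is_full)) {
    long_enough <- !is.na(rec$cdr3_aa) & nchar(rec$cdr3_aa) >= 3 &
      !is.na(rec$cdr3_nt) & nchar(rec$cdr3_nt) >= 9
    rec$cdr3_aa[long_enough] <- substr(rec$cdr3_aa[long_enough], 2L,
                                       nchar(rec$cdr3_aa[long_enough]) - 1L)
    rec$cdr3_nt[long_enough] <- substr(rec$cdr3_nt[long_enough], 4L,
                                       nchar(rec$cdr3_nt[long_enough]) - 3L)
  }

  reason <- rep(NA_character_, nrow(rec))
  bad <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(is.na(rec$chain), "unknown locus")
  reason <- bad(is.na(rec$patient_id) | rec$patient_id == "",
                "missing patient id")
  reason <- bad(is.na(rec$v_call) | rec$v_call == "", "missing V call")
  reason <- bad(is.na(rec$j_call) | rec$j_call == "", "missing J call")
  reason <- bad(is.na(rec$read_count) | rec$read_count < 0,
                "invalid read count")
  reason <- bad(!is_valid_aa(rec$cdr3_aa, allow_stop = TRUE),
                "unparseable CDR3")
  reason <- bad(rec$productive & !is_valid_aa(rec$cdr3_aa),
                "unparseable CDR3")
  reason <- bad(is.na(rec$cdr3_nt) | !grepl("^[ACGT]+$", rec$cdr3_nt),
                "unparseable CDR3")
  reason <- bad(nchar(rec$cdr3_nt) != 3L * nchar(rec$cdr3_aa),
                "nt/aa length mismatch")
  ok_len <- is.na(reason)
  trans <- rep(NA_character_, nrow(rec))
  trans[ok_len] <- translate_nt(rec$cdr3_nt[ok_len])
  reason <- bad(rec$productive & ok_len & trans != rec$cdr3_aa,
                "translation mismatch")

  kept <- rec[is.na(reason), ]
  out <- tibble::tibble(
    cell_id     = kept$cell_id,
    patient_id  = kept$patient_id,
    chain       = kept$chain,
    v_gene      = strip_allele(kept$v_call),
    v_subgroup  = v_subgroup_of(kept$v_call),
    v_ambiguous = grepl(",", kept$v_call),
    j_gene      = strip_allele(kept$j_call),
    cdr3_nt     = kept$cdr3_nt,
    cdr3_aa     = kept$cdr3_aa,
    read_count  = kept$read_count,
    productive  = kept$productive
  )
  rej <- rec[!is.na(reason), c("row", "cell_id")]
  rej$reason <- reason[!is.na(reason)]
  attr(out, "rejects") <- tibble::as_tibble(rej)
  out
}

#' @rdname read_rearrangements
#' @param records A tibble returned by [read_rearrangements()].
#' @export
rearrangement_rejects <- function(records) {
  rej <- attr(records, "rejects")
  if (is.null(rej)) reject_prototype() else rej
}

#' Write chain records back to the rearrangement dialect
#'
#' Inverse of [read_rearrangements()] for conformant inputs: emits the
#' retained columns in the AIRR-style layout so that a read/write round trip
#' reproduces them byte-identically.
#'
#' @param records Chain-record tibble.
#' @param path Output TSV path (omit to return the table).
#' @return The dialect-shaped tibble, invisibly when written to file.
#' @export
write_rearrangements <- function(records, path = NULL) {
  out <- tibble::tibble(
    cell_id         = records$cell_id,
    patient_id      = records$patient_id,
    locus           = ifelse(records$chain == "alpha", "TRA", "TRB"),
    v_call          = records$v_gene,
    j_call          = records$j_gene,
    junction        = records$cdr3_nt,
    junction_aa     = records$cdr3_aa,
    duplicate_count = records$read_count,
    productive      = ifelse(records$productive, "T", "F")
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}

#' Apply the read-support and dual-chain filters
#'
#' Within each cell and locus, chains are ranked by read support.  The top
#' chain is kept when its read count is at least `min_reads`; a second chain
#' is kept only when it also reaches `min_reads` and carries at least
#' `dual_min_fraction` of the top chain's reads.  At most two chains per
#' locus survive.  Unproductive chains are excluded up front by default
#' (they are flagged on input and take no part in clonotype calling).
#'
#' The filter is idempotent and never raises.
#'
#' @param records Chain-record tibble from [read_rearrangements()].
#' @param min_reads Minimum read support per chain (default 50).
#' @param dual_min_fraction Minimum fraction of the top chain's reads for a
#'   secondary (dual) chain to be accepted (default 0.10).
#' @param productive_only Drop unproductive chains first (default `TRUE`).
#' @return Filtered chain-record tibble.
#' @export
filter_chains <- function(records, min_reads = 50,
                          dual_min_fraction = 0.10,
                          productive_only = TRUE) {
  x <- records
  if (productive_only) x <- dplyr::filter(x, .data$productive)
  if (nrow(x) == 0L) return(x)
  x %>%
    arrange(.data$cell_id, .data$chain, dplyr::desc(.data$read_count),
            .data$cdr3_nt) %>%
    group_by(.data$cell_id, .data$chain) %>%
    mutate(.rank = row_number(), .top = first(.data$read_count)) %>%
    ungroup() %>%
    filter(.data$read_count >= min_reads,
           .data$.rank == 1L |
             (.data$.rank == 2L &
                .data$read_count >= dual_min_fraction * .data$.top)) %>%
    select(-".rank", -".top")
}

#' Call valid cells from filtered chains
#'
#' A valid cell carries one or two TCR-alpha and one or two TCR-beta chains,
#' with at most three chains in total.
#'
#' @param chains Filtered chain-record tibble.
#' @return Per-cell tibble (`cell_id`, `patient_id`, `n_alpha`, `n_beta`,
#'   `valid`).
#' @export
call_valid_cells <- function(chains) {
  chains %>%
    group_by(.data$cell_id, .data$patient_id) %>%
    summarise(n_alpha = sum(.data$chain == "alpha"),
              n_beta = sum(.data$chain == "beta"), .groups = "drop") %>%
    mutate(valid = .data$n_alpha >= 1L & .data$n_alpha <= 2L &
             .data$n_beta >= 1L & .data$n_beta <= 2L &
             .data$n_alpha + .data$n_beta <= 3L)
}

#' Call clonotypes from valid cells
#'
#' A clonotype is a patient-level clone keyed on its TCR-beta: identical V
#' gene, J gene and CDR3 nucleotide sequence.  Each valid cell contributes
#' its highest-read beta chain as the defining chain (nucleotide-lexicographic
#' tie-break).  The representative alpha chain is the alpha identity
#' observed in the most member cells, ties broken by higher total read
#' support and then lexicographic CDR3 nucleotide sequence; a second alpha
#' is attached when cells carrying the representative alpha also carry
#' another one (dual alpha).
#'
#' @param chains Filtered chain-record tibble.
#' @param cells Optional per-cell table from [call_valid_cells()]; computed
#'   when missing.
#' @return One row per clonotype with beta key, representative alpha
#'   chain(s), ambiguity flags, `dual_alpha` and `n_cells`.
#' @export
define_clonotypes <- function(chains, cells = NULL) {
  if (is.null(cells)) cells <- call_valid_cells(chains)
  valid_ids <- cells$cell_id[cells$valid]
  ch <- dplyr::filter(chains, .data$cell_id %in% valid_ids)

  betas <- ch %>%
    filter(.data$chain == "beta") %>%
    arrange(.data$cell_id, dplyr::desc(.data$read_count), .data$cdr3_nt) %>%
    group_by(.data$cell_id) %>%
    slice(1L) %>%
    ungroup()

  cell2ct <- betas %>%
    select("cell_id", "patient_id",
           v_beta = "v_gene", v_beta_subgroup = "v_subgroup",
           v_beta_ambiguous = "v_ambiguous", j_beta = "j_gene",
           cdr3_nt_beta = "cdr3_nt", cdr3_aa_beta = "cdr3_aa",
           reads_beta = "read_count")

  ct <- cell2ct %>%
    group_by(.data$patient_id, .data$v_beta, .data$j_beta,
             .data$cdr3_nt_beta) %>%
    summarise(v_beta_subgroup = first(.data$v_beta_subgroup),
              v_beta_ambiguous = first(.data$v_beta_ambiguous),
              cdr3_aa_beta = first(.data$cdr3_aa_beta),
              n_cells = dplyr::n(), .groups = "drop") %>%
    arrange(.data$patient_id, .data$v_beta, .data$j_beta,
            .data$cdr3_nt_beta) %>%
    group_by(.data$patient_id) %>%
    mutate(clonotype_id = sprintf("%s_CT%04d", .data$patient_id,
                                  row_number())) %>%
    ungroup()

  # map each member cell to its clonotype, then pick representative alphas
  cell2ct <- cell2ct %>%
    left_join(ct %>% select("patient_id", "v_beta", "j_beta",
                            "cdr3_nt_beta", "clonotype_id"),
              by = c("patient_id", "v_beta", "j_beta", "cdr3_nt_beta"))

  alphas <- ch %>%
    filter(.data$chain == "alpha") %>%
    left_join(cell2ct %>% select("cell_id", "clonotype_id"), by = "cell_id") %>%
    filter(!is.na(.data$clonotype_id))

  rank_alpha <- alphas %>%
    group_by(.data$clonotype_id, .data$v_gene, .data$v_subgroup,
             .data$v_ambiguous, .data$j_gene, .data$cdr3_nt, .data$cdr3_aa) %>%
    summarise(n_cells_alpha = dplyr::n_distinct(.data$cell_id),
              reads = sum(.data$read_count), .groups = "drop") %>%
    arrange(.data$clonotype_id, dplyr::desc(.data$n_cells_alpha),
            dplyr::desc(.data$reads), .data$cdr3_nt)

  a1 <- rank_alpha %>%
    group_by(.data$clonotype_id) %>%
    slice(1L) %>%
    ungroup() %>%
    select("clonotype_id", v_alpha = "v_gene",
           v_alpha_subgroup = "v_subgroup", v_alpha_ambiguous = "v_ambiguous",
           j_alpha = "j_gene", cdr3_nt_alpha = "cdr3_nt",
           cdr3_aa_alpha = "cdr3_aa")

  # second alpha: best-ranked identity co-occurring with the representative
  co <- alphas %>%
    left_join(a1 %>% select("clonotype_id", "cdr3_nt_alpha"),
              by = "clonotype_id") %>%
    group_by(.data$clonotype_id, .data$cell_id) %>%
    filter(any(.data$cdr3_nt == .data$cdr3_nt_alpha)) %>%
    ungroup() %>%
    filter(.data$cdr3_nt != .data$cdr3_nt_alpha)
  a2 <- co %>%
    group_by(.data$clonotype_id, .data$v_gene, .data$v_subgroup,
             .data$v_ambiguous, .data$j_gene, .data$cdr3_nt, .data$cdr3_aa) %>%
    summarise(n_cells_alpha = dplyr::n_distinct(.data$cell_id),
              reads = sum(.data$read_count), .groups = "drop") %>%
    arrange(.data$clonotype_id, dplyr::desc(.data$n_cells_alpha),
            dplyr::desc(.data$reads), .data$cdr3_nt) %>%
    group_by(.data$clonotype_id) %>%
    slice(1L) %>%
    ungroup() %>%
    select("clonotype_id", v_alpha2 = "v_gene",
           v_alpha2_subgroup = "v_subgroup",
           v_alpha2_ambiguous = "v_ambiguous", j_alpha2 = "j_gene",
           cdr3_nt_alpha2 = "cdr3_nt", cdr3_aa_alpha2 = "cdr3_aa")

  ct %>%
    left_join(a1, by = "clonotype_id") %>%
    left_join(a2, by = "clonotype_id") %>%
    mutate(dual_alpha = !is.na(.data$cdr3_nt_alpha2)) %>%
    select("clonotype_id", "patient_id", "v_beta", "v_beta_subgroup",
           "v_beta_ambiguous", "j_beta", "cdr3_nt_beta", "cdr3_aa_beta",
           "v_alpha", "v_alpha_subgroup", "v_alpha_ambiguous", "j_alpha",
           "cdr3_nt_alpha", "cdr3_aa_alpha", "v_alpha2", "v_alpha2_subgroup",
           "v_alpha2_ambiguous", "j_alpha2", "cdr3_nt_alpha2",
           "cdr3_aa_alpha2", "dual_alpha", "n_cells")
}

parse_flag <- function(x) {
  toupper(as.character(x)) %in% c("T", "TRUE", "1", "YES", "Y")
}

chain_record_prototype <- function() {
  tibble::tibble(cell_id = character(), patient_id = character(),
                 chain = character(), v_gene = character(),
                 v_subgroup = character(), v_ambiguous = logical(),
                 j_gene = character(), cdr3_nt = character(),
                 cdr3_aa = character(), read_count = numeric(),
                 productive = logical())
}

reject_prototype <- function() {
  tibble::tibble(row = integer(), cell_id = character(),
                 reason = character())
}
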