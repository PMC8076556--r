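# CDR3 trimming and assembly of the clustering sets.

#' Trim a CDR3 for specificity clustering
#'
#' Removes the two N-terminal residues (IMGT positions 105 and 106) and the
#' single C-terminal residue (IMGT position 117).  These positions do not
#' contact peptide antigen and are removed before clustering for shared
#' specificity.
#'
#' @param full_aa Character vector of CDR3 amino-acid strings (IMGT 105-117).
#' @return Character vector, three residues shorter than the input.
#' @export
#' @examples
#' trim_cdr3("ASSIRATDTQY")
trim_cdr3 <- function(full_aa) {
  n <- nchar(full_aa)
  if (any(is.na(full_aa)) || any(n < 3L)) {
    abort("trim_cdr3() needs CDR3s of at least 3 residues",
          class = "tcrmotifs_degenerate_input")
  }
  substr(full_aa, 3L, n - 1L)
}

#' Build the clustering set for one chain mode
#'
#' Trims every relevant CDR3, removes clonotypes whose trimmed CDR3 is
#' shorter than `min_trimmed_len` residues, and (for dual-alpha clonotypes
#' in alpha or paired mode) selects one of the two alpha chains by a seeded
#' uniform draw so that runs are reproducible.  In paired mode a clonotype is
#' excluded when either chain fails the length filter (set
#' `length_filter = "beta_only"` to filter on the beta chain alone).
#'
#' @param clonotypes Clonotype tibble from [define_clonotypes()].
#' @param chain_mode `"beta"`, `"alpha"` or `"paired"`.
#' @param min_trimmed_len Minimum trimmed CDR3 length (default 8).
#' @param seed Integer seed for the dual-alpha draw.
#' @param length_filter `"either"` (default) or `"beta_only"`, paired mode
#'   only.
#' @return Tibble ordered by `clonotype_id` with the full and trimmed CDR3s
#'   and the V-gene columns of the chains involved.
#' @export
prepare_clustering_set <- function(clonotypes,
                                   chain_mode = c("beta", "alpha", "paired"),
                                   min_trimmed_len = 8L, seed = 1L,
                                   length_filter = c("either", "beta_only")) {
  chain_mode <- match.arg(chain_mode)
  length_filter <- match.arg(length_filter)
  x <- arrange(clonotypes, .data$clonotype_id)

  if (chain_mode != "beta") {
    # seeded uniform pick between the two alphas of dual clonotypes
    pick2 <- rep(FALSE, nrow(x))
    dual <- which(x$dual_alpha)
    if (length(dual) > 0L) {
      pick2[dual] <- with_seed(seed, runif(length(dual)) < 0.5)
    }
    x$sel_v_alpha <- ifelse(pick2, x$v_alpha2, x$v_alpha)
    x$sel_v_alpha_subgroup <- ifelse(pick2, x$v_alpha2_subgroup,
                                     x$v_alpha_subgroup)
    x$sel_j_alpha <- ifelse(pick2, x$j_alpha2, x$j_alpha)
    x$sel_cdr3_alpha <- ifelse(pick2, x$cdr3_aa_alpha2, x$cdr3_aa_alpha)
  }

  out <- tibble::tibble(clonotype_id = x$clonotype_id,
                        patient_id = x$patient_id)
  if (chain_mode %in% c("beta", "paired")) {
    out$v_beta <- x$v_beta
    out$v_beta_subgroup <- x$v_beta_subgroup
    out$j_beta <- x$j_beta
    out$cdr3_beta <- x$cdr3_aa_beta
    out$trimmed_beta <- trim_cdr3(x$cdr3_aa_beta)
  }
  if (chain_mode %in% c("alpha", "paired")) {
    out$v_alpha <- x$sel_v_alpha
    out$v_alpha_subgroup <- x$sel_v_alpha_subgroup
    out$j_alpha <- x$sel_j_alpha
    out$cdr3_alpha <- x$sel_cdr3_alpha
    ok <- !is.na(out$cdr3_alpha) & nchar(out$cdr3_alpha) >= 3L
    out$trimmed_alpha <- NA_character_
    out$trimmed_alpha[ok] <- trim_cdr3(out$cdr3_alpha[ok])
  }

  keep <- switch(chain_mode,
    beta  = nchar(out$trimmed_beta) >= min_trimmed_len,
    alpha = !is.na(out$trimmed_alpha) &
      nchar(out$trimmed_alpha) >= min_trimmed_len,
    paired = if (length_filter == "either") {
      nchar(out$trimmed_beta) >= min_trimmed_len &
        !is.na(out$trimmed_alpha) &
        nchar(out$trimmed_alpha) >= min_trimmed_len
    } else {
      nchar(out$trimmed_beta) >= min_trimmed_len & !is.na(out$trimmed_alpha)
    }
  )
  out <- out[keep, , drop = FALSE]
  attr(out, "chain_mode") <- chain_mode
  out
}
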