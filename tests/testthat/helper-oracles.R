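# Independent reference implementations used to check the package's
# computational core, plus small fixture builders.

# full dynamic-programming edit-distance table (unit costs)
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  D <- matrix(0L, na + 1L, nb + 1L)
  D[, 1L] <- 0:na
  D[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (ca[i] != cb[j]),
                               D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
    }
  }
  D[na + 1L, nb + 1L]
}

# brute-force average-linkage agglomeration: averages recomputed from the
# original matrix over explicit leaf sets at every step (no Lance-Williams
# update), same smallest-(min id, max id) tie rule as the package documents
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        mn <- min(min(clusters[[i]]), min(clusters[[j]]))
        mx <- max(min(clusters[[i]]), min(clusters[[j]]))
        if (is.null(best) || avg < best$avg - 1e-12 ||
            (abs(avg - best$avg) <= 1e-12 &&
             (mn < best$mn || (mn == best$mn && mx < best$mx)))) {
          best <- list(i = i, j = j, avg = avg, mn = mn, mx = mx)
        }
      }
    }
    merges[[length(merges) + 1L]] <- sort(c(clusters[[best$i]],
                                            clusters[[best$j]]))
    heights <- c(heights, best$avg)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# leaf sets merged at each step of a tcr_dendrogram, for oracle comparison
tree_merge_sets <- function(tree) {
  k <- nrow(tree$merge)
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    l <- tree$merge[i, 1L]
    r <- tree$merge[i, 2L]
    sets[[i]] <- sort(c(if (l < 0L) -l else sets[[l]],
                        if (r < 0L) -r else sets[[r]]))
  }
  sets
}

random_aa <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

random_dist_matrix <- function(n, integer = TRUE, max_d = 10L) {
  d <- matrix(0, n, n)
  vals <- if (integer) sample(0:max_d, n * (n - 1) / 2, replace = TRUE)
  else runif(n * (n - 1) / 2, 0, max_d)
  d[lower.tri(d)] <- vals
  d + t(d)
}

# minimal clonotype table with all columns downstream functions expect
make_clonotypes <- function(patient_id, cdr3_aa_beta, v_beta,
                            j_beta = "TRBJ2-3",
                            cdr3_aa_alpha = NULL, v_alpha = "TRAV26-1",
                            j_alpha = "TRAJ20", dual_alpha = FALSE,
                            v_beta_ambiguous = FALSE,
                            v_alpha_ambiguous = FALSE,
                            cdr3_aa_alpha2 = NA_character_,
                            v_alpha2 = NA_character_,
                            j_alpha2 = NA_character_,
                            v_alpha2_ambiguous = FALSE,
                            n_cells = 1L) {
  n <- length(cdr3_aa_beta)
  if (is.null(cdr3_aa_alpha)) {
    cdr3_aa_alpha <- vapply(seq_len(n),
                            function(i) paste0("IV", random_aa(7), "LTF"),
                            "")
  }
  nt <- function(aa) {
    vapply(aa, function(s) {
      if (is.na(s)) NA_character_ else
        tcrmotifs::generate_cdr3_nt(s)$nt
    }, "", USE.NAMES = FALSE)
  }
  tibble::tibble(
    clonotype_id = sprintf("%s_CT%04d", rep_len(patient_id, n), seq_len(n)),
    patient_id = rep_len(patient_id, n),
    v_beta = rep_len(v_beta, n),
    v_beta_subgroup = tcrmotifs::v_subgroup_of(rep_len(v_beta, n)),
    v_beta_ambiguous = rep_len(v_beta_ambiguous, n),
    j_beta = rep_len(j_beta, n),
    cdr3_nt_beta = nt(cdr3_aa_beta), cdr3_aa_beta = cdr3_aa_beta,
    v_alpha = rep_len(v_alpha, n),
    v_alpha_subgroup = tcrmotifs::v_subgroup_of(rep_len(v_alpha, n)),
    v_alpha_ambiguous = rep_len(v_alpha_ambiguous, n),
    j_alpha = rep_len(j_alpha, n),
    cdr3_nt_alpha = nt(cdr3_aa_alpha), cdr3_aa_alpha = cdr3_aa_alpha,
    v_alpha2 = rep_len(v_alpha2, n),
    v_alpha2_subgroup = tcrmotifs::v_subgroup_of(rep_len(v_alpha2, n)),
    v_alpha2_ambiguous = rep_len(v_alpha2_ambiguous, n),
    j_alpha2 = rep_len(j_alpha2, n),
    cdr3_nt_alpha2 = nt(rep_len(cdr3_aa_alpha2, n)),
    cdr3_aa_alpha2 = rep_len(cdr3_aa_alpha2, n),
    dual_alpha = rep_len(dual_alpha, n),
    n_cells = rep_len(n_cells, n))
}

# one well-formed rearrangement row in the AIRR-style dialect
rearr_row <- function(cell_id, patient_id, locus, v_call, j_call, aa,
                      reads = 500, productive = "T",
                      nt = tcrmotifs::generate_cdr3_nt(aa)$nt) {
  tibble::tibble(cell_id = cell_id, patient_id = patient_id, locus = locus,
                 v_call = v_call, j_call = j_call, junction = nt,
                 junction_aa = aa, duplicate_count = reads,
                 productive = productive)
}
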