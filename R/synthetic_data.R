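# Synthetic multi-patient paired-chain repertoires with ground truth:
# planted CDR3 motifs, public sequences realised by convergent
# recombination, biased V/J usage, dual and unproductive chains and
# log-normal read supports, emitted in the same rearrangement dialect the
# ingestion module reads.

#' Specify a planted CDR3 motif
#'
#' A motif template is a full CDR3 amino-acid string in which `.` marks a
#' variable slot; each slot draws uniformly from the corresponding residue
#' pool.  Convergent positions have their codon drawn uniformly from the
#' residue's full codon set, so members with identical amino acids differ in
#' nucleotides with positive probability (convergent recombination); all
#' other positions use a fixed canonical codon per residue.
#'
#' @param name Motif label used in the truth table.
#' @param chain_mode `"alpha"`, `"beta"` or `"paired"`.
#' @param template_alpha,template_beta Templates (full CDR3, IMGT 105-117).
#' @param pools_alpha,pools_beta Character vector of residue pools, one
#'   string per `.` slot in template order.
#' @param v_alpha,j_alpha,v_beta,j_beta Gene-level V/J calls per chain.
#' @param prevalence Fraction of all clonotypes drawn from this motif.
#' @param epitope Epitope label planted in the truth and reference tables.
#' @param convergent_alpha,convergent_beta Integer template positions with
#'   convergent codon draws.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(name, chain_mode,
                       template_alpha = NULL, pools_alpha = character(),
                       template_beta = NULL, pools_beta = character(),
                       v_alpha = NA_character_, j_alpha = NA_character_,
                       v_beta = NA_character_, j_beta = NA_character_,
                       prevalence, epitope = NA_character_,
                       convergent_alpha = integer(),
                       convergent_beta = integer()) {
  stopifnot(chain_mode %in% c("alpha", "beta", "paired"),
            prevalence >= 0, prevalence <= 1)
  check_template <- function(tmpl, pools) {
    if (is.null(tmpl)) return()
    n_slots <- stringr::str_count(tmpl, stringr::fixed("."))
    if (n_slots != length(pools)) {
      abort("one residue pool is needed per '.' slot of the template",
            class = "tcrmotifs_validation_error")
    }
  }
  check_template(template_alpha, pools_alpha)
  check_template(template_beta, pools_beta)
  structure(list(name = name, chain_mode = chain_mode,
                 template_alpha = template_alpha, pools_alpha = pools_alpha,
                 template_beta = template_beta, pools_beta = pools_beta,
                 v_alpha = v_alpha, j_alpha = j_alpha,
                 v_beta = v_beta, j_beta = j_beta,
                 prevalence = prevalence, epitope = epitope,
                 convergent_alpha = as.integer(convergent_alpha),
                 convergent_beta = as.integer(convergent_beta)),
            class = "motif_spec")
}

#' Render a planted motif spec as a matchable motif row
#'
#' Converts a [motif_spec()] into the one-row tibble layout used by
#' [match_motif()], with `.` slots as wildcards, so that planted members can
#' be checked against their own motif.
#'
#' @param spec A `motif_spec`.
#' @return One-row tibble.
#' @export
as_motif_row <- function(spec) {
  tibble::tibble(name = spec$name, chain = spec$chain_mode,
                 pattern_alpha = spec$template_alpha %||% NA_character_,
                 pattern_beta = spec$template_beta %||% NA_character_,
                 v_alpha = spec$v_alpha, v_beta = spec$v_beta,
                 j_alpha = spec$j_alpha, j_beta = spec$j_beta,
                 v_match = "gene")
}

#' Default planted motif set
#'
#' A dominant paired motif shaped like the celiac R-motif family (an
#' `ASS.R.TDTQY`-type beta on TRBV7-2 paired with a TRAV26-1 alpha, at 10.5
#' percent prevalence) plus five minor single-chain and paired motifs at
#' 0.5-1 percent.
#'
#' @return List of `motif_spec` objects.
#' @export
default_planted_motifs <- function() {
  list(
    motif_spec("R-analog", "paired",
               template_alpha = "IV.NDYKLSTF", pools_alpha = "RSGN",
               template_beta = "ASS.R.TDTQY", pools_beta = c("ILVFYG", "ASTG"),
               v_alpha = "TRAV26-1", j_alpha = "TRAJ20",
               v_beta = "TRBV7-2", j_beta = "TRBJ2-3",
               prevalence = 0.105, epitope = "DQ2.5-glia-a2",
               convergent_beta = 5L),
    motif_spec("alpha-NTGNQ", "alpha",
               template_alpha = "AV.NTGNQFYF", pools_alpha = "RSD",
               v_alpha = "TRAV35", j_alpha = "TRAJ49",
               prevalence = 0.010, epitope = "DQ2.5-glia-a1a",
               convergent_alpha = 3L),
    motif_spec("alpha-TSGTY", "alpha",
               template_alpha = "ALS.TSGTYKYIF", pools_alpha = "EDG",
               v_alpha = "TRAV12-2", j_alpha = "TRAJ40",
               prevalence = 0.008, epitope = "DQ2.5-glia-o1"),
    motif_spec("beta-GTGEL", "beta",
               template_beta = "ASS.GTGELFF", pools_beta = "QEKR",
               v_beta = "TRBV9", j_beta = "TRBJ2-2",
               prevalence = 0.010, epitope = "DQ2.5-glia-o2",
               convergent_beta = 4L),
    motif_spec("beta-GQGNT", "beta",
               template_beta = "ASG.GQGNTEAFF", pools_beta = "TRL",
               v_beta = "TRBV19", j_beta = "TRBJ1-1",
               prevalence = 0.006, epitope = "DQ2.5-glia-a1a"),
    motif_spec("paired-NNND", "paired",
               template_alpha = "AGA.NNNDMRF", pools_alpha = "GSA",
               template_beta = "ASSP.SGNTIYF", pools_beta = "DRG",
               v_alpha = "TRAV29/DV5", j_alpha = "TRAJ43",
               v_beta = "TRBV5-1", j_beta = "TRBJ1-3",
               prevalence = 0.005, epitope = "DQ2.5-glia-o2")
  )
}

default_v_freqs <- function(chain) {
  if (chain == "alpha") {
    major <- c("TRAV26-1" = 0.10, "TRAV4" = 0.07, "TRAV35" = 0.06,
               "TRAV12-2" = 0.05, "TRAV12-3" = 0.04, "TRAV13-1" = 0.04,
               "TRAV8-3" = 0.03, "TRAV29/DV5" = 0.03, "TRAV23/DV6" = 0.03,
               "TRAV14/DV4" = 0.03, "TRAV38-2/DV8" = 0.02, "TRAV19" = 0.02,
               "TRAV21" = 0.02, "TRAV5" = 0.02, "TRAV9-2" = 0.02)
    minor <- c("TRAV1-2", "TRAV2", "TRAV3", "TRAV6", "TRAV8-1", "TRAV10",
               "TRAV16", "TRAV17", "TRAV18", "TRAV20", "TRAV24", "TRAV25",
               "TRAV27", "TRAV30", "TRAV34", "TRAV36/DV7", "TRAV39",
               "TRAV41")
  } else {
    major <- c("TRBV7-2" = 0.10, "TRBV29-1" = 0.07, "TRBV20-1" = 0.06,
               "TRBV5-1" = 0.05, "TRBV19" = 0.05, "TRBV9" = 0.04,
               "TRBV6-1" = 0.03, "TRBV7-3" = 0.03, "TRBV28" = 0.03,
               "TRBV2" = 0.03, "TRBV4-1" = 0.02, "TRBV10-3" = 0.02,
               "TRBV11-2" = 0.02, "TRBV12-3" = 0.02, "TRBV18" = 0.02)
    minor <- c("TRBV3-1", "TRBV5-4", "TRBV5-6", "TRBV6-2", "TRBV6-5",
               "TRBV7-6", "TRBV7-8", "TRBV7-9", "TRBV9-1", "TRBV10-2",
               "TRBV13", "TRBV14", "TRBV15", "TRBV16", "TRBV24-1",
               "TRBV25-1", "TRBV27", "TRBV30")
  }
  rest <- (1 - sum(major)) / length(minor)
  c(major, setNames(rep(rest, length(minor)), minor))
}

default_j_freqs <- function(chain) {
  if (chain == "alpha") {
    major <- c("TRAJ20" = 0.06, "TRAJ49" = 0.05, "TRAJ40" = 0.05,
               "TRAJ43" = 0.04)
    minor <- paste0("TRAJ", c(4, 6, 8, 9, 12, 13, 16, 21, 23, 26, 28, 30,
                              33, 34, 37, 39, 42, 44, 45, 47, 48, 52, 53,
                              54, 57))
    rest <- (1 - sum(major)) / length(minor)
    c(major, setNames(rep(rest, length(minor)), minor))
  } else {
    c("TRBJ2-3" = 0.15, "TRBJ2-1" = 0.12, "TRBJ1-1" = 0.10,
      "TRBJ2-7" = 0.10, "TRBJ1-2" = 0.08, "TRBJ2-5" = 0.08,
      "TRBJ1-5" = 0.07, "TRBJ2-2" = 0.07, "TRBJ1-3" = 0.06,
      "TRBJ1-6" = 0.06, "TRBJ1-4" = 0.05, "TRBJ2-4" = 0.03,
      "TRBJ2-6" = 0.03)
  }
}

# CDR3-like residue composition for background middles
aa_composition <- function() {
  w <- c(A = 6, C = 1, D = 4, E = 4, F = 3, G = 8, H = 2, I = 3, K = 3,
         L = 6, M = 1, N = 4, P = 3, Q = 4, R = 6, S = 9, T = 6, V = 4,
         W = 1, Y = 4)
  w / sum(w)
}

#' Configure the synthetic repertoire generator
#'
#' Defaults emulate the structure of a tetramer-sorted gluten-specific
#' single-cell cohort: 30 patients with 20-200 clonotypes each, biased V/J
#' usage with the dominant TRAV26-1:TRBV7-2 pairing at roughly 12 percent of
#' clonotypes, a full CDR3 length distribution with mean about 12.6
#' residues, dual productive alpha at 6.9 percent (beta 0.2 percent),
#' unproductive alpha at 16.1 percent (beta 3.5 percent), and log-normal
#' read supports with about 5 percent of chains below the read-50 filter.
#'
#' @param n_patients Number of patients.
#' @param clonotypes_per_patient Either a length-2 integer range for a
#'   uniform draw or a vector of exact per-patient counts.
#' @param planted_motifs List of [motif_spec()]s (may be empty).
#' @param public_fraction Target fraction of non-motif clonotypes carrying a
#'   cross-patient shared chain.
#' @param public_multiplicity Named probabilities of patients-per-public
#'   group.
#' @param dual_alpha_rate,dual_beta_rate,unproductive_alpha_rate,unproductive_beta_rate
#'   Per-clonotype / per-cell chain rates.
#' @param ambiguous_v_rate Fraction of background chains reported with an
#'   ambiguous two-gene V call.
#' @param v_freqs,j_freqs Named per-chain frequency tables (lists with
#'   `alpha`, `beta`); normalised on input.
#' @param cdr3_length_probs Named probabilities over full CDR3 lengths.
#' @param read_meanlog,read_sdlog Log-normal read-support parameters.
#' @param cells_lambda Cells per clonotype are `1 + Poisson(cells_lambda)`.
#' @param reference_clones_per_motif Reference clones with known epitope
#'   emitted per planted motif.
#' @param irgp_meanlog,irgp_sdlog,irgp_public_shift Surrogate
#'   generation-probability model (log scale); public chains are shifted up.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `tcr_sim_config` list.
#' @export
synthetic_config <- function(n_patients = 30L,
                             clonotypes_per_patient = c(20L, 200L),
                             planted_motifs = default_planted_motifs(),
                             public_fraction = 0.37,
                             public_multiplicity = c("2" = 0.60, "3" = 0.25,
                                                     "4" = 0.10, "5" = 0.05),
                             dual_alpha_rate = 0.069,
                             dual_beta_rate = 0.002,
                             unproductive_alpha_rate = 0.161,
                             unproductive_beta_rate = 0.035,
                             ambiguous_v_rate = 0.01,
                             v_freqs = list(alpha = default_v_freqs("alpha"),
                                            beta = default_v_freqs("beta")),
                             j_freqs = list(alpha = default_j_freqs("alpha"),
                                            beta = default_j_freqs("beta")),
                             cdr3_length_probs = c("10" = 0.005, "11" = 0.20,
                                                   "12" = 0.30, "13" = 0.25,
                                                   "14" = 0.14, "15" = 0.08,
                                                   "16" = 0.025),
                             read_meanlog = log(50) + 1.645 * 1.1,
                             read_sdlog = 1.1,
                             cells_lambda = 1.3,
                             reference_clones_per_motif = 5L,
                             irgp_meanlog = -25, irgp_sdlog = 2,
                             irgp_public_shift = 1.5,
                             seed = 1L) {
  rates <- c(public_fraction, dual_alpha_rate, dual_beta_rate,
             unproductive_alpha_rate, unproductive_beta_rate,
             ambiguous_v_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "tcrmotifs_validation_error")
  }
  prev <- sum(vapply(planted_motifs, function(m) m$prevalence, 0))
  if (prev > 1) {
    abort("planted motif prevalences sum to more than 1",
          class = "tcrmotifs_validation_error")
  }
  norm <- function(x) x / sum(x)
  cfg <- list(n_patients = as.integer(n_patients),
              clonotypes_per_patient = clonotypes_per_patient,
              planted_motifs = planted_motifs,
              public_fraction = public_fraction,
              public_multiplicity = norm(public_multiplicity),
              dual_alpha_rate = dual_alpha_rate,
              dual_beta_rate = dual_beta_rate,
              unproductive_alpha_rate = unproductive_alpha_rate,
              unproductive_beta_rate = unproductive_beta_rate,
              ambiguous_v_rate = ambiguous_v_rate,
              v_freqs = lapply(v_freqs, norm),
              j_freqs = lapply(j_freqs, norm),
              cdr3_length_probs = norm(cdr3_length_probs),
              read_meanlog = read_meanlog, read_sdlog = read_sdlog,
              cells_lambda = cells_lambda,
              reference_clones_per_motif = as.integer(reference_clones_per_motif),
              irgp_meanlog = irgp_meanlog, irgp_sdlog = irgp_sdlog,
              irgp_public_shift = irgp_public_shift,
              seed = as.integer(seed))
  class(cfg) <- "tcr_sim_config"
  cfg
}

#' Generate a CDR3 nucleotide sequence for an amino-acid string
#'
#' Non-convergent positions use one fixed canonical codon per residue;
#' convergent positions draw uniformly from the residue's full codon set
#' under the standard genetic code (arginine: six codons), so repeated calls
#' yield nucleotide variants encoding the same amino acids.
#'
#' @param aa Amino-acid string.
#' @param convergent_positions Integer positions with uniform codon draws.
#' @return List with `nt` and `aa` (the input); `translate_nt(nt)` equals
#'   `aa`.
#' @export
generate_cdr3_nt <- function(aa, convergent_positions = integer()) {
  res <- strsplit(aa, "")[[1]]
  if (!all(res %in% c(AA_ALPHABET, "*"))) {
    abort("invalid residue in amino-acid string",
          class = "tcrmotifs_validation_error")
  }
  codons <- canonical_codon(aa)
  for (p in convergent_positions) {
    opts <- codons_of(res[p])
    codons[p] <- opts[sample.int(length(opts), 1L)]
  }
  list(nt = paste(codons, collapse = ""), aa = aa)
}

sample_gene <- function(freqs, n) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

background_cdr3 <- function(len, v_gene, j_gene, comp = aa_composition()) {
  first2 <- c("AS", "AV", "AT", "AG", "AL", "SA")[
    (sum(utf8ToInt(v_gene)) %% 6L) + 1L]
  last1 <- c("F", "Y", "T", "H")[(sum(utf8ToInt(j_gene)) %% 4L) + 1L]
  mid <- paste(sample(names(comp), len - 3L, replace = TRUE, prob = comp),
               collapse = "")
  paste0(first2, mid, last1)
}

instantiate_template <- function(tmpl, pools) {
  res <- strsplit(tmpl, "")[[1]]
  slots <- which(res == ".")
  for (k in seq_along(slots)) {
    pool <- strsplit(pools[k], "")[[1]]
    res[slots[k]] <- pool[sample.int(length(pool), 1L)]
  }
  paste(res, collapse = "")
}

#' Generate a synthetic multi-patient repertoire
#'
#' Draws clonotypes per patient, plants motif members and public groups,
#' expands clonotypes into cells and chain reads, and emits the
#' rearrangement table alongside a reference clone table with known epitope
#' specificity, a per-clonotype surrogate generation-probability table and
#' the ground-truth labels.  Fully deterministic given `config$seed`.
#'
#' Public groups are realised by convergent recombination: all members of a
#' group share one chain's amino-acid identity across at least two patients
#' while every codon of that chain is drawn uniformly from the residue's
#' codon set, so the nucleotide sequences differ with positive probability.
#' The public channel operates on non-motif clonotypes; planted motifs can
#' create additional cross-patient sharing of their own through their
#' conserved templates.
#'
#' @param config A [synthetic_config()].
#' @return A `tcr_repertoire_sim` list: `rearrangements`,
#'   `reference_clones`, `irgp`, `truth`, `config`.
#' @export
generate_repertoire <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "tcr_sim_config"))
  with_seed(config$seed, generate_repertoire_impl(config))
}

generate_repertoire_impl <- function(cfg) {
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  cpp <- cfg$clonotypes_per_patient
  n_ct_per <- if (length(cpp) == 2L && cfg$n_patients != 2L) {
    sample(seq(cpp[1], cpp[2]), cfg$n_patients, replace = TRUE)
  } else if (length(cpp) == cfg$n_patients) {
    as.integer(cpp)
  } else {
    sample(seq(cpp[1], cpp[2]), cfg$n_patients, replace = TRUE)
  }
  n <- sum(n_ct_per)
  ct <- tibble::tibble(synth_id = sprintf("S%05d", seq_len(n)),
                       patient_id = rep(patients, n_ct_per))

  # --- motif membership -------------------------------------------------
  specs <- cfg$planted_motifs
  prev <- vapply(specs, function(m) m$prevalence, 0)
  u <- runif(n)
  motif_idx <- rep(0L, n)
  if (length(specs) > 0L) {
    br <- cumsum(prev)
    for (k in rev(seq_along(specs))) motif_idx[u < br[k]] <- k
  }

  # --- chain identities (first pass: motifs + background) ---------------
  lens <- as.integer(names(cfg$cdr3_length_probs))
  draw_background <- function(chain, m) {
    v <- sample_gene(cfg$v_freqs[[chain]], m)
    j <- sample_gene(cfg$j_freqs[[chain]], m)
    len <- sample(lens, m, replace = TRUE, prob = cfg$cdr3_length_probs)
    aa <- vapply(seq_len(m), function(i) background_cdr3(len[i], v[i], j[i]),
                 "")
    tibble::tibble(v = v, j = j, aa = aa)
  }

  beta <- draw_background("beta", n)
  alpha <- draw_background("alpha", n)
  conv_beta <- vector("list", n)
  conv_alpha <- vector("list", n)
  for (i in seq_len(n)) {
    k <- motif_idx[i]
    if (k > 0L) {
      sp <- specs[[k]]
      if (!is.null(sp$template_beta)) {
        beta$aa[i] <- instantiate_template(sp$template_beta, sp$pools_beta)
        beta$v[i] <- sp$v_beta
        beta$j[i] <- sp$j_beta
        conv_beta[[i]] <- sp$convergent_beta
      }
      if (!is.null(sp$template_alpha)) {
        alpha$aa[i] <- instantiate_template(sp$template_alpha, sp$pools_alpha)
        alpha$v[i] <- sp$v_alpha
        alpha$j[i] <- sp$j_alpha
        conv_alpha[[i]] <- sp$convergent_alpha
      }
    }
  }

  # --- public groups: top the sharing up to the overall target ----------
  # motif templates already create cross-patient identical chains; count
  # the clonotypes involved and mark only as many background clonotypes as
  # needed so the overall shared fraction approaches cfg$public_fraction
  shared_by_key <- function(tab) {
    key <- paste(tab$v, tab$j, tab$aa, sep = "|")
    pat_per_key <- tapply(ct$patient_id, key,
                          function(p) length(unique(p)))
    key %in% names(pat_per_key)[pat_per_key >= 2L]
  }
  already <- shared_by_key(beta) | shared_by_key(alpha)
  n_target <- round(cfg$public_fraction * n)
  n_needed <- max(0L, n_target - sum(already))
  eligible <- which(motif_idx == 0L & !already)
  marked_idx <- if (length(eligible) > 0L && n_needed > 0L) {
    sample(eligible, min(n_needed, length(eligible)))
  } else {
    integer(0)
  }
  marked <- seq_len(n) %in% marked_idx
  group_id <- rep(NA_integer_, n)
  queue <- sample(which(marked))
  gid <- 0L
  while (length(queue) >= 2L) {
    m <- as.integer(sample(names(cfg$public_multiplicity), 1L,
                           prob = cfg$public_multiplicity))
    take <- queue[1L]
    seen <- ct$patient_id[take]
    rest <- queue[-1L]
    for (q in rest) {
      if (length(take) >= m) break
      if (!ct$patient_id[q] %in% seen) {
        take <- c(take, q)
        seen <- c(seen, ct$patient_id[q])
      }
    }
    if (length(take) >= 2L) {
      gid <- gid + 1L
      group_id[take] <- gid
    }
    queue <- setdiff(queue, take)
  }
  marked <- !is.na(group_id)

  # group identities: one shared chain per group
  n_groups <- gid
  grp <- if (n_groups > 0L) {
    lens <- as.integer(names(cfg$cdr3_length_probs))
    chain <- ifelse(runif(n_groups) < 0.5, "alpha", "beta")
    v <- ifelse(chain == "alpha",
                sample_gene(cfg$v_freqs$alpha, n_groups),
                sample_gene(cfg$v_freqs$beta, n_groups))
    j <- ifelse(chain == "alpha",
                sample_gene(cfg$j_freqs$alpha, n_groups),
                sample_gene(cfg$j_freqs$beta, n_groups))
    len <- sample(lens, n_groups, replace = TRUE,
                  prob = cfg$cdr3_length_probs)
    aa <- vapply(seq_len(n_groups),
                 function(g) background_cdr3(len[g], v[g], j[g]), "")
    tibble::tibble(group = seq_len(n_groups), chain = chain, v = v, j = j,
                   aa = aa)
  } else {
    tibble::tibble(group = integer(), chain = character(), v = character(),
                   j = character(), aa = character())
  }

  # overwrite the shared chain of grouped clonotypes; every codon of a
  # public chain is drawn convergently
  for (i in which(marked)) {
    g <- grp[grp$group == group_id[i], ]
    if (g$chain == "beta") {
      beta$aa[i] <- g$aa
      beta$v[i] <- g$v
      beta$j[i] <- g$j
      conv_beta[[i]] <- seq_len(nchar(g$aa))
    } else {
      alpha$aa[i] <- g$aa
      alpha$v[i] <- g$v
      alpha$j[i] <- g$j
      conv_alpha[[i]] <- seq_len(nchar(g$aa))
    }
  }

  beta$nt <- vapply(seq_len(n), function(i) {
    generate_cdr3_nt(beta$aa[i], conv_beta[[i]] %||% integer())$nt
  }, "")
  alpha$nt <- vapply(seq_len(n), function(i) {
    generate_cdr3_nt(alpha$aa[i], conv_alpha[[i]] %||% integer())$nt
  }, "")

  # enforce distinct beta keys within a patient (clonotype identity)
  for (pass in 1:5) {
    key <- paste(ct$patient_id, beta$v, beta$j, beta$nt)
    dup <- duplicated(key)
    if (!any(dup)) break
    for (i in which(dup)) {
      beta$nt[i] <- generate_cdr3_nt(beta$aa[i],
                                     seq_len(nchar(beta$aa[i])))$nt
    }
  }

  # dual chains (clonotype level)
  dual_alpha <- runif(n) < cfg$dual_alpha_rate
  dual_beta <- runif(n) < cfg$dual_beta_rate
  alpha2 <- draw_background("alpha", n)
  alpha2$nt <- vapply(seq_len(n),
                      function(i) generate_cdr3_nt(alpha2$aa[i])$nt, "")
  beta2 <- draw_background("beta", n)
  beta2$nt <- vapply(seq_len(n),
                     function(i) generate_cdr3_nt(beta2$aa[i])$nt, "")

  # ambiguous V reporting on background chains only
  amb_beta <- motif_idx == 0L & !(marked & grp$chain[group_id] %in% "beta") &
    runif(n) < cfg$ambiguous_v_rate
  amb_alpha <- motif_idx == 0L &
    !(marked & grp$chain[group_id] %in% "alpha") &
    runif(n) < cfg$ambiguous_v_rate
  amb_beta[is.na(amb_beta)] <- FALSE
  amb_alpha[is.na(amb_alpha)] <- FALSE

  # --- expand into cells and chain rows ---------------------------------
  n_cells <- 1L + rpois(n, cfg$cells_lambda)
  ct$n_cells <- n_cells
  total_cells <- sum(n_cells)
  cell_ct <- rep(seq_len(n), n_cells)
  cell_id <- sprintf("%s_C%05d", ct$patient_id[cell_ct],
                     seq_len(total_cells))

  draw_reads <- function(m) {
    pmax(1, round(rlnorm(m, cfg$read_meanlog, cfg$read_sdlog)))
  }
  second_gene <- function(freqs, g) {
    # a plausible alternative call for ambiguous reporting
    nm <- names(freqs)
    alt <- nm[nm != g][1L]
    alt
  }
  vcall <- function(v, amb, freqs) {
    out <- paste0(v, "*01")
    if (any(amb)) {
      alt <- vapply(v[amb], function(g) second_gene(freqs, g), "")
      out[amb] <- paste0(v[amb], "*01,", alt, "*01")
    }
    out
  }

  chain_rows <- function(idx_cells, chain, tab, amb, freqs) {
    m <- length(idx_cells)
    tibble::tibble(
      cell_id = cell_id[idx_cells], patient_id = ct$patient_id[cell_ct[idx_cells]],
      locus = if (chain == "alpha") "TRA" else "TRB",
      v_call = vcall(tab$v[cell_ct[idx_cells]], amb[cell_ct[idx_cells]],
                     freqs),
      j_call = paste0(tab$j[cell_ct[idx_cells]], "*01"),
      junction = tab$nt[cell_ct[idx_cells]],
      junction_aa = tab$aa[cell_ct[idx_cells]],
      duplicate_count = draw_reads(m), productive = "T")
  }

  all_cells <- seq_len(total_cells)
  beta_rows <- chain_rows(all_cells, "beta", beta, amb_beta,
                          cfg$v_freqs$beta)
  alpha_rows <- chain_rows(all_cells, "alpha", alpha, amb_alpha,
                           cfg$v_freqs$alpha)
  # secondary (dual) chains carry a fraction of the primary chain's reads,
  # so the primary chain always defines the clonotype
  dual_frac <- function(primary_reads) {
    pmax(1, round(primary_reads * runif(length(primary_reads), 0.15, 0.9)))
  }
  da_cells <- all_cells[dual_alpha[cell_ct]]
  db_cells <- all_cells[dual_beta[cell_ct]]
  alpha2_rows <- chain_rows(da_cells, "alpha", alpha2, rep(FALSE, n),
                            cfg$v_freqs$alpha)
  alpha2_rows$duplicate_count <- dual_frac(
    alpha_rows$duplicate_count[da_cells])
  beta2_rows <- chain_rows(db_cells, "beta", beta2, rep(FALSE, n),
                           cfg$v_freqs$beta)
  beta2_rows$duplicate_count <- dual_frac(
    beta_rows$duplicate_count[db_cells])
  rows <- list(beta_rows, alpha_rows, alpha2_rows, beta2_rows)

  # unproductive extra chains, per cell
  unprod_rows <- function(chain, rate) {
    sel <- which(runif(total_cells) < rate)
    if (length(sel) == 0L) return(NULL)
    bg <- draw_background(chain, length(sel))
    aa <- vapply(bg$aa, function(s) {
      p <- max(3L, nchar(s) %/% 2L)
      paste0(substr(s, 1, p - 1L), "*", substr(s, p + 1L, nchar(s)))
    }, "", USE.NAMES = FALSE)
    nt <- vapply(aa, function(s) generate_cdr3_nt(s)$nt, "",
                 USE.NAMES = FALSE)
    tibble::tibble(cell_id = cell_id[sel],
                   patient_id = ct$patient_id[cell_ct[sel]],
                   locus = if (chain == "alpha") "TRA" else "TRB",
                   v_call = paste0(bg$v, "*01"),
                   j_call = paste0(bg$j, "*01"),
                   junction = nt, junction_aa = aa,
                   duplicate_count = draw_reads(length(sel)),
                   productive = "F")
  }
  rows <- c(rows, list(unprod_rows("alpha", cfg$unproductive_alpha_rate),
                       unprod_rows("beta", cfg$unproductive_beta_rate)))
  rearr <- dplyr::bind_rows(rows) %>%
    arrange(.data$cell_id, .data$locus, dplyr::desc(.data$duplicate_count))

  # --- truth ------------------------------------------------------------
  truth <- tibble::tibble(
    synth_id = ct$synth_id, patient_id = ct$patient_id,
    v_beta = beta$v, j_beta = beta$j, cdr3_nt_beta = beta$nt,
    cdr3_aa_beta = beta$aa, v_alpha = alpha$v, j_alpha = alpha$j,
    cdr3_aa_alpha = alpha$aa,
    motif = ifelse(motif_idx > 0L,
                   vapply(motif_idx, function(k) {
                     if (k > 0L) specs[[k]]$name else NA_character_
                   }, ""), NA_character_),
    epitope = ifelse(motif_idx > 0L,
                     vapply(motif_idx, function(k) {
                       if (k > 0L) specs[[k]]$epitope else NA_character_
                     }, ""), NA_character_),
    public_group = group_id,
    public_chain = ifelse(marked, grp$chain[group_id], NA_character_),
    dual_alpha = dual_alpha, dual_beta = dual_beta, n_cells = n_cells)

  # --- reference clones with known epitopes -----------------------------
  ref <- list()
  if (length(specs) > 0L && cfg$reference_clones_per_motif > 0L) {
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      for (r in seq_len(cfg$reference_clones_per_motif)) {
        a <- if (!is.null(sp$template_alpha)) {
          list(v = sp$v_alpha, j = sp$j_alpha,
               aa = instantiate_template(sp$template_alpha, sp$pools_alpha))
        } else {
          bg <- draw_background("alpha", 1L)
          list(v = bg$v, j = bg$j, aa = bg$aa)
        }
        b <- if (!is.null(sp$template_beta)) {
          list(v = sp$v_beta, j = sp$j_beta,
               aa = instantiate_template(sp$template_beta, sp$pools_beta))
        } else {
          bg <- draw_background("beta", 1L)
          list(v = bg$v, j = bg$j, aa = bg$aa)
        }
        ref[[length(ref) + 1L]] <- tibble::tibble(
          clone_id = sprintf("TCC_%s_%02d", sp$name, r),
          patient_id = sprintf("TCCP%02d", ((r - 1L) %% 5L) + 1L),
          epitope = sp$epitope,
          v_alpha = a$v, j_alpha = a$j, cdr3_aa_alpha = a$aa,
          v_beta = b$v, j_beta = b$j, cdr3_aa_beta = b$aa)
      }
    }
  }
  reference_clones <- if (length(ref)) dplyr::bind_rows(ref) else
    tibble::tibble(clone_id = character(), patient_id = character(),
                   epitope = character(), v_alpha = character(),
                   j_alpha = character(), cdr3_aa_alpha = character(),
                   v_beta = character(), j_beta = character(),
                   cdr3_aa_beta = character())

  # --- surrogate generation probabilities -------------------------------
  shift_a <- ifelse(!is.na(truth$public_chain) & truth$public_chain == "alpha",
                    cfg$irgp_public_shift, 0)
  shift_b <- ifelse(!is.na(truth$public_chain) & truth$public_chain == "beta",
                    cfg$irgp_public_shift, 0)
  irgp <- tibble::tibble(
    synth_id = ct$synth_id, patient_id = ct$patient_id,
    v_beta = beta$v, j_beta = beta$j, cdr3_nt_beta = beta$nt,
    level = "aa",
    p_alpha = exp(rnorm(n, cfg$irgp_meanlog + shift_a, cfg$irgp_sdlog)),
    p_beta = exp(rnorm(n, cfg$irgp_meanlog + shift_b, cfg$irgp_sdlog)))

  structure(list(rearrangements = rearr,
                 reference_clones = reference_clones,
                 irgp = irgp, truth = truth, config = cfg),
            class = "tcr_repertoire_sim")
}

#' @export
print.tcr_repertoire_sim <- function(x, ...) {
  cat(sprintf(paste0("<tcr_repertoire_sim> %d patients, %d clonotypes, ",
                     "%d chain rows\n"),
              x$config$n_patients, nrow(x$truth), nrow(x$rearrangements)))
  invisible(x)
}

#' Write a synthetic repertoire bundle to disk
#'
#' Emits the rearrangement, reference-clone, surrogate
#' generation-probability and truth tables as TSV plus a JSON echo of the
#' configuration (with its seed).
#'
#' @param sim A `tcr_repertoire_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_repertoire <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$rearrangements, file.path(dir, "rearrangements.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$reference_clones,
                   file.path(dir, "reference_clones.tsv"), progress = FALSE)
  readr::write_tsv(sim$irgp, file.path(dir, "irgp.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cfg <- sim$config
  cfg$planted_motifs <- lapply(cfg$planted_motifs, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
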