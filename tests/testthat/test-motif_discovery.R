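# Recursive motif extraction, alignment, regex construction, matching and
# established-motif exclusion.

# small beta clustering fixture: a planted near-identical family plus
# scattered background sequences
beta_fixture <- function(family_v = "TRBV7-2", n_family = 6,
                         background = 8, seed = 21) {
  set.seed(seed)
  fam <- vapply(seq_len(n_family), function(i) {
    paste0("ASS", sample(c("I", "L", "V"), 1), "R",
           sample(c("A", "S", "T"), 1), "TDTQY")
  }, "")
  bg <- vapply(seq_len(background), function(i) random_aa(12), "")
  make_clonotypes("P01", c(fam, bg),
                  c(rep_len(family_v, n_family), rep("TRBV20-1", background)))
}

discover_on <- function(ct, cutoff = 2, v_mode = "gene", min_leaves = 5L,
                        mode = "beta") {
  set <- prepare_clustering_set(ct, mode)
  tree <- upgma(cdr3_distances(set))
  discover_motifs(tree, set, cutoff, v_mode, min_leaves)
}

test_that("a V-coherent family below the cut-off becomes one candidate", {
  m <- discover_on(beta_fixture())
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_members, 6L)
  expect_equal(m$v_beta, "TRBV7-2")
  expect_lte(m$node_height, 2)
  # recursion stopped at the family node: no sub-candidate of it
  expect_equal(length(unique(unlist(m$members))), 6L)
})

test_that("families below the minimum leaf count yield no candidate", {
  m <- discover_on(beta_fixture(n_family = 4))
  expect_equal(nrow(m), 0L)
})

test_that("mixed V genes fail gene mode but pass subgroup mode", {
  ct <- beta_fixture(n_family = 6)
  ct$v_beta[1:3] <- "TRBV7-3"
  ct$v_beta_subgroup[1:3] <- "TRBV7"
  gene <- discover_on(ct, v_mode = "gene")
  expect_equal(nrow(gene), 0L)
  sub <- discover_on(ct, v_mode = "subgroup")
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$v_beta, "TRBV7")
})

test_that("candidates of one run are leaf-disjoint and self-consistent", {
  set.seed(22)
  ct <- dplyr::bind_rows(
    beta_fixture(seed = 31),
    make_clonotypes("P02", vapply(1:6, function(i) {
      paste0("ASGQ", sample(c("T", "R", "L"), 1), "GQGNTEAFF")
    }, ""), "TRBV19"))
  ct$clonotype_id <- sprintf("CT%03d", seq_len(nrow(ct)))
  m <- discover_on(ct, cutoff = 2)
  expect_gte(nrow(m), 2L)
  all_members <- unlist(m$members)
  expect_equal(anyDuplicated(all_members), 0L)
  for (i in seq_len(nrow(m))) {
    members <- ct[match(m$members[[i]], ct$clonotype_id), ]
    expect_true(all(match_motif(m[i, ], members)))
  }
})

test_that("raising the cut-off never shrinks candidate coverage", {
  set.seed(23)
  ct <- beta_fixture(n_family = 10, background = 15)
  covered <- vapply(c(0, 1, 2, 4, 8), function(co) {
    m <- discover_on(ct, cutoff = co)
    length(unique(unlist(m$members)))
  }, 1L)
  expect_true(all(diff(covered) >= 0L))
})

test_that("progressive alignment keeps rows recoverable and handles indels", {
  same <- align_members(c("SIRATDTQ", "SIRATDTQ", "SIRATDTQ"))
  expect_equal(same, rep("SIRATDTQ", 3))
  gap <- align_members(c("SIRATDTQ", "SIRTDTQ"))
  expect_equal(nchar(gap[1]), nchar(gap[2]))
  expect_equal(sum(strsplit(gap[2], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", gap[2]), "SIRTDTQ")
  set.seed(24)
  seqs <- vapply(1:8, function(i) random_aa(sample(6:10, 1)), "")
  msa <- align_members(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_gte(nchar(msa[1]), max(nchar(seqs)))
  expect_equal(gsub("-", "", msa), seqs)
  expect_error(align_members(character()),
               class = "tcrmotifs_degenerate_input")
})

test_that("regex columns follow the group, wildcard and gap rules", {
  expect_equal(build_regex(c("ARDT", "AKDT")), "A[KRED]DT")
  expect_equal(build_regex(c("AYT", "AVT")), "A.T")
  expect_equal(build_regex(c("AST", "A-T")), "AS?T")
  # overlapping groups resolve by charged > polar > amphipathic > hydrophobic
  expect_equal(build_regex(c("AYT", "ACT")), "A[QNHSTYC]T")
  expect_equal(build_regex(c("AYT", "AMT")), "A[WYM]T")
  # variable and gapped column renders class-then-optional
  expect_equal(build_regex(c("AKT", "ART", "A-T")), "A[KRED]?T")
})

test_that("amino-acid groups cover the alphabet with the stated overlaps", {
  g <- amino_acid_groups()
  expect_setequal(unique(unlist(g)),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_true("Y" %in% g$polar && "Y" %in% g$amphipathic)
  expect_true("M" %in% g$amphipathic && "M" %in% g$hydrophobic)
})

test_that("motif matching needs both the anchored pattern and the V gene", {
  est <- established_motifs()
  r_motif <- est[est$name == "R-motif", ]
  subj <- make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-2")
  expect_true(match_motif(r_motif, subj))
  expect_true(match_motif(r_motif,
                          make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-3")))
  expect_false(match_motif(r_motif,
                           make_clonotypes("P01", "ASSIRATDTQY", "TRBV5-1")))
  expect_false(match_motif(r_motif,
                           make_clonotypes("P01", "ASSIRATDTQYF", "TRBV7-2")))
  ext <- est[est$name == "Extended R-motif", ]
  expect_true(match_motif(ext,
                          make_clonotypes("P01", "ASSLRWGEQF", "TRBV7-2")))
})

test_that("paired motifs require both chains; dual alphas may satisfy either", {
  est <- established_motifs()
  paired <- est[est$name == "Paired R-motif", ]
  good <- make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-2",
                          cdr3_aa_alpha = "IVSNDYKLSF")
  expect_true(match_motif(paired, good))
  wrong_alpha <- make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-2",
                                 cdr3_aa_alpha = "IVSNDYKLSF",
                                 v_alpha = "TRAV4")
  expect_false(match_motif(paired, wrong_alpha))
  # the second alpha of a dual clonotype can satisfy the alpha side
  rescued <- wrong_alpha
  rescued$dual_alpha <- TRUE
  rescued$v_alpha2 <- "TRAV26-1"
  rescued$v_alpha2_subgroup <- "TRAV26"
  rescued$cdr3_aa_alpha2 <- "IVRNDYKLSF"
  expect_true(match_motif(paired, rescued))
})

test_that("J constraints are stored but only enforced on request", {
  est <- established_motifs()
  r_motif <- est[est$name == "R-motif", ]
  subj <- make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-2", j_beta = "TRBJ1-1")
  expect_true(match_motif(r_motif, subj))
  expect_false(match_motif(r_motif, subj, enforce_j = TRUE))
})

test_that("the established library carries the canonical patterns", {
  est <- established_motifs()
  expect_setequal(est$name, c("R-motif", "Extended R-motif", "NDYKLS",
                              "Paired R-motif"))
  expect_equal(est$pattern_beta[est$name == "R-motif"], "ASS.R.TDTQY")
  expect_equal(est$pattern_beta[est$name == "Extended R-motif"], "ASS.R.*")
  expect_equal(est$pattern_alpha[est$name == "NDYKLS"], "I.NDYKLS")
  expect_equal(est$v_beta[est$name == "R-motif"], "TRBV7-2,TRBV7-3")
  expect_equal(est$v_alpha[est$name == "Paired R-motif"], "TRAV26-1")
})

test_that("established-motif exclusion applies the member-overlap threshold", {
  # six members, exactly three matching the R-motif
  ct <- make_clonotypes("P01",
                        c("ASSIRATDTQY", "ASSLRSTDTQY", "ASSVRTTDTQY",
                          "ASSIAATDTQY", "ASSLASTDTQY", "ASSVATTDTQY"),
                        "TRBV7-2")
  m <- discover_on(ct, cutoff = 4)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_members, 6L)
  removed <- exclude_established(m, ct, overlap_threshold = 0.5)
  expect_equal(nrow(removed), 0L)
  expect_equal(attr(removed, "excluded")$excluded_by, "R-motif")
  expect_equal(attr(removed, "excluded")$overlap, 0.5)
  kept <- exclude_established(m, ct, overlap_threshold = 0.6)
  expect_equal(nrow(kept), 1L)
  # fully matching candidates are removed, non-matching kept
  full <- discover_on(make_clonotypes("P01", c(
    "ASSIRATDTQY", "ASSLRSTDTQY", "ASSVRTTDTQY", "ASSIRSTDTQY",
    "ASSLRTTDTQY", "ASSVRATDTQY"), "TRBV7-2"), cutoff = 2)
  expect_equal(nrow(exclude_established(full, make_clonotypes("P01", c(
    "ASSIRATDTQY", "ASSLRSTDTQY", "ASSVRTTDTQY", "ASSIRSTDTQY",
    "ASSLRTTDTQY", "ASSVRATDTQY"), "TRBV7-2"))), 0L)
})

test_that("motif frequency counts matching clonotypes order-independently", {
  ct <- dplyr::bind_rows(
    make_clonotypes("P01", c("ASSIRATDTQY", "ASSLRSTDTQY"), "TRBV7-2"),
    make_clonotypes("P02", vapply(1:8, function(i) random_aa(12), ""),
                    "TRBV20-1"))
  ct$clonotype_id <- sprintf("CT%03d", seq_len(nrow(ct)))
  est <- established_motifs()
  fr <- motif_frequency(est[est$name == "R-motif", ], ct)
  expect_equal(fr$count, 2L)
  expect_equal(fr$fraction, 0.2)
  shuffled <- ct[sample(nrow(ct)), ]
  fr2 <- motif_frequency(est[est$name == "R-motif", ], shuffled)
  expect_equal(fr2$count, fr$count)
  none <- motif_frequency(est[est$name == "NDYKLS", ], ct)
  expect_equal(none$count, 0L)
  expect_equal(none$fraction, 0)
  expect_error(motif_frequency(est, ct[0, ]),
               class = "tcrmotifs_degenerate_input")
})

test_that("text logos tabulate residue counts per column", {
  logo <- text_logo(c("ARDT", "AKDT"))
  expect_length(logo, 4L)
  expect_match(logo[1], "A:2")
  expect_match(logo[2], "K:1")
})
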