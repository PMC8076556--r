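# V-usage, public sharing, epitope annotation, database search and the
# rank-sum comparison.

test_that("dual alphas contribute half weight and mass is conserved", {
  ct <- make_clonotypes("P01", "ASSIRATDTQY", "TRBV7-2",
                        cdr3_aa_alpha = "IVSNDYKLSF",
                        v_alpha = "TRAV26-1", dual_alpha = TRUE,
                        cdr3_aa_alpha2 = "ALSDTGNQFYF", v_alpha2 = "TRAV4",
                        j_alpha2 = "TRAJ49")
  u <- vgene_usage(ct, "TRAV")
  expect_equal(sort(u$gene), c("TRAV26-1", "TRAV4"))
  expect_equal(u$weight, c(0.5, 0.5))
  expect_equal(sum(u$freq), 1)
  up <- vgene_usage(ct, "paired")
  expect_setequal(up$gene, c("TRAV26-1:TRBV7-2", "TRAV4:TRBV7-2"))
  expect_equal(sum(up$freq), 1)
})

test_that("usage frequencies always sum to one under ambiguity and duals", {
  set.seed(31)
  n <- 60
  ct <- make_clonotypes("P01", vapply(1:n, function(i) random_aa(12), ""),
                        sample(c("TRBV7-2", "TRBV9", "TRBV19"), n, TRUE))
  ct$v_beta_ambiguous[sample(n, 6)] <- TRUE
  ct$dual_alpha[sample(n, 10)] <- TRUE
  ct$cdr3_aa_alpha2[ct$dual_alpha] <- vapply(
    seq_len(sum(ct$dual_alpha)), function(i) random_aa(12), "")
  ct$v_alpha2[ct$dual_alpha] <- "TRAV4"
  ct$j_alpha2[ct$dual_alpha] <- "TRAJ49"
  for (mode in c("TRAV", "TRBV", "paired")) {
    expect_equal(sum(vgene_usage(ct, mode)$freq), 1, tolerance = 1e-12)
  }
  # single-chain clonotypes give integer counts
  simple <- vgene_usage(ct[!ct$dual_alpha, ], "TRBV")
  expect_true(all(simple$weight == round(simple$weight)))
})

test_that("rare genes collapse into 'other' only when requested", {
  ct <- make_clonotypes("P01",
                        c("ASSIRATDTQY", "ASSLRSTDTQY", "ASSQGTAYEQY"),
                        c("TRBV7-2", "TRBV7-2", "TRBV9"))
  full <- vgene_usage(ct, "TRBV")
  expect_setequal(full$gene, c("TRBV7-2", "TRBV9"))
  collapsed <- vgene_usage(ct, "TRBV", collapse_min = 2)
  expect_setequal(collapsed$gene, c("TRBV7-2", "other"))
  expect_equal(sum(collapsed$freq), 1)
})

public_fixture <- function() {
  shared_nt <- generate_cdr3_nt("ASSIRATDTQY")$nt
  ct <- dplyr::bind_rows(
    make_clonotypes("P01", c("ASSIRATDTQY", "ASSAAATDTQY"), "TRBV7-2"),
    make_clonotypes("P02", "ASSIRATDTQY", "TRBV7-2"),
    make_clonotypes("P03", "ASSIRATDTQY", "TRBV9"))
  ct$clonotype_id <- sprintf("CT%03d", seq_len(nrow(ct)))
  ct
}

test_that("public records need two patients; the key includes V and J genes", {
  ct <- public_fixture()
  pub <- find_public_sequences(ct, "beta")
  shared <- pub[pub$cdr3_aa_beta == "ASSIRATDTQY" & pub$v_beta == "TRBV7-2", ]
  expect_equal(shared$n_patients, 2L)
  expect_equal(shared$patients[[1]], c("P01", "P02"))
  expect_true(shared$public)
  # the TRBV9 copy stays apart under the V/J/CDR3 key ...
  expect_equal(sum(pub$public), 1L)
  # ... but groups with the others under the CDR3-only key
  pub_cdr3 <- find_public_sequences(ct, mode = "beta", key = "cdr3")
  row <- pub_cdr3[pub_cdr3$cdr3_aa_beta == "ASSIRATDTQY", ]
  expect_equal(row$n_patients, 3L)
})

test_that("public counts are patient-order invariant and monotone", {
  set.seed(32)
  ct <- public_fixture()
  pub1 <- find_public_sequences(ct, "beta")
  pub2 <- find_public_sequences(ct[sample(nrow(ct)), ], "beta")
  expect_equal(sum(pub1$public), sum(pub2$public))
  # removing a patient never increases any record's patient count
  pub3 <- find_public_sequences(ct[ct$patient_id != "P02", ], "beta")
  expect_true(all(pub3$n_patients <= max(pub1$n_patients)))
  expect_equal(sum(pub3$public), 0L)
})

test_that("planted public groups are recovered exactly from synthetic truth", {
  sim <- generate_repertoire(synthetic_config(
    n_patients = 8, clonotypes_per_patient = c(30, 50),
    planted_motifs = list(), unproductive_alpha_rate = 0,
    unproductive_beta_rate = 0, read_meanlog = 8, seed = 33))
  # high read support and no unproductive chains: nothing is lost on ingest
  ct <- define_clonotypes(filter_chains(read_rearrangements(
    sim$rearrangements)))
  expect_equal(nrow(ct), nrow(sim$truth))
  pub <- dplyr::bind_rows(find_public_sequences(ct, "alpha"),
                          find_public_sequences(ct, "beta"))
  expect_equal(sum(pub$public),
               dplyr::n_distinct(sim$truth$public_group, na.rm = TRUE))
})

test_that("per-patient shared fractions and the median are computed", {
  ct <- public_fixture()
  pub <- dplyr::bind_rows(find_public_sequences(ct, "alpha"),
                          find_public_sequences(ct, "beta"))
  sf <- shared_fraction_per_patient(ct, pub)
  expect_equal(sf$fraction[sf$patient_id == "P01"], 0.5)
  expect_equal(sf$fraction[sf$patient_id == "P02"], 1)
  expect_equal(sf$fraction[sf$patient_id == "P03"], 0)
  expect_equal(attr(sf, "median"), 0.5)
  binned <- shared_fraction_per_patient(ct, pub, bins = c(0, 100, 200))
  expect_true("bin" %in% names(binned))
})

reference_fixture <- function() {
  tibble::tibble(
    clone_id = sprintf("TCC%02d", 1:4),
    patient_id = "TCCP01",
    epitope = c("DQ2.5-glia-a2", "DQ2.5-glia-a2", "DQ2.5-glia-o2",
                "DQ2.5-glia-a1a"),
    v_alpha = "TRAV26-1", j_alpha = "TRAJ20",
    cdr3_aa_alpha = c("IVSNDYKLSF", "IVRNDYKLSF", "IVSNDYKLSF",
                      "IVSNDYKLSF"),
    v_beta = "TRBV7-2", j_beta = "TRBJ2-3",
    cdr3_aa_beta = c("ASSIRATDTQY", "ASSLRSTDTQY", "ASSIRATDTQY",
                     "ASSQQQTDTQY"))
}

test_that("motifs inherit epitopes from matching reference clones", {
  ct <- make_clonotypes("P01", c("ASSIRATDTQY", "ASSLRSTDTQY", "ASSVRTTDTQY",
                                 "ASSIRSTDTQY", "ASSLRTTDTQY"), "TRBV7-2")
  set <- prepare_clustering_set(ct, "beta")
  tree <- upgma(cdr3_distances(set))
  m <- discover_motifs(tree, set, 2, "gene")
  ann <- annotate_epitopes(m, reference_fixture())
  expect_setequal(ann$epitope, c("DQ2.5-glia-a2", "DQ2.5-glia-o2"))
  expect_true(all(ann$evidence == "clone_exact"))
  # both epitopes accumulate on the same motif (cross-reactivity)
  expect_equal(length(unique(ann$target_id)), 1L)
  expect_error(annotate_epitopes(m, dplyr::select(reference_fixture(),
                                                  -epitope)),
               class = "tcrmotifs_format_error")
})

test_that("public pairs annotate as exact at distance 0 and similar at 1", {
  pub <- tibble::tibble(
    v_alpha = "TRAV26-1", j_alpha = "TRAJ20",
    cdr3_aa_alpha = c("IVSNDYKLSF", "IVSNDYKLSF"),
    v_beta = "TRBV7-2", j_beta = "TRBJ2-3",
    cdr3_aa_beta = c("ASSIRATDTQY", "ASSIRTTDTQY"))
  ann <- annotate_epitopes(pub, reference_fixture())
  first <- ann[grepl("ASSIRATDTQY", ann$target_id), ]
  expect_setequal(first$evidence[first$epitope == "DQ2.5-glia-a2"],
                  "clone_exact")
  second <- ann[grepl("ASSIRTTDTQY", ann$target_id), ]
  expect_true(all(second$evidence == "clone_similar"))
  # beta distance 1 from two clones sharing V genes
  expect_setequal(second$epitope, c("DQ2.5-glia-a2", "DQ2.5-glia-o2"))
})

test_that("database searches exclude disease-related rows then count", {
  est <- established_motifs()
  r_motif <- est[est$name == "R-motif", ]
  db <- tibble::tibble(
    chain = c("TRB", "TRB", "TRB", "TRB", "TRB", "TRA"),
    cdr3_aa = c("ASSIRATDTQY", "ASSLRSTDTQY", "ASSIRATDTQY", "ASSQGTAYEQY",
                "ASSIRATDTQY", "IVSNDYKLSF"),
    v_gene = c("TRBV7-2*01", "TRBV7-3", "TRBV5-1", "TRBV7-2", "TRBV7-2",
               "TRAV26-1"),
    epitope = c("influenza M1", "EBV BMLF1", "CMV pp65", "influenza M1",
                "gliadin peptide", "influenza M1"))
  out <- search_external_db(r_motif, db)
  # 5th row is excluded as gluten-related; 3rd fails the V constraint
  expect_equal(out$n_matches, 2L)
  none <- search_external_db(r_motif,
                             db[db$epitope == "gliadin peptide", ])
  expect_equal(none$n_matches, 0L)
  # planted fixture with four matching rows
  db4 <- tibble::tibble(chain = "TRB",
                        cdr3_aa = rep("ASSIRATDTQY", 4),
                        v_gene = rep(c("TRBV7-2", "TRBV7-3"), 2),
                        epitope = "influenza M1")
  expect_equal(search_external_db(r_motif, db4)$n_matches, 4L)
})

test_that("paired generation probability is the exact product with bounds", {
  expect_equal(paired_generation_probability(1e-8, 1e-9), 1e-17)
  expect_equal(paired_generation_probability(0.3, 0), 0)
  expect_equal(paired_generation_probability(1, 0.25), 0.25)
  p <- runif(10)
  q <- runif(10)
  expect_true(all(paired_generation_probability(p, q) <= pmin(p, q)))
  expect_error(paired_generation_probability(1.2, 0.5),
               class = "tcrmotifs_validation_error")
})

test_that("the exact rank-sum p equals the exhaustive labeling oracle", {
  out <- compare_public_private(c(3, 4, 5), c(1, 2))
  expect_equal(out$statistic, 6)
  expect_equal(out$p.value, 1 / choose(5, 3))
  # tie-free samples agree with the closed-form exact test
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(3:10, 1)
    n2 <- sample(3:10, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    ours <- compare_public_private(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # tied samples agree with a brute-force enumeration done here
  x <- c(1, 2, 2, 3)
  y <- c(2, 1, 1)
  ours <- compare_public_private(x, y)
  r <- rank(c(x, y))
  labelings <- combn(7, 4)
  U_all <- colSums(matrix(r[labelings], nrow = 4)) - 4 * 5 / 2
  U_obs <- sum(r[1:4]) - 4 * 5 / 2
  expect_equal(ours$statistic, U_obs)
  expect_equal(ours$p.value, mean(U_all >= U_obs))
})

test_that("the large-sample path matches the corrected normal approximation", {
  set.seed(42)
  x <- round(rnorm(40, 0.5), 1)   # rounding induces ties
  y <- round(rnorm(35), 1)
  ours <- compare_public_private(x, y)
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(compare_public_private(numeric(), 1:3),
               class = "tcrmotifs_degenerate_input")
})

test_that("a true shift is detected with high power", {
  set.seed(43)
  hits <- vapply(1:60, function(i) {
    compare_public_private(rnorm(100, 2), rnorm(100))$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
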