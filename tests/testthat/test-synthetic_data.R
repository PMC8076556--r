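# Ground-truth properties of the synthetic repertoire generator.

small_cfg <- function(...) {
  synthetic_config(n_patients = 6, clonotypes_per_patient = c(25, 45), ...)
}

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_repertoire(small_cfg(seed = 9))
  b <- generate_repertoire(small_cfg(seed = 9))
  expect_identical(a$rearrangements, b$rearrangements)
  expect_identical(a$truth, b$truth)
  expect_identical(a$irgp, b$irgp)
  c <- generate_repertoire(small_cfg(seed = 10))
  expect_false(identical(a$rearrangements, c$rearrangements))
})

test_that("the codon machinery reflects the standard genetic code", {
  expect_length(codons_of("R"), 6L)   # arginine degeneracy drives sharing
  expect_setequal(codons_of("R"),
                  c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
  expect_length(codons_of("M"), 1L)
  expect_error(codons_of("B"), class = "tcrmotifs_validation_error")
})

test_that("generated nucleotides translate back to their amino acids", {
  set.seed(51)
  for (i in 1:25) {
    aa <- random_aa(sample(8:15, 1))
    out <- generate_cdr3_nt(aa, convergent_positions = sample(nchar(aa), 2))
    expect_equal(translate_nt(out$nt), aa)
  }
  expect_error(generate_cdr3_nt("ASB1"),
               class = "tcrmotifs_validation_error")
})

test_that("convergent positions draw codon variants; fixed positions do not", {
  aa <- "ARSDT"
  set.seed(52)
  conv <- replicate(40, generate_cdr3_nt(aa, convergent_positions = 2L)$nt)
  expect_gt(length(unique(conv)), 1L)
  codons <- unique(substr(conv, 4, 6))
  expect_true(all(codons %in% codons_of("R")))
  fixed <- replicate(5, generate_cdr3_nt(aa)$nt)
  expect_length(unique(fixed), 1L)
})

test_that("infeasible motif prevalences are rejected at configuration", {
  heavy <- list(
    motif_spec("a", "beta", template_beta = "ASSXRSTDTQY",
               prevalence = 0.6),
    motif_spec("b", "beta", template_beta = "ASSQGTAGELFF",
               prevalence = 0.6))
  expect_error(synthetic_config(planted_motifs = heavy),
               class = "tcrmotifs_validation_error")
  expect_error(synthetic_config(public_fraction = 1.3),
               class = "tcrmotifs_validation_error")
  expect_error(motif_spec("c", "beta", template_beta = "ASS.R.TDTQY",
                          pools_beta = "ILV", prevalence = 0.1),
               class = "tcrmotifs_validation_error")
})

test_that("planted counts follow the configured prevalence (census-shaped)", {
  cfg <- synthetic_config(n_patients = 34,
                          clonotypes_per_patient = c(rep(81L, 33), 91L),
                          seed = 53)
  sim <- generate_repertoire(cfg)
  expect_equal(nrow(sim$truth), 2764L)
  n_r <- sum(sim$truth$motif == "R-analog", na.rm = TRUE)
  # binomial 99% interval around 0.105 * 2764 = 290
  expect_true(abs(n_r - 290) < 2.576 * sqrt(2764 * 0.105 * 0.895) + 1)
  # planted R-analog betas are all 11 residues long
  expect_true(all(nchar(sim$truth$cdr3_aa_beta[
    sim$truth$motif == "R-analog" & !is.na(sim$truth$motif)]) == 11L))
})

test_that("every planted member matches its own motif specification", {
  sim <- generate_repertoire(small_cfg(seed = 54))
  truth <- sim$truth
  for (sp in sim$config$planted_motifs) {
    members <- truth[!is.na(truth$motif) & truth$motif == sp$name, ]
    if (nrow(members) == 0L) next
    subj <- tibble::tibble(
      cdr3_aa_beta = members$cdr3_aa_beta, v_beta = members$v_beta,
      v_beta_subgroup = v_subgroup_of(members$v_beta),
      j_beta = members$j_beta,
      cdr3_aa_alpha = members$cdr3_aa_alpha, v_alpha = members$v_alpha,
      v_alpha_subgroup = v_subgroup_of(members$v_alpha),
      j_alpha = members$j_alpha)
    expect_true(all(match_motif(as_motif_row(sp), subj)))
  }
})

test_that("background lengths and V usage track the configuration", {
  cfg <- synthetic_config(n_patients = 30,
                          clonotypes_per_patient = c(160, 180),
                          planted_motifs = list(), public_fraction = 0,
                          seed = 55)
  sim <- generate_repertoire(cfg)
  lens <- nchar(sim$truth$cdr3_aa_beta)
  target <- sum(as.integer(names(cfg$cdr3_length_probs)) *
                  cfg$cdr3_length_probs)
  expect_lt(abs(mean(lens) - target), 0.3)
  obs <- table(factor(sim$truth$v_beta, levels = names(cfg$v_freqs$beta)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = cfg$v_freqs$beta))
  expect_gt(gof$p.value, 0.01)
})

test_that("attrition bookkeeping balances exactly", {
  sim <- generate_repertoire(small_cfg(seed = 56))
  rec <- read_rearrangements(sim$rearrangements)
  expect_equal(nrow(rearrangement_rejects(rec)), 0L)
  productive <- rec[rec$productive, ]
  kept <- filter_chains(rec)
  cells <- call_valid_cells(kept)
  in_valid <- sum(kept$cell_id %in% cells$cell_id[cells$valid])
  dropped_filter <- nrow(productive) - nrow(kept)
  in_invalid <- nrow(kept) - in_valid
  expect_equal(nrow(productive) - dropped_filter - in_invalid, in_valid)
  expect_gt(dropped_filter, 0L)   # the read filter does bite
})

test_that("public group members share amino acids but vary in nucleotides", {
  sim <- generate_repertoire(synthetic_config(
    n_patients = 10, clonotypes_per_patient = c(40, 60),
    planted_motifs = list(), seed = 57))
  truth <- sim$truth
  grp <- truth[!is.na(truth$public_group) & truth$public_chain == "beta", ]
  counts <- table(grp$public_group)
  big <- names(counts)[counts >= 2]
  expect_gt(length(big), 5L)
  nt_differs <- vapply(big, function(g) {
    rows <- grp[grp$public_group == as.integer(g), ]
    length(unique(rows$cdr3_aa_beta)) == 1L &&
      length(unique(rows$cdr3_nt_beta)) > 1L
  }, TRUE)
  # identical-aa members differ at nucleotide level in nearly all groups
  expect_gte(mean(nt_differs), 0.9)
})

test_that("the bundle writes and the config echo carries the seed", {
  dir <- withr::local_tempdir()
  sim <- generate_repertoire(small_cfg(seed = 58))
  write_repertoire(sim, dir)
  expect_setequal(list.files(dir),
                  c("rearrangements.tsv", "reference_clones.tsv",
                    "irgp.tsv", "truth.tsv", "config.json"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 58L)
  back <- read_rearrangements(file.path(dir, "rearrangements.tsv"))
  expect_equal(nrow(back), nrow(sim$rearrangements))
})
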