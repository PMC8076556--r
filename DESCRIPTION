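Package: tcrmotifs
Title: CDR3 Motif Discovery and Public-Sequence Analysis for Single-Cell
    T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing annotated single-cell paired-chain T-cell
    receptor (TCR) rearrangement tables: read-support and dual-chain
    filtering, clonotype calling on TCR-beta nucleotide identity, CDR3
    trimming, Levenshtein/UPGMA hierarchical clustering of single-chain and
    paired CDR3 sets, recursive V-gene-constrained motif discovery with
    rule-based regular-expression construction, motif-to-epitope
    annotation against reference clone tables, public-clonotype sharing
    analysis, external TCR-database motif searches, and comparison of
    immune-receptor generation probabilities between public and private
    sequences.  Includes a synthetic-repertoire generator with planted
    motifs, convergent-recombination public sequences and ground-truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
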