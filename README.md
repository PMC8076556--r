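# tcrmotifs

Celiac disease is driven by CD4+ T cells that recognise deamidated gluten
peptides presented on HLA-DQ2.5. Single-cell sequencing of
tetramer-sorted gluten-specific T cells yields paired-chain T-cell
receptor (TCR) repertoires in which a handful of features recur across
patients: biased V-gene usage (TRAV26-1:TRBV7-2 above all), *public*
TCR chains shared by several individuals, and conserved CDR3 motifs — most
prominently the TCRβ "R-motif" `ASS.R.TDTQY` on TRBV7-2/TRBV7-3, whose
conserved non-germline arginine arises repeatedly through convergent
recombination (arginine has six codons).

`tcrmotifs` is an R package for this analysis style, aimed at
immunologists working with AIRR-style single-cell rearrangement tables.
It covers the full path from raw annotated chains to motif and
public-sequence reports:

- **Ingestion and clonotype calling** — read-support filtering (default
  < 50 reads discarded), dual-chain acceptance by read proportion, valid
  cells (1–2 α and 1–2 β, at most 3 chains), clonotypes keyed on identical
  TCRβ V gene, J gene and CDR3 *nucleotide* sequence per patient.
- **CDR3 clustering** — trimming of IMGT positions 105/106/117, removal of
  trimmed CDR3s under 8 residues, Levenshtein distances (paired receptors:
  sum of the α and β distances), exact UPGMA average-linkage trees with a
  documented deterministic tie-break.
- **Motif discovery** — recursive root-to-leaf scan of the dendrogram;
  nodes at or below a cut-off whose leaves all use one V gene (or one V
  subgroup) and hold at least five clonotypes become motif candidates;
  member CDR3s are aligned and rendered as anchored regular expressions
  using four amino-acid groups (charged `[KRED]`, polar `[QNHSTYC]`,
  amphipathic `[WYM]`, hydrophobic `[AILMFVPG]`), with gap columns marked
  optional. Candidates matching the established celiac motif library
  (shipped as packaged data) are excluded.
- **Repertoire statistics** — V-usage with dual chains counted 50% each,
  public chains (identical amino-acid identity in ≥ 2 patients),
  per-patient shared fractions, epitope annotation against reference
  clones with known specificity (exact or 1-mismatch), external database
  motif searches with disease-related entries excluded, and a one-sided
  Mann–Whitney U comparison of generation probabilities between public
  and private sequences (paired probability = product of chain
  probabilities).
- **Synthetic cohorts** — a ground-truth generator emulating the study
  design: biased V/J usage, planted motifs, public groups realised by
  convergent recombination at the codon level, dual and unproductive
  chains, log-normal read support.

## Worked example

```r
library(tcrmotifs)

sim <- generate_repertoire(synthetic_config(
  n_patients = 12, clonotypes_per_patient = c(30, 80), seed = 42))

clonotypes <- sim$rearrangements |>
  read_rearrangements() |>
  filter_chains() |>          # read support >= 50, dual rule
  define_clonotypes()         # beta-nucleotide clonotype keys
nrow(clonotypes)
#> [1] 664

set  <- prepare_clustering_set(clonotypes, "beta", seed = 1)
tree <- upgma(cdr3_distances(set))
motifs <- discover_motifs(tree, set, cutoff = 2, v_mode = "gene")
tidy(motifs)[, c("motif_id", "n_members", "node_height", "v_beta", "pattern_beta")]
#> # A tibble: 4 × 5
#>   motif_id      n_members node_height v_beta   pattern_beta
#> 1 B_gene_2_M001        67        1.84 TRBV7-2  ASS.R.TDTQY
#> 2 B_gene_2_M002        10        1    TRBV19   ASG.GQGNTEAFF
#> 3 B_gene_2_M003         7        1    TRBV9    ASS.GTGELFF
#> 4 B_gene_2_M004         5        0    TRBV11-2 AVADHDILASAY
```

The dominant candidate is the planted R-motif analogue: 67 TRBV7-2
clonotypes merging at an average Levenshtein distance of 1.84, whose
alignment renders exactly the canonical pattern. Its frequency matches
the planted 10.5% prevalence:

```r
motif_frequency(established_motifs(), clonotypes)
#> # A tibble: 4 × 3
#>   motif            count fraction
#> 1 R-motif             67    0.101
#> 2 Extended R-motif    68    0.102
#> 3 NDYKLS               0    0
#> 4 Paired R-motif      67    0.101

pub <- dplyr::bind_rows(find_public_sequences(clonotypes, "alpha"),
                        find_public_sequences(clonotypes, "beta"))
sum(pub$public)
#> [1] 89
attr(shared_fraction_per_patient(clonotypes, pub), "median")
#> [1] 0.365   # the cohort was generated with a 37% sharing target
```

`run_pipeline()` chains all stages (including paired-chain clustering,
subgroup-mode discovery, epitope annotation and the generation-probability
comparison) and writes a TSV/JSON report bundle that is byte-identical
across reruns with the same seed.

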