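---
title: "Motif discovery and public-sequence analysis in gluten-specific TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery and public-sequence analysis in gluten-specific TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmotifs)
```

# The analysis

`tcrmotifs` implements the repertoire-level search for conserved CDR3
motifs and public receptors in single-cell paired-chain TCR data, the
analysis style used to characterise gluten-specific CD4+ T cells in
celiac disease. The pipeline has five stages, each usable on its own.

## From chains to clonotypes

A rearrangement table carries one sequenced chain per row: cell and
patient identifiers, locus, V/J calls, the CDR3 junction in nucleotides
and amino acids, read support and a productivity flag. The package's CDR3
convention is IMGT positions 105–117, i.e. the junction *without* the
conserved C104 and F/W118 anchors; inputs that include the anchors are
converted with `rearrangement_dialect(junction_is_full = TRUE)`.

Quality filtering follows the sorted-single-cell logic: chains with fewer
than `min_reads = 50` reads are discarded; within a cell and locus a
second (dual) chain is accepted only when it also reaches the read floor
and carries at least `dual_min_fraction = 0.10` of the top chain's reads.
The primary source describes dual acceptance only as "based on read
support proportions" without a number, so the 10% default is an explicit,
configurable choice. A *valid cell* has one or two chains per locus and
at most three chains in total. Unproductive chains are read and flagged
but take no part in clonotype calling or anything downstream.

Clonotypes are patient-level clones keyed on the TCRβ at the *nucleotide*
level — identical V gene, J gene and CDR3 nucleotide sequence — so that
convergent recombinants (same protein, different codons) remain separate
clones. Each cell's defining β is its highest-read β chain; how rare
dual-β cells map to clonotypes is not specified by the source, and
"highest-read wins" is our deterministic resolution. The representative α
is the α identity seen in the most member cells, with ties broken by
total read support and then lexicographically; since well over 99% of
clonotypes carry a unique αβ combination, this tie-break almost never
matters.

## Clustering

For specificity clustering the CDR3s are trimmed: two residues from the N
terminus (IMGT 105, 106) and one from the C terminus (IMGT 117), the
positions that do not contact peptide antigen. Trimmed sequences shorter
than `min_trimmed_len = 8` are removed. In paired mode a clonotype is
dropped when *either* chain fails the filter (configurable to β-only; the
source does not state which convention it used). Dual-α clonotypes are
represented by one α chosen by a seeded uniform draw — the seed is
mandatory because an unseeded random pick would make runs irreproducible.

Distances are unit-cost Levenshtein distances on the trimmed sequences;
paired receptors use the sum of the α and β distances (a metric, being a
sum of metrics). Trees are built with unweighted average linkage (UPGMA).
Two numerical choices make the trees exactly reproducible:

* merge heights are computed from exact sums of the original integer
  distances, not from floating-point running averages, so heights are
  exact rationals and cluster membership can be tested with `<=` and no
  tolerance;
* when two candidate merges tie, the pair whose clusters contain the
  lexicographically smallest leaf labels wins, which makes the tree
  invariant under permutation of the input rows (up to relabeling).

Cutting a tree at height *h* returns the maximal subtrees whose merge
height is at most *h*; partitions at lower cuts refine partitions at
higher cuts.

## Motif discovery

Candidates are found by a recursive root-to-leaves scan. A node is
emitted when (i) its height is at or below the Levenshtein cut-off —
"below a given cut-off" is read as inclusive, which matters because
integer-average heights often equal the cut-off exactly — (ii) all leaf
clonotypes use the same V gene (alleles disregarded; same V subgroup in
subgroup mode; both chains coherent for paired sets) and (iii) it covers
at least `min_leaves = 5` clonotypes. The scan stops below an emitted
node, so one run's candidates never share clonotypes.

Member CDR3s (full, untrimmed) are aligned progressively in subtree
order with identity scoring (match 1, mismatch 0, gap −1) — candidates
are small sets of near-identical short peptides, so an elaborate aligner
would add nothing. The alignment becomes an anchored regular expression
column by column: a single residue is written literally; several residues
that fit one amino-acid group become that group's full character class
(charged `[KRED]`, polar `[QNHSTYC]`, amphipathic `[WYM]`, hydrophobic
`[AILMFVPG]`); residues spanning groups become the wildcard `.`; any gap
makes the column's token optional (`?`). The groups overlap in Y and M;
when a column fits more than one group we resolve by the fixed priority
charged > polar > amphipathic > hydrophobic (configurable in principle —
the source is silent on the point, and the choice only affects which
class label is printed, not which members match).

A sequence matches a motif when its full CDR3 matches the anchored
pattern *and* it expresses the motif's V gene; paired motifs require both
chains; either chain of a dual-α clonotype may satisfy the α side. J-gene
constraints are stored with the established motifs but not enforced by
default, because matching is defined by regex plus V gene only.
Candidates in which at least half the members match an established celiac
motif (R-motif `ASS.R.TDTQY`, extended R-motif `ASS.R.*`, NDYKLS
`I.NDYKLS`, and the paired R-motif; shipped in
`inst/extdata/established_motifs.tsv`) are removed; the 50% overlap
threshold quantifies the source's unquantified "matching" and is a
parameter of `exclude_established()`.

## Repertoire statistics

V-usage counts exclude chains with ambiguous V calls and give each
alternative chain of a dual clonotype weight 0.5, so the included mass
sums to one. Public sequences are chain identities — by default (V gene,
J gene, CDR3 amino acids); configurable to CDR3-only — observed in at
least two patients; every accepted chain is keyed, including both alphas
of dual clonotypes. The per-patient shared fraction is the share of a
patient's clonotypes whose α or β identity is public, with the cohort
median reported.

Epitope annotation compares targets with reference clones of known
specificity: motifs annotate through motif matching; public paired
records annotate exactly (identical V/J/CDR3 on both chains) or as
"similar" when V genes agree and the summed CDR3 distance over both
chains is at most one amino acid. External-database searches drop rows
whose epitope/pathology annotation matches celiac-related keywords before
counting regex+V matches.

Generation probabilities are consumed as precomputed per-chain inputs
(recombination-model inference is out of scope); the paired probability
is the exact product of the chain probabilities. Public and private
values are compared with a one-sided Mann–Whitney U test: for combined
samples up to 20 the p-value is an exhaustive permutation enumeration
(exact even under ties); larger samples use the normal approximation with
tie and continuity correction, which reproduces
`wilcox.test(exact = FALSE)` to machine precision.

# The synthetic cohort generator

Real cohorts of this kind are controlled-access, so validation runs on
`generate_repertoire()`, whose defaults encode the study conditions:
30 patients with 20–200 clonotypes each; V/J frequency tables biased so
that TRAV26-1 and TRBV7-2 lead and the TRAV26-1:TRBV7-2 pairing reaches
roughly 12% of clonotypes; full CDR3 lengths on 10–16 with mean ≈ 12.6
(so ~0.5% of clonotypes fall to the trimmed-length filter, matching the
observed 2764 → 2750 attrition); dual productive α at 6.9% and β at 0.2%;
unproductive α at 16.1% and β at 3.5%; log-normal read support placing
about 5% of chains under the read-50 floor; cells per clonotype
1 + Poisson(1.3) ≈ 2.3.

Planted motifs are templates with variable slots (the default set is an
R-motif-family analogue at 10.5% prevalence — `ASS.R.TDTQY` on
TRBV7-2/TRBJ2-3 paired with a TRAV26-1 α — plus five minor motifs at
0.5–1%). Nucleotides use one canonical codon per residue except at
*convergent positions*, where the codon is drawn uniformly from the
residue's full codon set; public chains draw every codon convergently, so
group members share amino acids while differing in nucleotides with high
probability — the convergent-recombination mechanism behind public
R-motif sharing (arginine alone has six codons).

Public sharing is specified as an overall target: the fraction of
clonotypes involved in a cross-patient identical chain, default 0.37.
Because motif templates already create identical chains across patients,
the generator first counts that motif-driven sharing and then adds only
as many background public groups (2–5 patients each, skewed toward
pairs) as needed to reach the target. Secondary (dual) chains carry
15–90% of the primary chain's reads, so the primary chain always defines
the clonotype.

What the generator does *not* emulate: realistic V(D)J junctional
machinery (insertions/deletions around germline segments — backgrounds
are i.i.d. residues with V/J-determined flanks), thymic selection,
sequencing error, cross-reactive specificities, or correlated α/β gene
usage beyond the planted motifs. Passing recovery tests on this material
therefore shows that the algorithms find what the model plants under
realistic noise and attrition — not that real repertoires contain such
motifs; surrogate generation probabilities (log-normal with a shift for
public chains) likewise test only the comparison machinery, not any
recombination model.

# Validation scales and determinism

The test suite exercises the distance and linkage code against
independent oracles (a full dynamic-programming edit-distance table;
brute-force agglomeration with averages recomputed from the raw matrix on
up to 8 leaves; `stats::hclust` on tie-free matrices), the regex builder
against hand-coded column rules on hundreds of random candidate families,
and the end-to-end pipeline on seeded cohorts of roughly 2,700 clonotypes
across 30 patients — the census at which planted-motif recovery (every
planted motif recovered with ≥ 95% member purity, the R-analogue
dominant) and public-sharing recovery (median within ±0.05 of the 0.37
target, group counts exact after attrition accounting) are asserted.
Sharing recovery is checked on a cohort without planted motifs, where
"exactly the planted groups" is well-posed; with motifs planted, their
templates legitimately add public records of their own. Every random
element (generator, dual-α selection, test fixtures) runs under explicit
seeds, and rerunning the pipeline on the same inputs and seed produces a
byte-identical report bundle, which the suite verifies by hashing.

# Known limitations

* The dendrogram is O(n²) in memory and the linkage engine O(n³) in the
  worst case; around 3,000 sequences this is seconds of work, but the
  implementation is not meant for bulk repertoires of 10⁵+ sequences.
* The progressive aligner is order-dependent like all progressive
  schemes; for the near-identical members of a candidate node the result
  is effectively unique, but it is not a general-purpose MSA tool.
* Epitope annotation is transfer by sequence identity/similarity to
  reference clones; it cannot assign specificities absent from the
  reference table.
* Public-sequence keys deduplicate within a patient but count every
  accepted chain, including dual alphas; cohorts processed with other
  conventions may report slightly different public counts.
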