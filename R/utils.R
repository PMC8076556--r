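# Shared helpers: genetic-code tables, gene-name handling, seeded RNG.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid physicochemical groups used for regex construction
#'
#' Four residue groups drive the column rules of [build_regex()]: charged
#' (K, R, E, D), polar (Q, N, H, S, T, Y, C), amphipathic (W, Y, M) and
#' hydrophobic (A, I, L, M, F, V, P, G).  The groups overlap (Y and M belong
#' to two groups each) and jointly cover all twenty residues.
#'
#' @return Named list of character vectors, in the fixed priority order used
#'   when a column's residues fit more than one group.
#' @export
#' @examples
#' amino_acid_groups()$charged
amino_acid_groups <- function() {
  list(
    charged     = c("K", "R", "E", "D"),
    polar       = c("Q", "N", "H", "S", "T", "Y", "C"),
    amphipathic = c("W", "Y", "M"),
    hydrophobic = c("A", "I", "L", "M", "F", "V", "P", "G")
  )
}

# codon -> amino acid map (standard code; stops as "*"), cached per session
.tcr_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.tcr_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .tcr_cache$gc <- setNames(as.character(gc), names(gc))
  }
  .tcr_cache$gc
}

# per-residue codon sets and canonical codons, cached
codon_sets <- function() {
  if (is.null(.tcr_cache$sets)) {
    gc <- genetic_code()
    aas <- unique(unname(gc))
    .tcr_cache$sets <- lapply(setNames(aas, aas),
                              function(a) sort(names(gc)[gc == a]))
  }
  .tcr_cache$sets
}

#' Codon set of an amino acid under the standard genetic code
#'
#' @param aa Single amino-acid letter (or "*" for stop).
#' @return Character vector of codons, alphabetically sorted.
#' @export
#' @examples
#' codons_of("R")  # six codons
codons_of <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) == 1L)
  sets <- codon_sets()
  if (is.null(sets[[aa]])) {
    abort(sprintf("'%s' is not an amino acid", aa),
          class = "tcrmotifs_validation_error")
  }
  sets[[aa]]
}

# one fixed codon per residue, used for non-convergent positions
canonical_codon <- function(aa) {
  if (is.null(.tcr_cache$canon)) {
    .tcr_cache$canon <- vapply(codon_sets(), `[`, "", 1L)
  }
  unname(.tcr_cache$canon[strsplit(aa, "")[[1]]])
}

#' Translate CDR3 nucleotide strings
#'
#' Vectorised standard-genetic-code translation.  Returns `NA` for sequences
#' whose length is not a multiple of three or that contain characters outside
#' ACGT; stop codons translate to `"*"`.
#'
#' @param nt Character vector of nucleotide strings.
#' @return Character vector of amino-acid strings.
#' @export
translate_nt <- function(nt) {
  gc <- genetic_code()
  vapply(nt, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- toupper(s)
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return(NA_character_)
    cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(gc[cod])
    if (anyNA(aa)) NA_character_ else paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Reduce a V/J call to gene level and to its IMGT subgroup
#'
#' `strip_allele()` removes the allele suffix (`*01`) and keeps only the
#' first call of an ambiguous comma-separated list.  `v_subgroup_of()` drops
#' the gene number within the subgroup, e.g. `"TRBV7-2"` to `"TRBV7"` and
#' `"TRAV23/DV6"` to `"TRAV23"`.
#'
#' @param call Character vector of V or J calls.
#' @return Character vector of the same length.
#' @export
#' @examples
#' strip_allele("TRAV26-1*01")
#' v_subgroup_of("TRBV7-2")
strip_allele <- function(call) {
  out <- stringr::str_trim(vapply(strsplit(call, ","), function(x) x[1L], "",
                                  USE.NAMES = FALSE))
  sub("\\*.*$", "", out)
}

#' @rdname strip_allele
#' @export
v_subgroup_of <- function(call) {
  sub("[-/].*$", "", strip_allele(call))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

is_valid_aa <- function(x, allow_stop = FALSE) {
  pat <- if (allow_stop) "^[ACDEFGHIKLMNPQRSTVWY*]+$" else
    "^[ACDEFGHIKLMNPQRSTVWY]+$"
  !is.na(x) & grepl(pat, x)
}
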