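# Local protein alignment used throughout the clustering and AAI code.
#
# Scoring scheme: BLOSUM62 with affine gap penalties (open 11, extend 1),
# the ubiquitous default for protein local alignment.  Identity is computed
# over aligned columns *including* internal gap columns (a conservative,
# symmetric denominator); coverage is expressed relative to the shorter
# sequence, matching the "-aS 0.8"-style alignment-coverage criterion of
# greedy clustering tools.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Optimal local alignment statistics for a pair of protein sequences
#'
#' Computes the optimal Smith-Waterman local alignment of two amino-acid
#' sequences under BLOSUM62 with affine gap penalties (gap open 11, gap
#' extend 1) and summarizes it as an identity fraction, a coverage fraction
#' relative to the shorter sequence, and the raw alignment score.
#'
#' Identity is the fraction of identical residue pairs over all aligned
#' columns, counting internal gap columns in the denominator.
#' `coverage_short` is the number of residues of the shorter sequence that
#' take part in the alignment, divided by its full length.  When no local
#' alignment with positive score exists (e.g. sequences over disjoint
#' alphabets), identity and coverage are reported as 0.
#'
#' @param a,b Non-empty amino-acid strings (20 canonical residues plus `X`).
#' @return A list with elements `identity`, `coverage_short` and `score`.
#' @examples
#' align_local("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
#' @export
align_local <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("both sequences must be non-empty amino-acid strings")
  }
  st <- .align_many(a, b)
  list(identity = st$identity, coverage_short = st$coverage_short,
       score = st$score)
}

# Vectorized workhorse: align each element of `patterns` against the single
# string `subject`.  Returns per-pair identity, coverage_short and score.
# One pairwiseAlignment() call keeps the R-level overhead of greedy
# clustering (many candidates vs one incoming sequence) negligible.
.align_many <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns),
    Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  sc <- Biostrings::score(aln)
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  len_p <- nchar(patterns)
  len_s <- nchar(subject)
  # residues of each sequence that fall inside the aligned region
  w_p <- BiocGenerics::width(Biostrings::pattern(aln)@range)
  w_s <- BiocGenerics::width(Biostrings::subject(aln)@range)
  cov <- ifelse(len_p <= len_s, w_p / len_p, w_s / len_s)
  bad <- sc <= 0
  identity[bad] <- 0
  cov[bad] <- 0
  data.frame(identity = identity, coverage_short = cov, score = sc)
}
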