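# Comparisons at the genome (MAG) level: quality filtering, coverage-based
# relative abundance, intra-lineage metabolic-differentiation ratios over
# KO categories, and average amino-acid identity (AAI) between proteomes.

.check_mag_table <- function(mags) {
  stopifnot(is.data.frame(mags),
            all(c("bin_id", "total_length", "mapped_reads",
                  "completeness", "contamination") %in% names(mags)))
  if (any(mags$total_length <= 0)) stop("total_length must be positive")
  if (any(mags$completeness < 0 | mags$completeness > 100)) {
    stop("completeness must lie in [0, 100] percent")
  }
  if (any(mags$contamination < 0)) stop("contamination must be non-negative")
  invisible(mags)
}

#' Quality-filter metagenome-assembled genomes
#'
#' Retains medium-to-high-quality draft genomes: completeness strictly
#' greater than `min_completeness` and contamination strictly less than
#' `max_contamination` (defaults 50% and 7%).  Both bounds are exclusive,
#' so a bin at exactly 50% completeness or exactly 7% contamination is
#' dropped.
#'
#' @param mags MAG table: data frame with columns `bin_id`, `total_length`
#'   (bp), `mapped_reads`, `completeness` (percent), `contamination`
#'   (percent).
#' @param min_completeness,max_contamination Exclusive bounds, in percent.
#' @return The retained rows; counts are attached as attributes
#'   `n_retained` and `n_excluded`.
#' @export
filter_mags <- function(mags, min_completeness = 50, max_contamination = 7) {
  .check_mag_table(mags)
  keep <- mags$completeness > min_completeness &
    mags$contamination < max_contamination
  out <- mags[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Coverage-normalized relative abundance of MAGs
#'
#' Three-step abundance estimate: (1) relativized coverage = mapped reads /
#' assembled length; (2) normalization to estimated genome size (assembled
#' length divided by the completeness fraction) by multiplying coverage by
#' that size; (3) relative abundance = each bin's value as a fraction of
#' the summed values.  Abundances sum to 1 and are invariant to a uniform
#' rescaling of read counts.
#'
#' @param mags MAG table (see [filter_mags()]); completeness must be
#'   positive for the genome-size estimate.
#' @return The table with `coverage`, `estimated_genome_size` and
#'   `relative_abundance` columns appended.
#' @export
mag_relative_abundance <- function(mags) {
  .check_mag_table(mags)
  if (nrow(mags) == 0L) stop("MAG table is empty")
  if (any(mags$completeness <= 0)) {
    stop("completeness must be positive to estimate genome size")
  }
  coverage <- mags$mapped_reads / mags$total_length
  size <- mags$total_length / (mags$completeness / 100)
  weight <- coverage * size
  mags$coverage <- coverage
  mags$estimated_genome_size <- size
  mags$relative_abundance <- weight / sum(weight)
  mags
}

#' Construct a genome KO annotation
#'
#' @param genome_id Genome identifier.
#' @param kos Character vector of KO identifiers carried by the genome
#'   (deduplicated).
#' @param lineage Optional lineage label shared by genomes being compared.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, kos, lineage = NA_character_) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  structure(list(genome_id = genome_id, lineage = lineage,
                 kos = unique(as.character(kos))),
            class = "genome_annotation")
}

#' Shared/unshared KO differentiation ratios for a genome pair
#'
#' For each KO category (by default the top-level KEGG categories
#' "Metabolism" and "Genetic Information Processing"), counts the KOs
#' shared by both genomes and the KOs found in only one of them (the
#' symmetric difference), and forms the ratio unshared / shared.  Plotting
#' the metabolism ratio against the genetic-information-processing ratio
#' for within-lineage genome pairs shows whether closely related genomes
#' are more differentiated in their metabolic complement than in their
#' (conserved) genetic-processing complement: points above the 1:1 line
#' indicate greater metabolic differentiation.
#'
#' KOs absent from the category map carry no category and are ignored;
#' their number is attached as attribute `n_unmapped`.  When a category has
#' no shared KO the ratio is undefined (`NA` with `defined = FALSE`), not
#' infinite; counts are still reported.
#'
#' @param a,b `genome_annotation` objects.
#' @param map KO category map (`ko`, `category`, `subcategory`).
#' @param categories Top-level categories to evaluate.
#' @return An object of class `pairwise_differentiation`: a data frame with
#'   one row per category and columns `genome_a`, `genome_b`, `category`,
#'   `shared`, `unshared`, `unique_a`, `unique_b`, `ratio`, `defined`.
#' @export
differentiation_ratios <- function(a, b, map,
                                   categories = c("Metabolism",
                                                  "Genetic Information Processing")) {
  stopifnot(inherits(a, "genome_annotation"), inherits(b, "genome_annotation"),
            is.data.frame(map), all(c("ko", "category") %in% names(map)))
  n_unmapped <- sum(!unique(c(a$kos, b$kos)) %in% map$ko)
  rows <- lapply(categories, function(cat) {
    cat_kos <- map$ko[map$category == cat]
    ka <- intersect(a$kos, cat_kos)
    kb <- intersect(b$kos, cat_kos)
    shared <- length(intersect(ka, kb))
    unique_a <- length(setdiff(ka, kb))
    unique_b <- length(setdiff(kb, ka))
    unshared <- unique_a + unique_b
    data.frame(genome_a = a$genome_id, genome_b = b$genome_id,
               category = cat, shared = shared, unshared = unshared,
               unique_a = unique_a, unique_b = unique_b,
               ratio = if (shared > 0) unshared / shared else NA_real_,
               defined = shared > 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("pairwise_differentiation", "data.frame")
  out
}

#' Average amino-acid identity (AAI) between two proteomes
#'
#' Aligns every protein of one proteome against every protein of the other
#' (local alignment, BLOSUM62, affine gaps), identifies reciprocal best
#' hits by alignment score, discards hits below `min_identity` identity or
#' `min_coverage` coverage of the shorter sequence, and reports the mean
#' and standard deviation of the retained best-hit identities as percent.
#' AAI is a whole-genome relatedness measure: values around 70% are
#' typical of genus/family-level relatives.
#'
#' @param proteome_a,proteome_b Protein record tables (see
#'   [protein_records()]).
#' @param min_identity Minimum alignment identity for a retained pair.
#' @param min_coverage Minimum coverage of the shorter sequence.
#' @return List of class `aai_result`: `mean_identity` and `sd_identity`
#'   (percent; sd is 0 for a single pair), `n_pairs`, and the per-pair
#'   table `pairs`.
#' @export
aai <- function(proteome_a, proteome_b, min_identity = 0.2, min_coverage = 0.5) {
  validate_protein_records(proteome_a)
  validate_protein_records(proteome_b)
  na <- nrow(proteome_a); nb <- nrow(proteome_b)
  score <- identity <- coverage <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    st <- .align_many(proteome_b$seq, proteome_a$seq[i])
    score[i, ] <- st$score
    identity[i, ] <- st$identity
    coverage[i, ] <- st$coverage_short
  }
  # reciprocal best hits under the (symmetric) local alignment score
  best_b_for_a <- max.col(score, ties.method = "first")
  best_a_for_b <- max.col(t(score), ties.method = "first")
  rbh_a <- which(best_a_for_b[best_b_for_a] == seq_len(na))
  rows <- lapply(rbh_a, function(i) {
    j <- best_b_for_a[i]
    data.frame(protein_a = proteome_a$protein_id[i],
               protein_b = proteome_b$protein_id[j],
               identity = identity[i, j], coverage_short = coverage[i, j],
               score = score[i, j])
  })
  pairs <- do.call(rbind, rows)
  pairs <- pairs[pairs$score > 0 & pairs$identity >= min_identity &
                   pairs$coverage_short >= min_coverage, , drop = FALSE]
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no reciprocal best-hit pair meets the identity/coverage thresholds; AAI undefined")
  }
  structure(list(mean_identity = 100 * mean(pairs$identity),
                 sd_identity = if (nrow(pairs) > 1L) 100 * stats::sd(pairs$identity) else 0,
                 n_pairs = nrow(pairs), pairs = pairs),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("AAI: %.1f%% +/- %.1f%% over %d reciprocal best-hit pairs\n",
              x$mean_identity, x$sd_identity, x$n_pairs))
  invisible(x)
}
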