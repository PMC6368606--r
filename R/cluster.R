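# Greedy incremental identity-threshold clustering of proteins into family
# "bins", applied as a cascade of decreasing thresholds (default 90%, 60%,
# 30%).  Sequences are processed longest-first; each sequence joins the
# best-matching existing representative that satisfies both the identity
# threshold and the coverage-of-the-shorter-sequence criterion, otherwise
# it founds a new cluster.

#' Build a protein record table
#'
#' Convenience constructor/validator for the protein tables used by the
#' clustering functions: a data frame with columns `protein_id`,
#' `metagenome_id` and `seq`.
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param metagenome_id Character vector (recycled) of sample identifiers.
#' @param seq Character vector of amino-acid sequences (canonical residues
#'   plus `X`).
#' @return A data frame of class `protein_records`.
#' @export
protein_records <- function(protein_id, metagenome_id, seq) {
  df <- data.frame(protein_id = as.character(protein_id),
                   metagenome_id = as.character(metagenome_id),
                   seq = as.character(seq),
                   stringsAsFactors = FALSE)
  validate_protein_records(df)
  class(df) <- c("protein_records", "data.frame")
  df
}

validate_protein_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "metagenome_id", "seq") %in% names(records)))
  if (nrow(records) == 0L) stop("protein record table is empty")
  if (anyDuplicated(records$protein_id)) {
    stop("protein_id values must be unique")
  }
  if (any(!nzchar(records$seq) | is.na(records$seq))) {
    stop("all sequences must be non-empty")
  }
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", records$seq))) {
    stop("sequences restricted to the 20 canonical residues plus X")
  }
  invisible(records)
}

#' Drop proteins at or below a length cutoff
#'
#' Short predicted proteins are excluded before family clustering; only
#' proteins strictly longer than `min_length` amino acids are retained
#' (default 50, so a 50-residue protein is dropped).
#'
#' @param records Protein record table (see [protein_records()]).
#' @param min_length Strict lower bound on sequence length, in residues.
#' @return The filtered table; the number of dropped records is attached as
#'   attribute `n_dropped`.
#' @export
filter_short_proteins <- function(records, min_length = 50) {
  validate_protein_records(records)
  keep <- nchar(records$seq) > min_length
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Greedy incremental clustering at a single identity threshold
#'
#' Sequences are sorted by decreasing length (ties broken lexicographically
#' by `protein_id`) and processed in order.  Each sequence is aligned
#' against all current cluster representatives; among representatives with
#' alignment identity at or above `threshold` and coverage of the shorter
#' sequence at or above `min_coverage`, it joins the one with the highest
#' identity (ties broken toward the longer representative, then by
#' identifier).  If none qualifies it founds a new cluster and becomes its
#' representative.
#'
#' @param records Protein record table.
#' @param threshold Identity threshold in (0, 1].
#' @param min_coverage Minimum aligned fraction of the shorter sequence.
#' @return An object of class `cluster_set`: a list with `threshold`,
#'   `min_coverage`, `assignment` (named character vector mapping each
#'   protein_id to its representative's protein_id) and `clusters` (a list,
#'   ordered by decreasing representative length, mapping representative id
#'   to member ids).
#' @export
cluster_at <- function(records, threshold, min_coverage = 0.8) {
  validate_protein_records(records)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]")
  }
  ord <- order(-nchar(records$seq), records$protein_id, method = "radix")
  ids <- records$protein_id[ord]
  seqs <- records$seq[ord]
  lens <- nchar(seqs)

  rep_idx <- integer(0)              # indices (into ids/seqs) of representatives
  assignment <- character(length(ids))
  names(assignment) <- ids
  eps <- 1e-9                        # guard against floating identity round-off

  for (i in seq_along(ids)) {
    if (length(rep_idx) > 0L) {
      st <- .align_many(seqs[rep_idx], seqs[i])
      ok <- st$identity >= threshold - eps &
        st$coverage_short >= min_coverage - eps & st$score > 0
      if (any(ok)) {
        cand <- which(ok)
        # highest identity; ties -> longer representative, then lexicographic id
        o <- order(-st$identity[cand], -lens[rep_idx[cand]],
                   ids[rep_idx[cand]], method = "radix")
        best <- rep_idx[cand[o[1L]]]
        assignment[i] <- ids[best]
        next
      }
    }
    assignment[i] <- ids[i]
    rep_idx <- c(rep_idx, i)
  }

  reps <- ids[rep_idx]               # founding order == decreasing rep length
  clusters <- lapply(reps, function(r) unname(names(assignment)[assignment == r]))
  names(clusters) <- reps
  structure(list(threshold = threshold, min_coverage = min_coverage,
                 assignment = assignment, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d proteins in %d clusters (identity >= %g, coverage >= %g)\n",
              length(x$assignment), length(x$clusters), x$threshold,
              x$min_coverage))
  invisible(x)
}

#' Cascaded protein-family clustering
#'
#' Runs the greedy clustering at a sequence of strictly decreasing identity
#' thresholds (default 0.90, 0.60, 0.30).  The full data set is clustered
#' at the first threshold; the resulting representatives are re-clustered
#' at the second; their representatives at the third.  Memberships are
#' propagated down so every protein maps to exactly one final family, and
#' each level is a coarsening of the previous one.
#'
#' Proteins at or below `min_length` residues are excluded before
#' clustering (see [filter_short_proteins()]); set `min_length = 0` to keep
#' everything.
#'
#' @param records Protein record table.
#' @param thresholds Strictly decreasing identity thresholds.
#' @param min_coverage Minimum aligned fraction of the shorter sequence.
#' @param min_length Strict length cutoff applied before clustering.
#' @return An object of class `family_assignment`: a data frame with one
#'   row per retained protein and columns `protein_id`, `metagenome_id`,
#'   one `cluster_<level>` column per threshold, and `family` (the cluster
#'   label at the final, coarsest level).  Attributes: `levels`
#'   (thresholds), `n_clusters` (clusters per level), `n_dropped_short`.
#' @export
cascade <- function(records, thresholds = c(0.90, 0.60, 0.30),
                    min_coverage = 0.8, min_length = 50) {
  validate_protein_records(records)
  if (length(thresholds) < 1L || any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing")
  }
  kept <- filter_short_proteins(records, min_length)
  n_dropped <- attr(kept, "n_dropped")
  if (nrow(kept) == 0L) stop("no proteins left after length filtering")

  out <- data.frame(protein_id = kept$protein_id,
                    metagenome_id = kept$metagenome_id,
                    stringsAsFactors = FALSE)
  level_records <- kept
  label <- kept$protein_id           # current cluster label per protein
  n_clusters <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    cs <- cluster_at(level_records, thresholds[k], min_coverage)
    # map each protein's current label through this level's assignment
    label <- unname(cs$assignment[label])
    out[[sprintf("cluster_%02d", round(100 * thresholds[k]))]] <- label
    n_clusters[k] <- length(cs$clusters)
    reps <- names(cs$clusters)
    level_records <- kept[match(reps, kept$protein_id), , drop = FALSE]
  }
  out$family <- label
  structure(out,
            class = c("family_assignment", "data.frame"),
            levels = thresholds, n_clusters = n_clusters,
            n_dropped_short = n_dropped)
}

#' Per-metagenome protein-family abundance table
#'
#' Tallies, for every metagenome and every final family of a cascade
#' assignment, the number of proteins of that metagenome falling in that
#' family ("abundance-weighted protein bin counts").  Zero cells are kept
#' explicitly, and row sums equal the per-metagenome protein counts.
#'
#' @param assignment A `family_assignment` from [cascade()].
#' @param records Optional protein record table; when supplied, every
#'   record must appear in `assignment` (proteins dropped by the length
#'   filter excepted only if they are absent from `records` too), otherwise
#'   a consistency error is raised.
#' @return Integer matrix, metagenomes in rows, families in columns.
#' @export
family_abundance <- function(assignment, records = NULL) {
  if (!inherits(assignment, "family_assignment")) {
    stop("assignment must be a family_assignment (see cascade())")
  }
  if (any(is.na(assignment$family))) {
    stop("every protein must carry a family assignment")
  }
  if (!is.null(records)) {
    missing <- setdiff(records$protein_id, assignment$protein_id)
    if (length(missing) > 0L) {
      stop(sprintf("%d protein(s) lack a family assignment (e.g. %s)",
                   length(missing), missing[1L]))
    }
  }
  mg <- factor(assignment$metagenome_id,
               levels = sort(unique(assignment$metagenome_id)))
  fam <- factor(assignment$family, levels = unique(assignment$family))
  tab <- table(mg, fam)
  mat <- matrix(as.integer(tab), nrow = nlevels(mg),
                dimnames = list(levels(mg), levels(fam)))
  mat
}
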