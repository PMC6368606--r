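# KO (KEGG Orthology) profile comparison among metagenomes: per-sample
# normalization, mean-centered enrichment values, category subsetting,
# Bray-Curtis dissimilarity and principal-coordinates ordination.
#
# Tables are matrices with metagenomes in rows and KO identifiers in
# columns.  This module involves no random number generation; outputs are
# bit-stable for fixed inputs.

.check_ko_table <- function(table) {
  if (!is.matrix(table) || is.null(rownames(table)) || is.null(colnames(table))) {
    stop("KO table must be a matrix with metagenome row names and KO column names")
  }
  if (any(table < 0)) stop("KO table must be non-negative")
  invisible(table)
}

#' Normalize KO counts to within-metagenome frequencies
#'
#' Divides each metagenome's KO counts by that metagenome's total, so every
#' row sums to 1.  This accounts for unequal sequencing effort between
#' deeply and shallowly sequenced metagenomes.
#'
#' @param table KO count matrix (metagenomes x KOs).
#' @return Matrix of frequencies with unit row sums.
#' @export
normalize_ko <- function(table) {
  .check_ko_table(table)
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop(sprintf("metagenome(s) with zero total KO count: %s",
                 paste(rownames(table)[totals == 0], collapse = ", ")))
  }
  table / totals
}

#' Mean-centered KO enrichment values
#'
#' For each KO, subtracts the across-metagenome mean of its normalized
#' abundance and divides by that mean:
#' \deqn{E_{k,s} = (a_{k,s} - \bar a_k) / \bar a_k.}
#' With \eqn{S} metagenomes, a KO exclusive to one metagenome attains the
#' maximum \eqn{S - 1} there (14 with 15 samples); a KO absent from a
#' metagenome scores exactly \eqn{-1} there.  KOs with zero abundance in
#' every metagenome (mean 0) are dropped and listed in the `dropped_kos`
#' attribute.
#'
#' @param normalized Normalized KO frequency matrix from [normalize_ko()].
#' @return Enrichment matrix with KOs in rows and metagenomes in columns;
#'   every row averages to 0.
#' @export
ko_enrichment <- function(normalized) {
  .check_ko_table(normalized)
  m <- colMeans(normalized)
  drop <- m == 0
  if (any(drop)) {
    normalized <- normalized[, !drop, drop = FALSE]
    m <- m[!drop]
  }
  e <- t(sweep(sweep(normalized, 2L, m, "-"), 2L, m, "/"))
  attr(e, "dropped_kos") <- names(drop)[drop]
  e
}

#' Restrict a KO table to one functional category or subcategory
#'
#' Keeps the columns whose KO carries the requested label in the category
#' map, either as its top-level category (e.g. "Metabolism") or as its
#' subcategory (e.g. "Energy Metabolism").  KOs present in the table but
#' absent from the map are necessarily excluded; their number is attached
#' as attribute `n_unmapped`.  Note that subsetting and normalization do
#' not commute: normalize over the full KO complement or the subset
#' depending on the question.
#'
#' @param table KO matrix (counts or frequencies).
#' @param map KO category map: data frame with columns `ko`, `category`,
#'   `subcategory`.
#' @param label A category or subcategory name present in the map.
#' @return The column-subset matrix (possibly with zero columns, with a
#'   warning, when no table KO carries the label).
#' @export
subset_category <- function(table, map, label) {
  .check_ko_table(table)
  stopifnot(is.data.frame(map), all(c("ko", "category", "subcategory") %in% names(map)))
  if (!(label %in% map$category || label %in% map$subcategory)) {
    stop(sprintf("label '%s' does not occur in the category map", label))
  }
  labelled <- map$ko[map$category == label | map$subcategory == label]
  keep <- colnames(table) %in% labelled
  out <- table[, keep, drop = FALSE]
  if (ncol(out) == 0L) {
    warning(sprintf("no KO in the table carries label '%s'", label))
  }
  attr(out, "n_unmapped") <- sum(!colnames(table) %in% map$ko)
  out
}

#' Bray-Curtis dissimilarity between metagenome KO profiles
#'
#' \eqn{d(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)}, computed with
#' `vegan::vegdist`.  Conventionally applied to normalized frequencies so
#' that sequencing depth does not drive the distances.
#'
#' @param table Non-negative matrix (metagenomes x KOs) with positive row
#'   totals.
#' @return Symmetric dissimilarity matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(table) {
  .check_ko_table(table)
  if (nrow(table) < 2L) stop("need at least 2 metagenomes")
  if (any(rowSums(table) == 0)) {
    stop(sprintf("metagenome(s) with all-zero profile: %s",
                 paste(rownames(table)[rowSums(table) == 0], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: Gower double-centering of \eqn{-d^2/2},
#' eigendecomposition, and coordinates formed by scaling eigenvectors by
#' the square root of their (positive) eigenvalues.  Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported but their axes are omitted; no correction constant is applied.
#' Axis signs are fixed by forcing the largest-magnitude coordinate on
#' each axis to be positive, so ordinations are reproducible.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param k Maximum number of axes to return (at most n - 1).
#' @return An object of class `pcoa_ordination`: list with `coordinates`
#'   (n x m matrix, m = min(k, number of positive eigenvalues)),
#'   `eigenvalues` (all n), and `proportion_explained` (per returned axis,
#'   over the positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(abs(d - t(d)) > 1e-8)) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal (and no negative self-distance)")
  n <- nrow(d)
  if (k > n - 1L) stop("k must be at most n - 1")
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-10 + 1e-12
  pos <- which(eig > tol)
  m <- min(k, length(pos))
  if (m == 0L) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
    prop <- numeric(0)
  } else {
    coords <- sc$points[, seq_len(m), drop = FALSE]
    # reproducible sign convention: largest |coordinate| positive per axis
    for (j in seq_len(m)) {
      i_max <- which.max(abs(coords[, j]))
      if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
    }
    dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(m)))
    prop <- eig[pos][seq_len(m)] / sum(eig[pos])
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d axes returned (%s of positive-eigenvalue variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = " + ")))
  invisible(x)
}
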