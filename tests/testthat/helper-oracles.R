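# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the alignment oracle is a plain-R dynamic
# program, identities of constructed fixtures are checked by direct
# character comparison, and tree statistics are recomputed by naive edge
# enumeration.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Fraction of identical positions between two equal-length sequences
# (ungapped, column-by-column).
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# Exhaustive affine-gap Smith-Waterman under BLOSUM62 (gap of length L
# costs open + ext * L).  Score only; quadratic, for short fixtures.
sw_oracle_score <- function(a, b, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm[A[i - 1], B[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Naive branch-length-contribution oracle: per edge, enumerate descendant
# tips by recursion over the edge matrix.
bf_branch_fraction <- function(tree, tips, mode) {
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  s <- 0
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (mode == "exclusive") {
      if (all(desc_tips(ch) %in% tips)) s <- s + tree$edge.length[e]
    } else {
      if (ch <= ntip && tree$tip.label[ch] %in% tips) s <- s + tree$edge.length[e]
    }
  }
  s / sum(tree$edge.length)
}

# Hand Bray-Curtis for two abundance vectors.
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Partition equality up to label renaming (exact cluster recovery).
same_partition <- function(lab1, lab2) {
  tab <- table(lab1, lab2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Adjusted Rand index between two labelings.
ari <- function(lab1, lab2) mclust::adjustedRandIndex(lab1, lab2)

# A small well-separated clustering fixture: `n_fam` families of `n_mem`
# members at `within` identity to a shared founder, founders mutually
# dissimilar.  Returns a protein record table with a `family_truth` column.
make_cluster_fixture <- function(n_fam = 3, n_mem = 3, len = 60,
                                 within = 0.95) {
  founders <- replicate(n_fam, random_aa(len))
  rows <- list()
  k <- 0
  for (f in seq_len(n_fam)) {
    for (m in seq_len(n_mem)) {
      k <- k + 1
      rows[[k]] <- data.frame(
        protein_id = sprintf("p%02d", k), metagenome_id = "M1",
        seq = thermodiv::mutate_to_identity(founders[f], within),
        family_truth = sprintf("F%d", f))
    }
  }
  df <- do.call(rbind, rows)
  class(df) <- c("protein_records", "data.frame")
  df
}
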