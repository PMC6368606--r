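# Synthetic hot-spring "studies" with known ground truth.  The generator
# emulates the inputs of the comparative pipeline -- per-spring predicted
# proteomes with controlled family structure, spring geochemistry, KO
# tables with planted exclusive and shared KOs, MAG summary tables, and a
# random phylogeny with a tagged tip subset -- so that every downstream
# stage (clustering, rarefaction, regression, enrichment, differentiation,
# tree metrics) can be validated against planted parameters without any
# external data.

#' Configuration for a synthetic study
#'
#' Defaults describe a study of 40 springs whose planted protein-family
#' richness increases linearly with the fluid-mixing proxy log10(SO4/Cl)
#' at 8 families per log unit around an intercept of 30 families, with
#' Gaussian richness noise (sd 2 families) and lognormal within-spring
#' family abundances.  Families are planted as clouds of sequences at 95%
#' identity to a family founder, with founders pairwise below 25% identity
#' (enforced by rejection sampling), so the 90/60/30 clustering cascade is
#' expected to recover the planted partition.
#'
#' @param seed Integer RNG seed; the study is a deterministic function of
#'   the full configuration, seed included.
#' @param n_springs Number of springs/metagenomes.
#' @param pool_size Number of distinct protein families in the global pool.
#' @param richness_intercept,richness_slope Linear link from log10(SO4/Cl)
#'   to planted per-spring family richness (families; families per log
#'   unit).
#' @param richness_noise_sd Gaussian noise sd on planted richness.
#' @param abundance_shape Lognormal sigma of within-spring family member
#'   counts.
#' @param family_identity Within-family identity of members to their
#'   founder, in (0, 1].
#' @param between_identity_max Exclusive upper bound on ungapped pairwise
#'   identity between family founders.
#' @param seq_length Protein length in amino acids.
#' @param n_ko,n_categories Size of the KO universe and number of
#'   functional categories.
#' @param exclusive_ko_count Number of KOs planted as present in exactly
#'   one metagenome.
#' @param pair_shared_fraction_met,pair_shared_fraction_gen Planted
#'   fraction of each paired genome's category KOs shared with its partner,
#'   for the Metabolism and Genetic Information Processing categories.
#' @param n_genome_pairs Number of planted within-lineage genome pairs.
#' @param pair_category_size KOs per evaluated category per genome.
#' @param n_mags Number of MAG records.
#' @param tree_tips,tagged_fraction Tree size and the proportion of tips
#'   tagged as the focal (e.g. single-community) subset.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_springs = 40L,
                             pool_size = 120L,
                             richness_intercept = 30,
                             richness_slope = 8,
                             richness_noise_sd = 2,
                             abundance_shape = 1,
                             family_identity = 0.95,
                             between_identity_max = 0.25,
                             seq_length = 150L,
                             n_ko = 200L,
                             n_categories = 4L,
                             exclusive_ko_count = 3L,
                             pair_shared_fraction_met = 0.5,
                             pair_shared_fraction_gen = 0.8,
                             n_genome_pairs = 5L,
                             pair_category_size = 30L,
                             n_mags = 108L,
                             tree_tips = 60L,
                             tagged_fraction = 0.1) {
  cfg <- list(seed = as.integer(seed), n_springs = as.integer(n_springs),
              pool_size = as.integer(pool_size),
              richness_intercept = richness_intercept,
              richness_slope = richness_slope,
              richness_noise_sd = richness_noise_sd,
              abundance_shape = abundance_shape,
              family_identity = family_identity,
              between_identity_max = between_identity_max,
              seq_length = as.integer(seq_length),
              n_ko = as.integer(n_ko), n_categories = as.integer(n_categories),
              exclusive_ko_count = as.integer(exclusive_ko_count),
              pair_shared_fraction_met = pair_shared_fraction_met,
              pair_shared_fraction_gen = pair_shared_fraction_gen,
              n_genome_pairs = as.integer(n_genome_pairs),
              pair_category_size = as.integer(pair_category_size),
              n_mags = as.integer(n_mags), tree_tips = as.integer(tree_tips),
              tagged_fraction = tagged_fraction)
  counts <- c("n_springs", "pool_size", "seq_length", "n_ko", "n_categories",
              "n_mags", "tree_tips", "pair_category_size")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stop(sprintf("%s must be a positive count", f))
  }
  if (cfg$exclusive_ko_count < 0L || cfg$exclusive_ko_count > cfg$n_ko) {
    stop("exclusive_ko_count must lie in [0, n_ko]")
  }
  if (cfg$n_genome_pairs < 0L) stop("n_genome_pairs must be non-negative")
  for (f in c("pair_shared_fraction_met", "pair_shared_fraction_gen",
              "tagged_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(sprintf("%s must lie in [0, 1]", f))
  }
  if (cfg$family_identity <= 0 || cfg$family_identity > 1) {
    stop("family_identity must lie in (0, 1]")
  }
  if (cfg$between_identity_max <= 0 || cfg$between_identity_max > 1) {
    stop("between_identity_max must lie in (0, 1]")
  }
  if (cfg$richness_noise_sd < 0 || cfg$abundance_shape < 0) {
    stop("richness_noise_sd and abundance_shape must be non-negative")
  }
  if (cfg$tree_tips < 2L) stop("tree_tips must be at least 2")
  structure(cfg, class = "synthetic_config")
}

#' Mutate a protein sequence to an exact target identity
#'
#' Substitutes exactly `round((1 - target_identity) * nchar(seq))`
#' positions of `seq`, chosen uniformly at random, each to a residue
#' different from the original, so the returned sequence has the requested
#' ungapped identity to the input (up to the rounding of the position
#' count).  Uses the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param seq Non-empty amino-acid string over the 20 canonical residues.
#' @param target_identity Identity fraction in (0, 1].
#' @return The mutated sequence (same length).
#' @export
mutate_to_identity <- function(seq, target_identity) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("seq must be a non-empty amino-acid string")
  }
  if (!is.numeric(target_identity) || length(target_identity) != 1L ||
      target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]")
  }
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% .AA_ALPHABET)) {
    stop("seq must use the 20-letter amino-acid alphabet")
  }
  n_sub <- round((1 - target_identity) * length(chars))
  paste(.mutate_chars(chars, n_sub), collapse = "")
}

# Substitute exactly n_sub random positions of a character vector, each to
# a different residue (resampling draws that landed on the original).
.mutate_chars <- function(chars, n_sub) {
  if (n_sub == 0L) return(chars)
  pos <- sample.int(length(chars), n_sub)
  repl <- sample(.AA_ALPHABET, n_sub, replace = TRUE)
  while (any(bad <- repl == chars[pos])) {
    repl[bad] <- sample(.AA_ALPHABET, sum(bad), replace = TRUE)
  }
  chars[pos] <- repl
  chars
}

# Random amino-acid sequence of length n (character vector form).
.random_aa_chars <- function(n) sample(.AA_ALPHABET, n, replace = TRUE)

# Founder pool: pool_size random sequences, rejection-sampled so that all
# pairwise ungapped identities stay below the configured ceiling.
.generate_founders <- function(pool_size, seq_length, ceiling_identity) {
  founders <- matrix("", nrow = pool_size, ncol = seq_length)
  i <- 1L
  attempts <- 0L
  while (i <= pool_size) {
    cand <- .random_aa_chars(seq_length)
    ok <- TRUE
    if (i > 1L) {
      ident <- rowMeans(founders[seq_len(i - 1L), , drop = FALSE] ==
                          matrix(cand, i - 1L, seq_length, byrow = TRUE))
      ok <- all(ident < ceiling_identity)
    }
    if (ok) {
      founders[i, ] <- cand
      i <- i + 1L
    } else {
      attempts <- attempts + 1L
      if (attempts > 1000L * pool_size) {
        stop("could not sample founders below the between-family identity ceiling")
      }
    }
  }
  founders
}

.KO_CATEGORY_POOL <- data.frame(
  category = c("Metabolism", "Metabolism",
               "Genetic Information Processing", "Genetic Information Processing",
               "Environmental Information Processing", "Cellular Processes"),
  subcategory = c("Energy Metabolism", "Carbohydrate Metabolism",
                  "Translation", "Replication and Repair",
                  "Membrane Transport", "Cell Motility"))

#' Generate a complete synthetic study
#'
#' Draws spring geochemistry (sulfate and chloride log-uniform over ranges
#' spanning the vapor-to-reservoir mixing axis), plants per-spring family
#' richness from the configured linear link (clamped to `[1, pool_size]`),
#' draws lognormal family member counts, emits member sequences mutated to
#' the configured within-family identity, builds a KO table with planted
#' metagenome-exclusive KOs, plants within-lineage genome pairs with
#' configured shared-KO fractions per category, draws a MAG summary table
#' and a random phylogeny with a tagged tip subset, and records everything
#' planted in `$truth`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_study`: list with elements
#'   `config`, `geochem`, `proteins` (protein record table with a
#'   `family_truth` column), `truth_family_table`, `ko_table`,
#'   `ko_categories`, `genome_pairs`, `mag_table`, `tree`, `tagged_tips`
#'   and `truth`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be a synthetic_config")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  springs <- sprintf("SP%03d", seq_len(config$n_springs))

  ## geochemistry: log-uniform concentrations spanning the mixing axis
  sulfate <- 10 ^ stats::runif(config$n_springs, log10(5), log10(200))
  chloride <- 10 ^ stats::runif(config$n_springs, log10(0.5), log10(500))
  geochem <- geochem_records(data.frame(
    spring_id = springs,
    pH = round(stats::runif(config$n_springs, 2, 9.5), 2),
    temperature = round(stats::runif(config$n_springs, 40, 92), 1),
    sulfate = sulfate, chloride = chloride))

  ## protein families
  family_ids <- sprintf("FAM%04d", seq_len(config$pool_size))
  founder_chars <- .generate_founders(config$pool_size, config$seq_length,
                                      config$between_identity_max)
  n_sub <- round((1 - config$family_identity) * config$seq_length)
  planted_richness <- pmin(pmax(round(
    config$richness_intercept +
      config$richness_slope * geochem$log_ratio +
      stats::rnorm(config$n_springs, 0, config$richness_noise_sd)), 1L),
    config$pool_size)

  truth_table <- matrix(0L, config$n_springs, config$pool_size,
                        dimnames = list(springs, family_ids))
  prot <- vector("list", config$n_springs)
  for (s in seq_len(config$n_springs)) {
    fams <- sort(sample.int(config$pool_size, planted_richness[s]))
    counts <- as.integer(ceiling(stats::rlnorm(length(fams), meanlog = 1,
                                               sdlog = config$abundance_shape)))
    truth_table[s, fams] <- counts
    fam_of <- rep.int(fams, counts)
    seqs <- vapply(fam_of, function(f) {
      paste(.mutate_chars(founder_chars[f, ], n_sub), collapse = "")
    }, character(1))
    prot[[s]] <- data.frame(
      protein_id = sprintf("%s_P%05d", springs[s], seq_along(fam_of)),
      metagenome_id = springs[s],
      seq = seqs,
      family_truth = family_ids[fam_of])
  }
  proteins <- do.call(rbind, prot)
  rownames(proteins) <- NULL
  class(proteins) <- c("protein_records", "data.frame")

  ## KO universe, categories, counts with planted exclusives
  ko_ids <- sprintf("K%05d", seq_len(config$n_ko))
  n_cat <- min(config$n_categories, nrow(.KO_CATEGORY_POOL))
  cat_pool <- .KO_CATEGORY_POOL[seq_len(n_cat), , drop = FALSE]
  # balanced allocation of KOs over categories (random which KO gets which),
  # so category sizes are a stable property of the configuration
  cat_idx <- sample(rep_len(seq_len(n_cat), config$n_ko))
  ko_categories <- data.frame(ko = ko_ids,
                              category = cat_pool$category[cat_idx],
                              subcategory = cat_pool$subcategory[cat_idx])

  ko_table <- matrix(stats::rpois(config$n_springs * config$n_ko, lambda = 3),
                     config$n_springs, config$n_ko,
                     dimnames = list(springs, ko_ids))
  exclusive_kos <- if (config$exclusive_ko_count > 0L) {
    sort(sample.int(config$n_ko, config$exclusive_ko_count))
  } else integer(0)
  host_spring <- integer(0)
  if (length(exclusive_kos) > 0L) {
    host_spring <- sample.int(config$n_springs, length(exclusive_kos),
                              replace = TRUE)
    for (j in seq_along(exclusive_kos)) {
      ko_table[, exclusive_kos[j]] <- 0L
      ko_table[host_spring[j], exclusive_kos[j]] <-
        stats::rpois(1L, lambda = 5) + 1L
    }
  }
  # every non-exclusive KO must occur in at least two metagenomes, so the
  # planted exclusives are exactly the single-occurrence columns
  if (config$n_springs >= 2L) {
    for (j in setdiff(seq_len(config$n_ko), exclusive_kos)) {
      pos <- which(ko_table[, j] > 0L)
      if (length(pos) < 2L) {
        add <- sample(setdiff(seq_len(config$n_springs), pos), 2L - length(pos))
        ko_table[add, j] <- 1L
      }
    }
  }

  ## within-lineage genome pairs with planted shared-KO fractions
  pair_specs <- list(Metabolism = config$pair_shared_fraction_met,
                     `Genetic Information Processing` = config$pair_shared_fraction_gen)
  genome_pairs <- vector("list", config$n_genome_pairs)
  for (p in seq_len(config$n_genome_pairs)) {
    kos_a <- kos_b <- character(0)
    for (cat in names(pair_specs)) {
      cat_kos <- ko_categories$ko[ko_categories$category == cat]
      n <- config$pair_category_size
      s <- round(pair_specs[[cat]] * n)
      need <- s + 2L * (n - s)
      if (length(cat_kos) < need) {
        stop(sprintf("category '%s' has %d KOs but the pair design needs %d; increase n_ko",
                     cat, length(cat_kos), need))
      }
      picked <- sample(cat_kos, need)
      shared <- picked[seq_len(s)]
      uniq_a <- picked[s + seq_len(n - s)]
      uniq_b <- picked[s + (n - s) + seq_len(n - s)]
      kos_a <- c(kos_a, shared, uniq_a)
      kos_b <- c(kos_b, shared, uniq_b)
    }
    lineage <- sprintf("LIN%02d", p)
    genome_pairs[[p]] <- list(
      a = genome_annotation(sprintf("G%02da", p), kos_a, lineage),
      b = genome_annotation(sprintf("G%02db", p), kos_b, lineage))
  }

  ## MAG summary table
  total_length <- round(stats::runif(config$n_mags, 5e5, 5e6))
  mag_table <- data.frame(
    bin_id = sprintf("Bin%03d", seq_len(config$n_mags)),
    total_length = total_length,
    mapped_reads = round(stats::rlnorm(config$n_mags, log(10), 1) *
                           total_length / 250) + 1L,
    completeness = round(stats::runif(config$n_mags, 20, 100), 1),
    contamination = round(pmin(stats::rexp(config$n_mags, 1 / 3), 40), 1))

  ## phylogeny with tagged tip subset
  tree <- ape::rtree(config$tree_tips)
  tree$tip.label <- sprintf("TIP%03d", seq_len(config$tree_tips))
  n_tag <- max(1L, round(config$tagged_fraction * config$tree_tips))
  tagged_tips <- sort(sample(tree$tip.label, n_tag))
  terminal <- tree$edge[, 2L] <= ape::Ntip(tree)
  tag_terminal <- tree$edge.length[terminal][
    match(tagged_tips, tree$tip.label[tree$edge[terminal, 2L]])]

  truth <- list(slope = config$richness_slope,
                intercept = config$richness_intercept,
                noise_sd = config$richness_noise_sd,
                planted_richness = stats::setNames(planted_richness, springs),
                exclusive_ko_ids = ko_ids[exclusive_kos],
                exclusive_ko_springs = stats::setNames(springs[host_spring],
                                                       ko_ids[exclusive_kos]),
                pair_shared_fraction_met = config$pair_shared_fraction_met,
                pair_shared_fraction_gen = config$pair_shared_fraction_gen,
                tagged_tips = tagged_tips,
                branch_fraction_tip_only = sum(tag_terminal) /
                  sum(tree$edge.length))

  structure(list(config = config, geochem = geochem, proteins = proteins,
                 truth_family_table = truth_table, ko_table = ko_table,
                 ko_categories = ko_categories, genome_pairs = genome_pairs,
                 mag_table = mag_table, tree = tree,
                 tagged_tips = tagged_tips, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d springs, %d proteins (%d planted families), %d KOs, %d genome pairs, %d MAGs, %d-tip tree\n",
    x$config$n_springs, nrow(x$proteins),
    sum(colSums(x$truth_family_table) > 0), x$config$n_ko,
    length(x$genome_pairs), nrow(x$mag_table), ape::Ntip(x$tree)))
  invisible(x)
}
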