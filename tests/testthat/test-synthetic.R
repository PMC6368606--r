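# The synthetic-study generator: exact mutation counts, determinism,
# planted structure, and file round trips.

test_that("mutate_to_identity substitutes exactly the rounded number of positions", {
  set.seed(61)
  s <- random_aa(100)
  expect_identical(mutate_to_identity(s, 1.0), s)
  m <- mutate_to_identity(s, 0.90)
  expect_equal(nchar(m), 100)
  expect_equal(hamming_identity(s, m), 0.90)
  # every realized identity within rounding of the target
  for (t in c(0.95, 0.7, 0.33)) {
    mm <- mutate_to_identity(s, t)
    expect_lte(abs(hamming_identity(s, mm) - t), 1 / nchar(s) / 2 + 1e-12)
  }
  expect_error(mutate_to_identity(s, 0), "target_identity")
  expect_error(mutate_to_identity(s, 1.2), "target_identity")
  expect_error(mutate_to_identity("", 0.9), "non-empty")
})

test_that("synthetic_config validates its fields", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_springs = 0), "positive")
  expect_error(synthetic_config(family_identity = 1.5), "family_identity")
  expect_error(synthetic_config(tagged_fraction = -0.1), "tagged_fraction")
  expect_error(synthetic_config(exclusive_ko_count = 999, n_ko = 10), "exclusive_ko_count")
  expect_error(generate_study(list()), "synthetic_config")
})

test_that("generate_study is deterministic for a fixed config", {
  cfg <- synthetic_config(seed = 7, n_springs = 5, pool_size = 15,
                          richness_intercept = 8, n_mags = 10, tree_tips = 10)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$ko_table, s2$ko_table)
  expect_identical(s1$geochem, s2$geochem)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(synthetic_config(seed = 8, n_springs = 5, pool_size = 15,
                                        richness_intercept = 8, n_mags = 10,
                                        tree_tips = 10))
  expect_false(identical(s1$ko_table, s3$ko_table))
})

test_that("generated studies satisfy their structural invariants", {
  cfg <- synthetic_config(seed = 9, n_springs = 8, pool_size = 30,
                          richness_intercept = 12, richness_slope = 3,
                          exclusive_ko_count = 3, n_ko = 120, n_mags = 20,
                          tree_tips = 20)
  st <- generate_study(cfg)
  # every spring with proteins appears in the geochemistry table
  expect_true(all(unique(st$proteins$metagenome_id) %in% st$geochem$spring_id))
  # truth table row sums equal per-spring protein counts
  expect_equal(unname(rowSums(st$truth_family_table)),
               unname(table(factor(st$proteins$metagenome_id,
                                   levels = rownames(st$truth_family_table)))),
               ignore_attr = TRUE)
  # planted richness matches the number of planted families per spring
  expect_equal(unname(rowSums(st$truth_family_table > 0)),
               unname(st$truth$planted_richness))
  # exactly the planted number of single-occurrence KO columns
  single <- colSums(st$ko_table > 0) == 1
  expect_equal(sum(single), 3L)
  expect_setequal(names(which(single)), st$truth$exclusive_ko_ids)
  # tagged tips are a subset of the tree's tips
  expect_true(all(st$tagged_tips %in% st$tree$tip.label))
  expect_true(all(st$tree$edge.length > 0))
  # within-family identity of members to each other is near the target
  pr <- st$proteins[st$proteins$family_truth == st$proteins$family_truth[1], ]
  if (nrow(pr) >= 2) {
    expect_gte(hamming_identity(pr$seq[1], pr$seq[2]), 0.88)
  }
})

test_that("planted richness is non-decreasing in the mixing proxy when noise-free", {
  cfg <- synthetic_config(seed = 10, n_springs = 12, pool_size = 60,
                          richness_intercept = 20, richness_slope = 6,
                          richness_noise_sd = 0)
  st <- generate_study(cfg)
  o <- order(st$geochem$log_ratio)
  expect_true(all(diff(st$truth$planted_richness[o]) >= 0))
})

test_that("genome pairs carry the planted shared fractions per category", {
  cfg <- synthetic_config(seed = 11, n_springs = 3, pool_size = 5,
                          richness_intercept = 3, n_genome_pairs = 4)
  st <- generate_study(cfg)
  expect_length(st$genome_pairs, 4)
  for (p in st$genome_pairs) {
    d <- differentiation_ratios(p$a, p$b, st$ko_categories)
    met <- d[d$category == "Metabolism", ]
    gen <- d[d$category == "Genetic Information Processing", ]
    n <- cfg$pair_category_size
    expect_equal(met$shared, round(cfg$pair_shared_fraction_met * n))
    expect_equal(gen$shared, round(cfg$pair_shared_fraction_gen * n))
    expect_equal(met$unshared, 2L * (n - met$shared))
  }
})

test_that("a study round-trips through its on-disk representation", {
  cfg <- synthetic_config(seed = 12, n_springs = 3, pool_size = 8,
                          richness_intercept = 4, n_ko = 40, n_mags = 6,
                          tree_tips = 8, n_genome_pairs = 1,
                          pair_category_size = 4)
  st <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)

  pr <- read_protein_fasta(list.files(file.path(dir, "proteins"),
                                      full.names = TRUE))
  expect_setequal(pr$protein_id, st$proteins$protein_id)
  expect_equal(pr$seq[match(st$proteins$protein_id, pr$protein_id)],
               st$proteins$seq)

  ko <- read_ko_table(file.path(dir, "ko_table.tsv"))
  expect_equal(ko, st$ko_table * 1.0)

  g <- read_geochem(file.path(dir, "geochem.tsv"))
  expect_equal(g$log_ratio, st$geochem$log_ratio, tolerance = 1e-9)

  mags <- read_mag_table(file.path(dir, "mag_table.tsv"))
  expect_equal(mags$total_length, st$mag_table$total_length)

  cats <- read_ko_categories(file.path(dir, "ko_categories.tsv"))
  expect_equal(cats$ko, st$ko_categories$ko)

  tr <- parse_newick(paste(readLines(file.path(dir, "tree.nwk")), collapse = ""))
  expect_setequal(tr$tip.label, st$tree$tip.label)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$slope, st$truth$slope)
  expect_setequal(truth$exclusive_ko_ids, st$truth$exclusive_ko_ids)
})
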