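# Local alignment statistics and the greedy identity-cascade clustering.

test_that("align_local matches the exhaustive dynamic-programming oracle", {
  set.seed(101)
  for (i in 1:10) {
    a <- random_aa(sample(12:25, 1))
    b <- random_aa(sample(12:25, 1))
    st <- align_local(a, b)
    expect_equal(st$score, sw_oracle_score(a, b),
                 info = sprintf("pair %d: %s vs %s", i, a, b))
  }
})

test_that("align_local reports identity over aligned columns and coverage of the shorter sequence", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  self <- align_local(s, s)
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage_short, 1.0)

  # single interior substitution (L -> A at position 10): the optimal local
  # alignment spans the full length, so identity is exactly 19/20
  mut <- sub("L", "A", s)
  st <- align_local(s, mut)
  expect_equal(st$identity, 0.95)
  expect_equal(st$coverage_short, 1.0)
  expect_equal(st$score, sw_oracle_score(s, mut))

  # sequences over disjoint alphabets admit no positive-scoring alignment
  none <- align_local(strrep("A", 20), strrep("W", 20))
  expect_equal(none$identity, 0)
  expect_equal(none$coverage_short, 0)

  expect_error(align_local("", "ACD"), "non-empty")
})

test_that("cluster_at groups identical sequences under the lexicographically first id", {
  s <- random_aa(40)
  recs <- protein_records(c("b", "a", "c"), "M1", c(s, s, s))
  cs <- cluster_at(recs, 0.9)
  expect_length(cs$clusters, 1)
  expect_equal(names(cs$clusters), "a")
  expect_setequal(cs$clusters[["a"]], c("a", "b", "c"))
})

test_that("cluster_at separates families and absorbs high-identity members", {
  set.seed(11)
  s1 <- random_aa(60)
  s1b <- mutate_to_identity(s1, 0.95)
  s2 <- random_aa(60)
  # fixture sanity via direct character comparison, not the alignment code
  expect_equal(hamming_identity(s1, s1b), 0.95)
  expect_lt(hamming_identity(s1, s2), 0.25)
  recs <- protein_records(c("s1", "s1b", "s2"), "M1", c(s1, s1b, s2))
  cs <- cluster_at(recs, 0.9)
  expect_length(cs$clusters, 2)
  expect_setequal(cs$assignment[c("s1", "s1b")], "s1")
  expect_equal(unname(cs$assignment["s2"]), "s2")
})

test_that("an exact prefix fully covered by the longer sequence joins its cluster", {
  set.seed(12)
  long <- random_aa(100)
  pre <- substr(long, 1, 70)
  recs <- protein_records(c("long", "pre"), "M1", c(long, pre))
  st <- align_local(pre, long)
  expect_equal(st$coverage_short, 1.0)
  expect_equal(st$identity, 1.0)
  cs <- cluster_at(recs, 0.9)
  expect_length(cs$clusters, 1)
  expect_equal(names(cs$clusters), "long")
})

test_that("cascade reproduces the manual three-level fixture", {
  set.seed(13)
  s1 <- random_aa(60)
  recs <- protein_records(
    c("p1", "p2", "p3", "p4"), "M1",
    c(s1, mutate_to_identity(s1, 0.95), mutate_to_identity(s1, 0.70),
      random_aa(60)))
  fa <- cascade(recs)
  expect_equal(attr(fa, "n_clusters"), c(3L, 2L, 2L))
  # level 90: p1+p2 together, p3 and p4 apart
  l90 <- fa$cluster_90[match(c("p1", "p2", "p3", "p4"), fa$protein_id)]
  expect_equal(l90[1], l90[2])
  expect_length(unique(l90), 3)
  # level 60 merges the p1 representative with p3; final families
  fam <- fa$family[match(c("p1", "p2", "p3", "p4"), fa$protein_id)]
  expect_length(unique(fam), 2)
  expect_equal(fam[1], fam[2])
  expect_equal(fam[1], fam[3])
  expect_false(fam[4] == fam[1])
})

test_that("cascade handles degenerate inputs and rejects bad thresholds", {
  s <- random_aa(60)
  one <- protein_records("p1", "M1", s)
  fa <- cascade(one)
  expect_equal(nrow(fa), 1)
  expect_equal(attr(fa, "n_clusters"), c(1L, 1L, 1L))

  same <- protein_records(c("a", "b", "c"), "M1", rep(s, 3))
  expect_length(unique(cascade(same)$family), 1)

  expect_error(cascade(one, thresholds = c(0.3, 0.6, 0.9)), "decreasing")
  expect_error(cluster_at(one, 0), "threshold")
})

test_that("short proteins are excluded before clustering with a strict 50-aa bound", {
  recs <- protein_records(c("keep", "at50", "short"), "M1",
                          c(random_aa(51), random_aa(50), random_aa(20)))
  kept <- filter_short_proteins(recs)
  expect_equal(kept$protein_id, "keep")
  expect_equal(attr(kept, "n_dropped"), 2L)
  fa <- cascade(recs)
  expect_equal(fa$protein_id, "keep")
  expect_equal(attr(fa, "n_dropped_short"), 2L)
})

test_that("cascade output is a partition, coarsens across levels, and satisfies thresholds post hoc", {
  set.seed(14)
  recs <- make_cluster_fixture(n_fam = 4, n_mem = 3, len = 60)
  fa <- cascade(recs)
  # partition: every protein exactly once
  expect_setequal(fa$protein_id, recs$protein_id)
  expect_false(anyDuplicated(fa$protein_id) > 0)
  # coarsening of cluster counts
  nc <- attr(fa, "n_clusters")
  expect_true(all(diff(nc) <= 0))
  expect_lte(nc[1], nrow(recs))
  # level-90 soundness: every member meets identity/coverage vs its representative
  cs <- cluster_at(recs, 0.9)
  for (rep_id in names(cs$clusters)) {
    rep_seq <- recs$seq[recs$protein_id == rep_id]
    for (m in cs$clusters[[rep_id]]) {
      st <- align_local(recs$seq[recs$protein_id == m], rep_seq)
      expect_gte(st$identity, 0.9 - 1e-9)
      expect_gte(st$coverage_short, 0.8)
    }
  }
})

test_that("final partition is invariant to input order on well-separated fixtures", {
  set.seed(15)
  recs <- make_cluster_fixture(n_fam = 3, n_mem = 3, len = 60)
  fa1 <- cascade(recs)
  perm <- recs[sample(nrow(recs)), , drop = FALSE]
  class(perm) <- class(recs)
  fa2 <- cascade(perm)
  o1 <- fa1$family[match(recs$protein_id, fa1$protein_id)]
  o2 <- fa2$family[match(recs$protein_id, fa2$protein_id)]
  expect_true(same_partition(o1, o2))
})

test_that("cascade recovers the generator's planted families on separated studies", {
  ok <- 0
  for (s in 1:5) {
    cfg <- synthetic_config(seed = s, n_springs = 1, pool_size = 4,
                            richness_intercept = 4, richness_slope = 0,
                            richness_noise_sd = 0, abundance_shape = 0.6,
                            n_genome_pairs = 0, n_mags = 5, tree_tips = 5,
                            seq_length = 80)
    st <- generate_study(cfg)
    fa <- cascade(st$proteins)
    truth <- st$proteins$family_truth[match(fa$protein_id, st$proteins$protein_id)]
    if (isTRUE(all.equal(ari(fa$family, truth), 1))) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("family_abundance tallies counts with explicit zeros and consistent row sums", {
  set.seed(16)
  s1 <- random_aa(60)
  s2 <- random_aa(60)
  recs <- protein_records(
    sprintf("p%d", 1:5),
    c("M1", "M1", "M1", "M2", "M2"),
    c(s1, mutate_to_identity(s1, 0.95), mutate_to_identity(s1, 0.95), s2,
      mutate_to_identity(s2, 0.95)))
  fa <- cascade(recs)
  tab <- family_abundance(fa, recs)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(sort(unname(rowSums(tab))), c(2L, 3L))
  # the family founded by s2 has no M1 proteins: explicit zero retained
  expect_true(any(tab == 0))
  # independent tally by grouping labels
  oracle <- unclass(table(fa$metagenome_id, fa$family))
  expect_equal(unname(tab[rownames(oracle), colnames(oracle)]), unname(oracle))

  # single metagenome, one family of three
  recs1 <- protein_records(c("a", "b", "c"), "M1", rep(s1, 3))
  tab1 <- family_abundance(cascade(recs1))
  expect_equal(unname(tab1[1, 1]), 3L)

  # consistency error when records are missing from the assignment
  extra <- protein_records(c("a", "b", "c", "zz"), "M1", rep(s1, 4))
  expect_error(family_abundance(cascade(recs1), extra), "zz")
})
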