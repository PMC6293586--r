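test_that("induced quartets classify restrictions, polytomies and absences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(as.integer(induced_quartet(t1, c("A", "B", "C", "D"))), 1L)
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(as.integer(induced_quartet(star, c("A", "B", "C", "D"))), 0L)
  expect_true(is.na(induced_quartet(t1, c("A", "B", "C", "E"))))
  # caterpillar quartets match the independent restriction oracle
  cat5 <- ape::read.tree(text = "(((((A,B),C),D),E));")
  set.seed(3)
  for (k in 1:10) {
    tr <- ape::rtree(7)
    four <- sample(tr$tip.label, 4)
    expect_equal(as.integer(induced_quartet(tr, four)),
                 oracle_quartet(tr, four))
  }
  expect_equal(as.integer(induced_quartet(cat5, c("A", "B", "C", "D"))),
               oracle_quartet(cat5, c("A", "B", "C", "D")))
})

test_that("quartet score equals the brute-force double loop and its maximum", {
  t6 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  gts <- list(t6, t6, t6)
  expect_equal(quartet_score(ape::unroot(t6), gts), 3 * choose(6, 4))
  set.seed(9)
  rand_gts <- lapply(1:8, function(i) {
    g <- ape::rtree(6)
    g$tip.label <- sample(c("A", "B", "C", "D", "E", "F"))
    g
  })
  cand <- ape::unroot(ape::read.tree(text = "((A,C),((B,D),(E,F)));"))
  brute <- 0L
  taxa <- sort(cand$tip.label)
  for (g in rand_gts) for (q in asplit(combn(taxa, 4), 2)) {
    cg <- oracle_quartet(g, q)
    cc <- oracle_quartet(cand, q)
    if (!is.na(cg) && cg > 0 && cg == cc) brute <- brute + 1L
  }
  expect_equal(quartet_score(cand, rand_gts), brute)
})

test_that("exact search enumerates all topologies and recovers the plurality tree", {
  t6 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  res <- exact_quartet_search(list(t6, t6))
  expect_equal(res$n_topologies, 105)
  expect_length(res$trees, 1)
  expect_equal(phangorn::RF.dist(res$trees[[1]], ape::unroot(t6)), 0)
  # invariant to gene-tree order
  set.seed(20)
  mix <- c(list(t6, t6, t6), lapply(1:4, function(i) {
    r <- ape::rtree(6)
    r$tip.label <- sample(c("A", "B", "C", "D", "E", "F"))
    r
  }))
  r1 <- exact_quartet_search(mix)
  r2 <- exact_quartet_search(rev(mix))
  expect_equal(r1$score, r2$score)
  expect_setequal(vapply(r1$trees, ape::write.tree, ""),
                  vapply(r2$trees, ape::write.tree, ""))
  expect_error(exact_quartet_search(list(ape::rtree(9))), "8 taxa")
})

test_that("exact search is consistent under the multispecies coalescent", {
  sp <- ape::read.tree(text = paste0(
    "((A:0.05,B:0.05):0.02,((C:0.04,D:0.04):0.02,(E:0.03,F:0.03):0.02):0.01);"))
  cfg <- sim_config(n_taxa = 6, coalescent_theta = 0.02, n_genes = 500,
                    gene_rate_sigma = 0, lineage_rate_sigma = 0, seed = 17)
  gts <- simulate_gene_trees(sp, cfg)
  res <- exact_quartet_search(gts)
  expect_true(any(vapply(res$trees, function(t)
    phangorn::RF.dist(t, ape::unroot(sp)) == 0, logical(1))))
})

test_that("branch support frequencies sum to one and reflect conflict", {
  t6 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  t6$edge.length <- rep(1, nrow(t6$edge))
  bs <- branch_support_table(t6, list(t6, t6, t6))
  expect_true(all(abs(bs$f1 + bs$f2 + bs$f3 - 1) < 1e-9))
  expect_true(all(bs$f1 == 1))
  # 50/50 conflict on one branch
  alt <- ape::read.tree(text = "((A,C),((B,D),(E,F)));")
  alt$edge.length <- rep(1, nrow(alt$edge))
  bs2 <- branch_support_table(t6, c(rep(list(t6), 5), rep(list(alt), 5)))
  row_ab <- bs2[vapply(strsplit(bs2$bipartition, " \\| "), function(s)
    setequal(strsplit(s[1], ",")[[1]], c("A", "B")) ||
      setequal(strsplit(s[2], ",")[[1]], c("A", "B")), logical(1)), ]
  expect_equal(nrow(row_ab), 1)
  expect_equal(row_ab$f1, 0.5, tolerance = 1e-9)
  expect_lt(row_ab$f3 + row_ab$f2, 0.51)
})

test_that("the subsampling experiment records recovery per replicate", {
  t6 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  gts <- rep(list(t6), 12)
  ex <- subsampling_experiment(gts, keep_fraction = 0.5, n_replicates = 4,
                               focal_clade = c("C", "D"), seed = 5)
  expect_equal(ex$recovery_fraction, 1)
  expect_equal(ex$mean_f1_recovered, 1)
  ex_full <- subsampling_experiment(gts, keep_fraction = 1, n_replicates = 3,
                                    focal_clade = c("E", "F"), seed = 5)
  expect_true(all(ex_full$table$recovered))
  expect_error(
    subsampling_experiment(gts, 0.5, 2, focal_clade = LETTERS[1:6], seed = 1),
    "proper subset")
})
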