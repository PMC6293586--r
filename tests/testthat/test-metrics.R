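test_that("p-distance counts only mutually informative sites", {
  expect_equal(p_distance("ACDEF", "ACDEY"), 0.2)
  expect_equal(p_distance("AC-EF", "ACDEY"), 0.25)
  expect_true(is.na(p_distance("---", "ACD")))
  expect_error(p_distance("AC", "ACD"), "length")
  # symmetry and range on random pairs
  set.seed(1)
  for (i in 1:10) {
    a <- sample(c(AA, "-", "X"), 30, replace = TRUE)
    b <- sample(c(AA, "-", "X"), 30, replace = TRUE)
    d <- p_distance(a, b)
    expect_identical(d, p_distance(b, a))
    if (!is.na(d)) expect_true(d >= 0 && d <= 1)
  }
})

test_that("patristic distances are path sums and match a graph-algorithm oracle", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1,D:1):0.5);")
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 3)
  set.seed(42)
  rt <- ape::rtree(10)
  expect_equal(patristic_matrix(rt),
               floyd_warshall_patristic(rt)[rt$tip.label, rt$tip.label],
               tolerance = 1e-12)
  # four-point condition on random trees
  d10 <- patristic_matrix(rt)
  tips <- rt$tip.label
  set.seed(5)
  for (k in 1:20) {
    q <- sample(tips, 4)
    s <- c(d10[q[1], q[2]] + d10[q[3], q[4]],
           d10[q[1], q[3]] + d10[q[2], q[4]],
           d10[q[1], q[4]] + d10[q[2], q[3]])
    s <- sort(s)
    expect_lt(abs(s[2] - s[3]), 1e-9)
  }
})

test_that("root-to-tip distances and variance follow the worked examples", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  rt <- root_to_tip(tr, outgroup = "C")
  expect_equal(unname(rt$distances[c("A", "B")]), c(1, 1))
  expect_equal(rt$variance, 0)

  tr2 <- ape::read.tree(text = "((A:1,B:3):1,C:2);")
  rt2 <- root_to_tip(tr2, ingroup = c("A", "B", "C"))
  expect_equal(sort(unname(rt2$distances)), c(2, 2, 4))
  expect_equal(rt2$variance, 4 / 3)

  # scaling all branch lengths by k multiplies the variance by k^2
  tr3 <- tr2
  tr3$edge.length <- tr3$edge.length * 2.5
  expect_equal(root_to_tip(tr3, ingroup = c("A", "B", "C"))$variance,
               2.5^2 * rt2$variance)

  # ultrametric trees have zero variance whatever the leaf order
  set.seed(8)
  u <- ape::rcoal(8)
  expect_equal(root_to_tip(u, ingroup = u$tip.label)$variance, 0,
               tolerance = 1e-12)
  expect_error(root_to_tip(tr, outgroup = c("A", "B", "C")), "ingroup")
})

test_that("posterior rate summaries average draws with percentile intervals", {
  tr1 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  s1 <- posterior_rate_summary(list(tr1, tr1, tr1), ingroup = c("A", "B"),
                               outgroup = "C", n_draws = 50, seed = 3)
  expect_equal(s1$ci_low, s1$mean_root_to_tip)
  expect_equal(s1$ci_high, s1$mean_root_to_tip)

  tr3 <- ape::read.tree(text = "((A:3,B:1):1,C:2);")
  s2 <- posterior_rate_summary(list(tr1, tr3), ingroup = c("A", "B"),
                               outgroup = "C", n_draws = 2000, seed = 4)
  # taxon A alternates between distance 1 and 3: mean ~ 2
  se <- 1 / sqrt(2000)
  expect_lt(abs(s2$mean_root_to_tip[s2$taxon == "A"] - 2), 3 * se)
  expect_equal(s2$n_samples, c(2000L, 2000L))
})

test_that("RCFV measures compositional spread", {
  same <- mk_msa(c(x = "ARND", y = "ARND", z = "DNRA"))
  expect_equal(as.numeric(rcfv(same)), 0)
  opposite <- mk_msa(c(x = "AA", y = "RR"))
  expect_equal(as.numeric(rcfv(opposite)), 1)
  # invariant to column order
  a <- mk_msa(c(x = "ARNDAR", y = "NDARRA", z = "AAARRN"))
  b <- msa(unclass(a)[, c(3, 1, 4, 2, 6, 5)], "perm")
  expect_equal(as.numeric(rcfv(a)), as.numeric(rcfv(b)))
  expect_gte(as.numeric(rcfv(a)), 0)
})

test_that("missing fraction counts absent taxa and gap cells", {
  full <- mk_msa(c(a = "ARND", b = "ARND"))
  expect_equal(missing_fraction(full), 0)
  expect_equal(missing_fraction(full, expected_taxa = c("a", "b", "c", "d")),
               0.5)
  gappy <- mk_msa(c(a = "AR-D", b = "XRND"))
  expect_equal(missing_fraction(gappy), 0.25)
})

test_that("Poisson distance correction matches the closed form and is monotone", {
  expect_equal(as.numeric(correct_distance(0)), 0)
  expect_equal(as.numeric(correct_distance(0.5)), 0.7098, tolerance = 1e-4)
  p <- seq(0, 0.9, by = 0.05)
  expect_true(all(diff(as.numeric(correct_distance(p))) > 0))
  capped <- correct_distance(0.99)
  expect_equal(as.numeric(capped), as.numeric(correct_distance(0.94)))
  expect_error(correct_distance(-0.1), "negative")
})

test_that("neighbor joining recovers additive trees exactly and flags problems", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- patristic_matrix(tr)
  nj1 <- nj_gene_tree(d)
  expect_equal(sort(nj1$tip.label), c("A", "B", "C", "D"))
  expect_equal(phangorn::RF.dist(nj1, ape::unroot(tr)), 0)
  expect_equal(patristic_matrix(nj1)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # continuity: a tiny perturbation keeps the topology
  set.seed(2)
  eps <- matrix(stats::rnorm(16, 0, 1e-6), 4, 4)
  eps <- (eps + t(eps)) / 2
  diag(eps) <- 0
  d2 <- d + eps
  expect_equal(phangorn::RF.dist(nj_gene_tree(d2), ape::unroot(tr)), 0)
  # unavailable entries signal a skip
  d3 <- d
  d3["A", "B"] <- d3["B", "A"] <- NA
  expect_error(nj_gene_tree(d3), class = "phylosieve_skip")
})
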