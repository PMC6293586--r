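test_that("pruning matches brute-force enumeration and closed forms", {
  m <- poisson_model(gamma_shape = 0.6, n_categories = 3,
                     prop_invariant = 0.15)
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.05,D:0.3):0.1);")
  aln <- mk_msa(c(A = "ACW", B = "RCW", C = "A-W", D = "NCX"))
  ll <- site_log_likelihoods(aln, tr, m)
  bb <- brute_force_loglik(aln, tr, m)
  expect_lt(max(abs(ll - bb) / abs(bb)), 1e-10)

  # single leaf, uniform frequencies
  m0 <- poisson_model()
  one <- msa(matrix("A", 1, 1, dimnames = list("A", NULL)))
  expect_equal(site_log_likelihoods(one, ape::read.tree(text = "(A:1);"), m0),
               log(1 / 20))

  # two identical one-site sequences at zero distance: ln(pi)
  two <- mk_msa(c(A = "A", B = "A"))
  expect_equal(
    site_log_likelihoods(two, ape::read.tree(text = "(A:0,B:0);"), m0),
    log(1 / 20))

  # 20-state equal-rates closed form for a shared state at path length 0.1
  tr2 <- ape::read.tree(text = "(A:0.04,B:0.06);")
  closed <- log((1 / 20) * (1 / 20 + (19 / 20) * exp(-20 * 0.1 / 19)))
  expect_equal(site_log_likelihoods(two, tr2, m0), closed, tolerance = 1e-10)
})

test_that("likelihood is invariant to rerooting and gamma limits behave", {
  m <- poisson_model(gamma_shape = 0.9, n_categories = 4,
                     prop_invariant = 0.1)
  set.seed(7)
  tr <- ape::rtree(6)
  aln <- simulate_alignment(tr, m, 40, seed = 2)
  ll <- tree_log_likelihood(aln, tr, m)
  for (og in c("t1", "t3")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(aln, rr, m), ll, tolerance = 1e-10)
  }
  # gamma categories average to exactly 1
  expect_equal(mean(discrete_gamma_rates(0.3, 4)), 1)
  expect_equal(mean(discrete_gamma_rates(5, 8)), 1)
  # k = 1 reduces to the homogeneous model; huge alpha approaches it
  m1 <- poisson_model(n_categories = 1)
  mk4 <- poisson_model(gamma_shape = 1e6, n_categories = 4)
  ll1 <- tree_log_likelihood(aln, tr, m1)
  expect_equal(tree_log_likelihood(aln, tr, mk4), ll1, tolerance = 1e-6)
  # all-gap column contributes exactly zero log-likelihood
  gap <- msa(matrix("-", 6, 1, dimnames = list(tr$tip.label, NULL)))
  expect_equal(site_log_likelihoods(gap, tr, m), 0)
})

test_that("independent likelihood implementation agrees on random trees", {
  m <- poisson_model(gamma_shape = 0.7, n_categories = 4)
  set.seed(12)
  tr <- ape::rtree(7)
  aln <- simulate_alignment(tr, m, 60, seed = 3)
  fit <- phangorn::pml(ape::unroot(tr),
                       phangorn::phyDat(unclass(aln), type = "AA"),
                       k = 4, shape = 0.7)
  expect_equal(tree_log_likelihood(aln, tr, m), fit$logLik,
               tolerance = 1e-8)
})

test_that("branch-length optimization ascends and recovers simulated lengths", {
  m <- poisson_model()
  true_tr <- ape::read.tree(text = "((A:0.15,B:0.25):0.2,(C:0.1,D:0.3):0.1);")
  aln <- simulate_alignment(true_tr, m, 50000, seed = 13)
  start <- true_tr
  start$edge.length <- rep(0.1, nrow(start$edge))
  ll0 <- tree_log_likelihood(aln, start, m)
  fit <- optimize_branch_lengths(aln, start, m)
  expect_gte(attr(fit, "loglik"), ll0)
  # recovered lengths within 10% of truth (consistency at 50k sites)
  tru <- ape::reorder.phylo(true_tr, "postorder")
  expect_true(all(abs(fit$edge.length - tru$edge.length) /
                    tru$edge.length < 0.10))

  # duplicating the data leaves optima unchanged and doubles the likelihood
  dbl <- msa(cbind(unclass(aln), unclass(aln))[, ], "dbl")
  fit2 <- optimize_branch_lengths(aln, fit, m)
  fit_dbl <- optimize_branch_lengths(dbl, fit, m)
  expect_equal(fit_dbl$edge.length, fit2$edge.length, tolerance = 1e-3)
  expect_equal(attr(fit_dbl, "loglik"), 2 * attr(fit2, "loglik"),
               tolerance = 1e-6)
})

test_that("topology enumeration has double-factorial counts in a stable order", {
  expect_equal(length(enumerate_topologies(c("a", "b", "c", "d"))), 3)
  t5 <- enumerate_topologies(letters[1:5])
  expect_equal(length(t5), 15)
  expect_equal(length(enumerate_topologies(letters[1:6])), 105)
  for (tr in t5) expect_setequal(tr$tip.label, letters[1:5])
  # deterministic order
  expect_identical(vapply(t5, ape::write.tree, ""),
                   vapply(enumerate_topologies(letters[1:5]), ape::write.tree, ""))
})

test_that("topology search maximizes the likelihood and honours constraints", {
  m <- poisson_model()
  true_tr <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.3,((C:0.1,D:0.1):0.3,E:0.2):0.1);")
  aln <- simulate_alignment(true_tr, m, 500, seed = 4)
  res <- search_topology(aln, m)
  expect_equal(res$n_evaluated, 15)
  expect_true(satisfies_constraint(res$tree, list(c("A", "B"))))
  # scored best really is the max over all candidates
  lls <- vapply(enumerate_topologies(rownames(aln)), function(tp)
    attr(optimize_branch_lengths(aln, tp, m), "loglik"), numeric(1))
  expect_equal(res$loglik, max(lls), tolerance = 1e-6)
  # constraint filtering keeps only satisfying topologies
  con <- search_topology(aln, m, constraint = list(c("C", "D", "E")))
  expect_true(satisfies_constraint(con$tree, list(c("C", "D", "E"))))
  expect_lt(con$n_evaluated, 15)
  expect_error(
    search_topology(aln, m, constraint = list(c("A", "B"), c("B", "C"))),
    "overlap")
})

test_that("gene-wise deltas are zero at identity, additive, and discriminate topologies", {
  m <- poisson_model()
  tA <- ape::read.tree(text = "((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3);")
  tB <- ape::read.tree(text = "((A:0.1,C:0.1):0.3,(B:0.1,D:0.1):0.3);")
  n_genes <- 100
  alns <- lapply(seq_len(n_genes), function(g)
    simulate_alignment(tA, m, 300, seed = 1000 + g,
                       gene_id = sprintf("g%03d", g)))
  concat <- msa(do.call(cbind, lapply(alns, unclass)), "concat")
  part <- data.frame(gene_id = vapply(alns, phylosieve:::gene_id, ""),
                     start = seq(0, by = 300, length.out = n_genes),
                     end = seq(300, by = 300, length.out = n_genes))
  # identity: same tree on both sides gives all-zero deltas
  d0 <- gene_deltas(concat, part, tA, tA, m)
  expect_equal(d0$delta, rep(0, n_genes))
  # additivity and discrimination
  d <- gene_deltas(concat, part, tA, tB, m)
  expect_equal(sum(d$delta),
               attr(d, "ll_unconstrained") - attr(d, "ll_constrained"),
               tolerance = 1e-6)
  expect_gt(mean(d$delta > 0), 0.9)
  # overlapping partitions are rejected
  bad <- part
  bad$start[2] <- 100
  expect_error(gene_deltas(concat, bad, tA, tB, m), "overlap")
})
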