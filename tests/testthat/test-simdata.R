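test_that("species-tree simulation honours the clock limit, overrides and determinism", {
  cfg <- sim_config(n_taxa = 6, tree_height = 0.4, lineage_rate_sigma = 0,
                    gene_rate_sigma = 0, seed = 11)
  tr <- simulate_species_tree(cfg)
  expect_equal(ape::Ntip(tr), 6)
  root <- ape::Ntip(tr) + 1
  depths <- ape::dist.nodes(tr)[root, seq_len(6)]
  expect_equal(unname(depths), rep(0.4, 6), tolerance = 1e-12)

  cfg2 <- sim_config(n_taxa = 6, tree_height = 0.4, lineage_rate_sigma = 0,
                     lineage_rate_overrides = list(t03 = 5), seed = 11)
  tr2 <- simulate_species_tree(cfg2)
  i <- match("t03", tr2$tip.label)
  expect_equal(tr2$edge.length[tr2$edge[, 2] == i],
               5 * tr$edge.length[tr$edge[, 2] == match("t03", tr$tip.label)])

  expect_identical(ape::write.tree(simulate_species_tree(cfg)),
                   ape::write.tree(simulate_species_tree(cfg)))
  expect_error(sim_config(n_taxa = 3), "n_taxa")
})

test_that("gene trees equal the species tree under theta = 0 and scale with the gene rate", {
  cfg <- sim_config(n_taxa = 8, n_genes = 10, coalescent_theta = 0,
                    gene_rate_sigma = 0.6, seed = 4)
  sp <- simulate_species_tree(cfg)
  gts <- simulate_gene_trees(sp, cfg)
  for (gt in gts) {
    expect_equal(phangorn::RF.dist(ape::unroot(gt), ape::unroot(sp)), 0)
    r <- attr(gt, "gene_rate")
    expect_equal(sum(gt$edge.length), r * sum(sp$edge.length),
                 tolerance = 1e-12)
  }
  bad <- cfg
  bad$coalescent_theta <- -1
  expect_error(simulate_gene_trees(sp, bad), "theta")
})

test_that("MSC gene-tree discordance matches the closed form 2/3 exp(-T)", {
  theta <- 0.05
  Tcoal <- 0.1
  sp <- ape::read.tree(text = sprintf(
    "(O:1,(C:0.5,(A:0.3,B:0.3):%.10f):0.5);", Tcoal * theta))
  cfg <- sim_config(n_taxa = 4, coalescent_theta = theta, n_genes = 2000,
                    gene_rate_sigma = 0, lineage_rate_sigma = 0, seed = 7)
  gts <- simulate_gene_trees(sp, cfg)
  codes <- vapply(gts, induced_quartet, integer(1),
                  four_taxa = c("A", "B", "C", "O"))
  p_minor <- (2 / 3) * exp(-Tcoal) / 2
  se <- sqrt(p_minor * (1 - p_minor) / 2000)
  for (minor in 2:3)
    expect_lt(abs(mean(codes == minor) - p_minor), 3 * se)
})

test_that("alignment simulation matches closed-form divergence and stationarity", {
  m <- poisson_model()
  # zero branch lengths: all taxa identical to the root draw
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  a0 <- simulate_alignment(tr0, m, 50, seed = 2)
  expect_true(all(apply(unclass(a0), 2, function(col) length(unique(col)) == 1)))

  # two taxa, total path 0.1: fraction differing ~ JC20 closed form
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  a <- simulate_alignment(tr, m, 10000, seed = 5)
  p_obs <- p_distance(unclass(a)["A", ], unclass(a)["B", ])
  p_exp <- jc20_pdiff(0.1)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # long branch: child composition approaches stationarity
  freqs <- (1:20) / sum(1:20)
  m2 <- subst_model(frequencies = freqs)
  a2 <- simulate_alignment(ape::read.tree(text = "(A:25,B:25);"), m2, 20000,
                           seed = 6)
  comp <- tabulate(match(unclass(a2)["B", ], AA), 20) / 20000
  se <- sqrt(freqs * (1 - freqs) / 20000)
  expect_true(all(abs(comp - freqs) < 3 * se + 1e-9))
})

test_that("composition bias, occupancy masking and contamination behave as stated", {
  base <- sim_config(n_taxa = 8, n_genes = 12, occupancy_target = 1,
                     gene_length_range = c(80, 80), seed = 3)
  ds <- build_dataset(base)

  # strength 0: alignments unchanged
  cfg0 <- base
  cfg0$composition_bias <- list(
    list(taxon = "t01", target = rep(1 / 20, 20), strength = 0))
  expect_identical(inject_bias_and_gaps(ds, cfg0)$alignments, ds$alignments)

  # strength 1, all mass on one state: the biased taxon becomes that state
  eA <- c(1, rep(0, 19))
  cfg1 <- base
  cfg1$composition_bias <- list(
    list(taxon = "t01", target = eA, strength = 1))
  ds1 <- inject_bias_and_gaps(ds, cfg1)
  expect_true(all(unclass(ds1$alignments[[1]])["t01", ] == "A"))

  # occupancy: realized occupancy just at or below the target
  cfg <- sim_config(n_taxa = 20, n_genes = 100, occupancy_target = 0.7,
                    gene_length_range = c(60, 60), seed = 9)
  ds2 <- build_dataset(cfg)
  occ <- mean(ds2$occupancy_mask)
  expect_lte(occ, 0.7)
  expect_gt(occ, 0.7 - 1 / (100 * 20))
  expect_true(all(rowSums(ds2$occupancy_mask) >= 4))
  # conservation: removed cells match (1 - occupancy) * G * T exactly
  expect_equal(sum(!ds2$occupancy_mask), round((1 - occ) * 100 * 20))
  # masked taxa really are absent from the alignments
  g1_gone <- colnames(ds2$occupancy_mask)[!ds2$occupancy_mask[1, ]]
  expect_false(any(g1_gone %in% rownames(ds2$alignments[[1]])))

  expect_error(sim_config(occupancy_target = 0), "occupancy")
})

test_that("datasets are fully determined by config and seed", {
  cfg <- sim_config(n_taxa = 6, n_genes = 5, occupancy_target = 0.8,
                    contamination_events = list(
                      list(gene = 2L, victim = "t01", donor = "t04")),
                    seed = 21)
  d1 <- build_dataset(cfg)
  d2 <- build_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(d1$contamination_log$gene, 2L)
  expect_equal(d1$contamination_log$victim, "t01")

  dir1 <- file.path(tempdir(), "ds_a")
  dir2 <- file.path(tempdir(), "ds_b")
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(dir1, f1))),
                   unname(tools::md5sum(file.path(dir2, f1))))
})

test_that("clock configurations yield zero root-to-tip variance in every gene tree", {
  fx <- make_fixtures("clock", seed = 2)
  for (gt in fx$dataset$gene_trees_true) {
    rt <- root_to_tip(gt, ingroup = gt$tip.label)
    expect_equal(rt$variance, 0, tolerance = 1e-20)
  }
})

test_that("mean simulated site log-likelihood is reproducible across independent batches", {
  # simulator/likelihood consistency: both batches estimate the model's
  # expected per-site entropy rate on the true tree
  m <- poisson_model(gamma_shape = 0.8, n_categories = 4)
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.15,D:0.25):0.1);")
  mean_ll <- function(seed) {
    a <- simulate_alignment(tr, m, 10000, seed = seed)
    ll <- site_log_likelihoods(a, tr, m)
    c(mean(ll), sd(ll) / sqrt(length(ll)))
  }
  b1 <- mean_ll(101)
  b2 <- mean_ll(202)
  expect_lt(abs(b1[1] - b2[1]), 3 * sqrt(b1[2]^2 + b2[2]^2))
})
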