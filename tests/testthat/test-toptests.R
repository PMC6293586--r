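test_that("SOWH test detects a violated constraint and respects the add-one formula", {
  m <- poisson_model()
  # truth separates A+B; constraining A+C must be rejected with strong data
  true_tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.4,(C:0.1,D:0.1):0.4);")
  aln <- simulate_alignment(true_tr, m, 500, seed = 31)
  res <- sowh_test(aln, m, list(c("A", "C")), n_replicates = 19, seed = 8)
  expect_gt(res$delta_observed, 0)
  expect_equal(res$p_value,
               (1 + sum(res$delta_null >= res$delta_observed)) / 20)
  expect_equal(res$p_value, 1 / 20)          # all nulls far below delta_obs
  expect_length(res$delta_null, 19)
  expect_gt(min(res$p_value), 0)             # add-one: never zero

  # boundary: the unconstrained tree satisfies the constraint -> delta 0, p 1
  res0 <- sowh_test(aln, m, list(c("A", "B")), n_replicates = 19, seed = 9)
  expect_equal(res0$delta_observed, 0)
  expect_equal(res0$p_value, 1)
  expect_error(sowh_test(aln, m, list(c("A", "C")), n_replicates = 5), ">= 19")
})

test_that("delta summaries filter on |delta| and count support groups", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3"), delta = c(4, -2, 5))
  s <- delta_summary(rec, cutoff = 3)
  expect_equal(s$n_retained, 2L)
  expect_equal(unname(s$counts), c(2L, 0L))
  expect_equal(s$ordered$delta, c(5, 4))
  expect_warning(s0 <- delta_summary(data.frame(gene_id = "g", delta = 0)),
                 "cutoff")
  expect_equal(s0$n_retained, 0L)
  # counts invariant to gene order
  s2 <- delta_summary(rec[c(3, 1, 2), ], cutoff = 3)
  expect_equal(s2$counts, s$counts)
})

screen_rows <- function(n, seed, effect = 0) {
  set.seed(seed)
  rows <- data.frame(rcfv = runif(n), rt_variance = rexp(n),
                     saturation = runif(n), missing_fraction = runif(n))
  z <- (rows$rcfv - mean(rows$rcfv)) / sd(rows$rcfv)
  rows$delta <- effect * z + rnorm(n, 0, 1) + 5 * sign(rnorm(n))
  rows
}

test_that("the confounder screen is calibrated under the null", {
  hits <- 0L
  n_screens <- 200
  for (i in seq_len(n_screens)) {
    rows <- screen_rows(40, seed = 4000 + i)
    sc <- confounder_screen(rows, n_permutations = 199, seed = i, cutoff = 3)
    if (sc$permutation_p_value < 0.05) hits <- hits + 1L
  }
  band <- qbinom(c(0.025, 0.975), n_screens, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("the confounder screen finds planted effects and perfect fits", {
  # delta an exact linear function of rcfv: R^2 = 1, F p ~ 0
  rows <- screen_rows(60, seed = 77)
  rows$delta <- 10 + 4 * rows$rcfv
  sc <- suppressWarnings(confounder_screen(rows, n_permutations = 99,
                                           seed = 1, cutoff = 3))
  expect_equal(sc$r_squared, 1, tolerance = 1e-8)
  expect_lt(sc$f_p_value, 1e-12)

  # power: planted dependence of delta on rcfv
  rows2 <- screen_rows(100, seed = 55, effect = 5)
  sc2 <- confounder_screen(rows2, n_permutations = 199, seed = 2, cutoff = 3)
  expect_lt(sc2$f_p_value, 0.01)
})

test_that("Wilks' lambda is invariant to row duplication and affine rescaling", {
  rows <- screen_rows(40, seed = 12)
  sc1 <- confounder_screen(rows, n_permutations = 199, seed = 3)
  dup <- rbind(rows, rows)
  sc2 <- confounder_screen(dup, n_permutations = 199, seed = 3)
  expect_equal(sc2$wilks_lambda, sc1$wilks_lambda, tolerance = 1e-10)

  resc <- rows
  resc$rcfv <- 100 * resc$rcfv - 7
  resc$saturation <- 0.01 * resc$saturation + 3
  sc3 <- confounder_screen(resc, n_permutations = 199, seed = 3)
  expect_equal(sc3$wilks_lambda, sc1$wilks_lambda, tolerance = 1e-10)
  expect_equal(sc3$permutation_p_value, sc1$permutation_p_value)
})
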