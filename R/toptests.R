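# Topology hypothesis testing and signal dissection: the SOWH parametric
# bootstrap, delta-distribution summaries with the |delta| > 3 cutoff, and
# the confounder screen (multiple regression + permutation test on Wilks'
# lambda over the per-gene diagnostics).

# Golden-section fit of the gamma shape on a fixed tree (branch lengths
# held), then a grid over prop_invariant, then branch lengths re-fit.
fit_rate_model <- function(alignment, tree, model,
                           alpha_bounds = c(0.05, 10),
                           pinv_grid = seq(0, 0.5, by = 0.05)) {
  refit <- model
  if (!is.null(model$gamma_shape)) {
    f <- function(a) {
      m2 <- subst_model(model$exchangeabilities, model$frequencies,
                        gamma_shape = a, n_categories = model$n_categories,
                        prop_invariant = refit$prop_invariant)
      tree_log_likelihood(alignment, tree, m2)
    }
    opt <- optimize(f, interval = alpha_bounds, maximum = TRUE, tol = 1e-3)
    refit$gamma_shape <- opt$maximum
  }
  if (model$prop_invariant > 0 || !is.null(model$gamma_shape)) {
    lls <- vapply(pinv_grid, function(p) {
      m2 <- subst_model(model$exchangeabilities, model$frequencies,
                        gamma_shape = refit$gamma_shape,
                        n_categories = model$n_categories,
                        prop_invariant = p)
      tree_log_likelihood(alignment, tree, m2)
    }, numeric(1))
    refit$prop_invariant <- pinv_grid[which.max(lls)]
  }
  subst_model(model$exchangeabilities, model$frequencies,
              gamma_shape = refit$gamma_shape,
              n_categories = model$n_categories,
              prop_invariant = refit$prop_invariant)
}

#' SOWH parametric-bootstrap topology test
#'
#' Compares the observed likelihood deficit of a monophyly constraint,
#' `delta_obs = ll(best unconstrained) - ll(best constrained)`, against the
#' null distribution of the same statistic computed on `n_replicates`
#' datasets simulated on the fitted constrained tree (branch lengths, gamma
#' shape and invariant proportion fitted on the constrained topology).
#' The reported p-value uses the add-one Monte-Carlo formula
#' `(1 + #(delta_null >= delta_obs)) / (n_replicates + 1)`, so it is never 0.
#'
#' @param alignment an [msa].
#' @param model a [subst_model]; rate parameters are re-fit on the
#'   constrained tree before simulating.
#' @param constraint monophyly constraint (see [satisfies_constraint()]).
#' @param n_replicates number of parametric-bootstrap replicates (>= 19).
#' @param seed RNG seed.
#' @param mode search mode passed to [search_topology()].
#' @return object of class `sowh_result`: list with `delta_observed`,
#'   `delta_null`, `p_value`, `n_replicates`, `model_used`,
#'   `constraint_label`, `tree_unconstrained`, `tree_constrained`.
#' @export
sowh_test <- function(alignment, model, constraint, n_replicates = 99L,
                      seed = 1L, mode = "auto") {
  if (n_replicates < 19) stop_invalid("n_replicates must be >= 19")
  unc <- search_topology(alignment, model, constraint = NULL, mode = mode)
  con <- search_topology(alignment, model, constraint = constraint, mode = mode)
  delta_obs <- unc$loglik - con$loglik
  if (delta_obs < -1e-6)
    stop_invalid("constrained search beat the unconstrained search; ",
                 "topology search failed")
  delta_obs <- max(delta_obs, 0)

  fitted_model <- fit_rate_model(alignment, con$tree, model)
  con_fit <- optimize_branch_lengths(alignment, con$tree, fitted_model)

  delta_null <- vapply(seq_len(n_replicates), function(r) {
    sim <- simulate_alignment(con_fit, fitted_model, ncol(alignment),
                              seed = derive_seed(seed, r),
                              gene_id = sprintf("sowh_rep%03d", r))
    u <- search_topology(sim, fitted_model, constraint = NULL, mode = mode)
    c0 <- search_topology(sim, fitted_model, constraint = constraint,
                          mode = mode)
    max(u$loglik - c0$loglik, 0)
  }, numeric(1))

  p <- (1 + sum(delta_null >= delta_obs)) / (n_replicates + 1)
  structure(list(delta_observed = delta_obs, delta_null = delta_null,
                 p_value = p, n_replicates = n_replicates,
                 model_used = fitted_model,
                 constraint_label = paste(unlist(constraint), collapse = "+"),
                 tree_unconstrained = unc$tree, tree_constrained = con$tree),
            class = "sowh_result")
}

#' @export
print.sowh_result <- function(x, ...) {
  cat(sprintf("<sowh_result> delta = %.4f, p = %.4g (%d replicates; constraint %s)\n",
              x$delta_observed, x$p_value, x$n_replicates, x$constraint_label))
  invisible(x)
}

#' Summarize gene-wise delta values above a cutoff
#'
#' Retains genes with `|delta| > cutoff` (default 3), reports counts and mean
#' `|delta|` for the group favoring the unconstrained topology (positive
#' delta) and the constrained one (negative delta), and the delta vector
#' ordered decreasingly for profile plots.
#'
#' @param records data frame with `gene_id` and `delta` (e.g. from
#'   [gene_deltas()]).
#' @param cutoff non-negative retention threshold on `|delta|`.
#' @return list with `counts`, `mean_abs_delta`, `ordered` (data frame), and
#'   `n_retained`.
#' @export
delta_summary <- function(records, cutoff = 3) {
  if (cutoff < 0) stop_invalid("cutoff must be >= 0")
  keep <- abs(records$delta) > cutoff
  if (!any(keep)) {
    warning("no genes pass the |delta| cutoff; empty summary")
    return(list(counts = c(unconstrained = 0L, constrained = 0L),
                mean_abs_delta = c(unconstrained = NA_real_,
                                   constrained = NA_real_),
                ordered = records[0, , drop = FALSE], n_retained = 0L))
  }
  r <- records[keep, , drop = FALSE]
  grp <- ifelse(r$delta > 0, "unconstrained", "constrained")
  counts <- c(unconstrained = sum(grp == "unconstrained"),
              constrained = sum(grp == "constrained"))
  mabs <- c(unconstrained = if (counts[1]) mean(abs(r$delta[grp == "unconstrained"])) else NA_real_,
            constrained = if (counts[2]) mean(abs(r$delta[grp == "constrained"])) else NA_real_)
  list(counts = counts, mean_abs_delta = mabs,
       ordered = r[order(-r$delta), , drop = FALSE],
       n_retained = sum(keep))
}

wilks_lambda <- function(X, g) {
  Xc <- scale(X, scale = FALSE)
  Tm <- crossprod(Xc)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in unique(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    W <- W + crossprod(scale(Xi, scale = FALSE))
  }
  det(W) / det(Tm)
}

#' Confounder screen on gene-wise delta values
#'
#' Tests whether topological signal tracks potential systematic biases:
#' (a) ordinary least squares of delta on the four per-gene diagnostics
#' (RCFV, root-to-tip variance, saturation, missing fraction) with the
#' overall F-test and R-squared; (b) a two-group multivariate location test
#' on the diagnostics (groups = sign of delta) using Wilks' lambda from
#' between/within scatter, with a label-permutation p-value. Only genes with
#' `|delta| > cutoff` enter. Near-constant (collinear) predictors are
#' dropped and reported.
#'
#' @param rows data frame with columns `delta`, `rcfv`, `rt_variance`,
#'   `saturation`, `missing_fraction`.
#' @param n_permutations permutation count for the group test.
#' @param seed RNG seed for permutations.
#' @param cutoff retention threshold on `|delta|` (default 3).
#' @return object of class `confounder_screen`: regression coefficients,
#'   `r_squared`, `f_p_value`, `wilks_lambda`, `permutation_p_value`,
#'   `dropped_predictors`, `n_genes`, `group_sizes`.
#' @export
confounder_screen <- function(rows, n_permutations = 9999L, seed = 1L,
                              cutoff = 3) {
  preds <- c("rcfv", "rt_variance", "saturation", "missing_fraction")
  keep <- abs(rows$delta) > cutoff & stats::complete.cases(rows[, c("delta", preds)])
  d <- rows[keep, , drop = FALSE]
  if (nrow(d) < 6) stop_invalid("too few genes pass the |delta| cutoff")
  g <- ifelse(d$delta > 0, "pos", "neg")
  group_test <- min(table(factor(g, levels = c("pos", "neg")))) >= 2
  if (!group_test)
    warning("fewer than 2 genes in a support group; group test skipped")

  X <- as.matrix(d[, preds])
  dropped <- character(0)
  repeat {
    W <- matrix(0, ncol(X), ncol(X))
    for (lev in unique(g))
      W <- W + crossprod(scale(X[g == lev, , drop = FALSE], scale = FALSE))
    if (ncol(X) == 1) break
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * max(ev, 1e-300)) break
    drop_i <- which.min(diag(W))
    dropped <- c(dropped, colnames(X)[drop_i])
    X <- X[, -drop_i, drop = FALSE]
  }
  if (length(dropped))
    warning("dropped collinear predictor(s): ", paste(dropped, collapse = ", "))

  fit <- lm(d$delta ~ X)
  sm <- summary(fit)
  f_p <- if (!is.null(sm$fstatistic))
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  else NA_real_

  lam_obs <- perm_p <- NA_real_
  if (group_test) {
    lam_obs <- wilks_lambda(X, g)
    n <- length(g)
    perm_hits <- with_seed(derive_seed(seed, 1L), {
      sum(vapply(seq_len(n_permutations), function(i) {
        wilks_lambda(X, g[sample.int(n)]) <= lam_obs
      }, logical(1)))
    })
    perm_p <- (1 + perm_hits) / (n_permutations + 1)
  }

  structure(list(coefficients = coef(fit), r_squared = sm$r.squared,
                 f_p_value = f_p, wilks_lambda = lam_obs,
                 permutation_p_value = perm_p,
                 dropped_predictors = dropped, n_genes = nrow(d),
                 group_sizes = table(g), cutoff = cutoff),
            class = "confounder_screen")
}

#' @export
print.confounder_screen <- function(x, ...) {
  cat(sprintf("<confounder_screen> %d genes (|delta| > %.3g): R^2 = %.3f (F p = %.3g); Wilks' lambda = %.3f (perm p = %.3g)\n",
              x$n_genes, x$cutoff, x$r_squared, x$f_p_value,
              x$wilks_lambda, x$permutation_p_value))
  invisible(x)
}
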