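# Felsenstein pruning under reversible amino-acid models, branch-length
# optimization by coordinate ascent, small-scale (un)constrained topology
# search, and gene-wise delta log-likelihoods. The per-site mixture is
#   L(site) = p_inv * [site invariant ? pi_state : 0]
#           + (1 - p_inv) * mean over gamma categories of L_cat(site)
# with category rates scaled to mean 1 (the p_inv and gamma components are
# independent mixture weights, not folded into the category rates).

encode_tips <- function(alignment, tips) {
  missing_tips <- setdiff(tips, rownames(alignment))
  if (length(missing_tips))
    stop_invalid("tree taxa absent from alignment: ",
                 paste(missing_tips, collapse = ", "))
  m <- unclass(alignment)[tips, , drop = FALSE]
  st <- match(m, aa_alphabet())
  st[is.na(st)] <- 0L
  matrix(as.integer(st), nrow = length(tips))
}

# Invariant-site contribution per site: sum of pi over states compatible
# with every observed symbol (0 if two observed states differ, 1 if the
# column is all-gap, pi_state otherwise).
invariant_contrib <- function(states, freq) {
  apply(states, 2, function(col) {
    obs <- unique(col[col > 0L])
    if (length(obs) == 0L) 1
    else if (length(obs) > 1L) 0
    else freq[obs]
  })
}

combine_mixture <- function(catll, pinv, pc) {
  k <- nrow(catll)
  if (pinv <= 0) {
    if (k == 1L) return(as.numeric(catll))
    M <- apply(catll, 2, max)
    sh <- sweep(catll, 2, M)
    return(M + log(colSums(exp(sh))) - log(k))
  }
  vapply(seq_len(ncol(catll)), function(s) {
    logsumexp(c(catll[, s] + log((1 - pinv) / k),
                if (pc[s] > 0) log(pinv * pc[s]) else NULL))
  }, numeric(1))
}

# Closure over edge lengths for repeated likelihood evaluation on a fixed
# topology; site patterns are compressed (unique columns with weights).
ll_machine <- function(alignment, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  states <- encode_tips(alignment, tr$tip.label)
  key <- apply(states, 2, paste, collapse = ".")
  first <- !duplicated(key)
  ust <- states[, first, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  eg <- model_eigen(model)
  rates <- model_rates(model)
  pc <- invariant_contrib(ust, model$frequencies)
  site_map <- match(key, key[first])

  site_ll_compressed <- function(el) {
    catll <- cat_site_loglik(tr$edge, el, ust, eg$A, eg$B, eg$lambda,
                             rates, model$frequencies)
    combine_mixture(catll, model$prop_invariant, pc)
  }
  list(tree = tr,
       total = function(el) sum(w * site_ll_compressed(el)),
       site_ll = function(el) site_ll_compressed(el)[site_map])
}

#' Per-site log-likelihoods by the pruning algorithm
#'
#' @param alignment an [msa]; the tree's taxa must all be present.
#' @param tree a `phylo` with non-negative branch lengths.
#' @param model a [subst_model].
#' @return numeric vector of natural-log site likelihoods.
#' @export
site_log_likelihoods <- function(alignment, tree, model) {
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_invalid("branch lengths must be non-negative")
  if (ape::Ntip(tree) == 1L) {
    states <- encode_tips(alignment, tree$tip.label)
    pc <- invariant_contrib(states, model$frequencies)
    if (any(pc <= 0)) stop_invalid("zero likelihood at site ", which(pc <= 0)[1])
    return(log(pc))
  }
  mach <- ll_machine(alignment, tree, model)
  ll <- mach$site_ll(mach$tree$edge.length)
  if (any(!is.finite(ll)))
    stop_invalid("non-finite site likelihood at site ",
                 which(!is.finite(ll))[1])
  ll
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_log_likelihoods
#' @return a single number, the sum of per-site log-likelihoods.
#' @export
tree_log_likelihood <- function(alignment, tree, model) {
  sum(site_log_likelihoods(alignment, tree, model))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimized by bounded scalar
#' search on `[1e-8, 20]`, sweeping until the total log-likelihood gain of a
#' sweep drops below `tol` or `max_sweeps` is reached. The log-likelihood
#' never decreases between sweeps.
#'
#' @inheritParams site_log_likelihoods
#' @param topology a `phylo`; missing or non-positive branch lengths are
#'   reset to `initial`.
#' @param initial starting branch length for missing lengths (default 0.1).
#' @param tol sweep-gain convergence threshold in log-likelihood units.
#' @param max_sweeps hard cap on sweeps; hitting it sets the `converged`
#'   attribute to `FALSE` and warns.
#' @return the tree with optimized lengths, with attributes `loglik` and
#'   `converged`.
#' @export
optimize_branch_lengths <- function(alignment, topology, model,
                                    initial = 0.1, tol = 1e-4,
                                    max_sweeps = 50L) {
  mach <- ll_machine(alignment, topology, model)
  tr <- mach$tree
  el <- tr$edge.length
  el[el <= 0] <- initial
  cur <- mach$total(el)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (i in seq_along(el)) {
      opt <- optimize(function(x) {
        e2 <- el
        e2[i] <- x
        mach$total(e2)
      }, interval = c(1e-8, 20), maximum = TRUE, tol = 1e-4)
      if (opt$objective > cur) {
        el[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("branch-length optimization hit the sweep cap; returning best found")
  tr$edge.length <- el
  attr(tr, "loglik") <- cur
  attr(tr, "converged") <- converged
  tr
}

#' Enumerate all unrooted binary topologies
#'
#' Sequential leaf insertion in the order given: taxon i+1 is attached to
#' every branch of every topology on the first i taxa. This documented
#' first-found order is also the tie-break order of [search_topology()].
#'
#' @param taxa character vector of at least 4 labels.
#' @return list of `(2n-5)!!` unrooted `phylo` objects without branch lengths.
#' @export
enumerate_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 4) stop_invalid("need at least 4 taxa")
  insert <- function(tr, leaf) {
    res <- list(list(tr, leaf))
    if (!is.character(tr)) {
      for (L in insert(tr[[1]], leaf))
        res <- c(res, list(list(L, tr[[2]])))
      for (R in insert(tr[[2]], leaf))
        res <- c(res, list(list(tr[[1]], R)))
    }
    res
  }
  rooted <- list(taxa[2])
  for (i in 3:n) {
    rooted <- unlist(lapply(rooted, insert, leaf = taxa[i]), recursive = FALSE)
  }
  nwk <- function(tr) {
    if (is.character(tr)) tr
    else paste0("(", nwk(tr[[1]]), ",", nwk(tr[[2]]), ")")
  }
  lapply(rooted, function(tr) {
    ape::read.tree(text = paste0("(", nwk(tr[[1]]), ",", nwk(tr[[2]]), ",",
                                 taxa[1], ");"))
  })
}

validate_constraint <- function(constraint, taxa) {
  if (is.null(constraint) || !length(constraint)) return(invisible(NULL))
  if (is.character(constraint)) constraint <- list(constraint)
  for (cl in constraint) {
    if (!all(cl %in% taxa) || length(cl) < 2 || length(cl) >= length(taxa))
      stop_invalid("constraint clade must be a proper subset (>= 2 taxa) of the taxon set")
  }
  if (length(constraint) > 1) {
    for (i in seq_along(constraint)) for (j in seq_len(i - 1)) {
      a <- constraint[[i]]
      b <- constraint[[j]]
      if (length(intersect(a, b)) > 0 && !(all(a %in% b) || all(b %in% a)))
        stop_invalid("constraint clades overlap without nesting")
    }
  }
  invisible(constraint)
}

#' Does a tree satisfy a monophyly constraint?
#'
#' Each clade must appear as a clade-vs-rest bipartition of the unrooted tree.
#'
#' @param tree a `phylo`.
#' @param constraint a character vector (one clade) or list of character
#'   vectors; `NULL` is trivially satisfied.
#' @return logical.
#' @export
satisfies_constraint <- function(tree, constraint) {
  if (is.null(constraint) || !length(constraint)) return(TRUE)
  if (is.character(constraint)) constraint <- list(constraint)
  tips <- tree$tip.label
  for (cl in constraint) {
    if (!all(cl %in% tips)) return(FALSE)
    out <- setdiff(tips, cl)
    tr <- ape::root(ape::unroot(tree), outgroup = out[1], resolve.root = TRUE)
    if (!ape::is.monophyletic(tr, cl)) return(FALSE)
  }
  TRUE
}

#' Search for the maximum-likelihood topology
#'
#' Exhaustive enumeration (all `(2n-5)!!` unrooted topologies, optional
#' monophyly constraint, branch lengths optimized per candidate) for up to 7
#' taxa; nearest-neighbour-interchange hill climbing from a neighbor-joining
#' start for larger taxon sets. Ties are broken by the enumeration order of
#' [enumerate_topologies()].
#'
#' @inheritParams site_log_likelihoods
#' @param constraint optional monophyly constraint (see
#'   [satisfies_constraint()]).
#' @param taxa taxa to include; default all alignment rows.
#' @param mode `"auto"` (exhaustive when `<= 7` taxa), `"exhaustive"`, or
#'   `"nni"`.
#' @param tol passed to [optimize_branch_lengths()].
#' @return list with `tree` (branch lengths optimized, `loglik` attribute),
#'   `loglik`, and `n_evaluated`.
#' @export
search_topology <- function(alignment, model, constraint = NULL,
                            taxa = NULL, mode = c("auto", "exhaustive", "nni"),
                            tol = 1e-4) {
  mode <- match.arg(mode)
  taxa <- taxa %||% rownames(alignment)
  validate_constraint(constraint, taxa)
  if (mode == "auto") mode <- if (length(taxa) <= 7) "exhaustive" else "nni"
  sub <- msa(unclass(alignment)[taxa, , drop = FALSE], gene_id(alignment))

  score_one <- function(topo) {
    fit <- optimize_branch_lengths(sub, topo, model, tol = tol)
    attr(fit, "loglik")
  }

  if (mode == "exhaustive") {
    cands <- Filter(function(tr) satisfies_constraint(tr, constraint),
                    enumerate_topologies(taxa))
    if (!length(cands)) stop_invalid("constraint unsatisfiable on this taxon set")
    best <- NULL
    best_ll <- -Inf
    for (topo in cands) {
      fit <- optimize_branch_lengths(sub, topo, model, tol = tol)
      ll <- attr(fit, "loglik")
      if (ll > best_ll) {
        best_ll <- ll
        best <- fit
      }
    }
    return(list(tree = best, loglik = best_ll, n_evaluated = length(cands)))
  }

  # NNI hill climbing from an NJ (or constraint-compatible) start
  dm <- correct_distance(p_distance_matrix(sub))
  start <- tryCatch(nj_gene_tree(dm), error = function(e) NULL)
  if (is.null(start) || !satisfies_constraint(start, constraint))
    start <- constrained_start_tree(taxa, constraint)
  cur <- optimize_branch_lengths(sub, start, model, tol = tol)
  cur_ll <- attr(cur, "loglik")
  n_eval <- 1L
  repeat {
    improved <- FALSE
    for (nb in nni_neighbors(cur)) {
      if (!satisfies_constraint(nb, constraint)) next
      fit <- optimize_branch_lengths(sub, nb, model, tol = tol)
      n_eval <- n_eval + 1L
      if (attr(fit, "loglik") > cur_ll + 1e-8) {
        cur <- fit
        cur_ll <- attr(fit, "loglik")
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = cur, loglik = cur_ll, n_evaluated = n_eval)
}

# Caterpillar start honouring nested monophyly constraints.
constrained_start_tree <- function(taxa, constraint) {
  if (is.character(constraint)) constraint <- list(constraint)
  grp <- function(labels) {
    if (length(labels) == 1) return(labels)
    paste0("(", labels[1], ",", grp(labels[-1]), ")")
  }
  used <- character(0)
  parts <- character(0)
  if (!is.null(constraint)) {
    cls <- constraint[order(-vapply(constraint, length, 1L))]
    for (cl in cls) {
      cl <- setdiff(cl, used)
      if (length(cl) < 2) next
      parts <- c(parts, grp(cl))
      used <- c(used, cl)
    }
  }
  rest <- setdiff(taxa, used)
  parts <- c(parts, rest)
  if (length(parts) < 3) parts <- c(parts, parts[1])[1:3]
  txt <- paste0("(", parts[1], ",", parts[2], ",",
                if (length(parts) > 3) grp(parts[-(1:2)]) else parts[3], ");")
  ape::read.tree(text = txt)
}

# All NNI neighbours of an unrooted binary tree.
nni_neighbors <- function(tree) {
  tr <- ape::unroot(tree)
  tr$edge.length <- NULL
  n_tip <- ape::Ntip(tr)
  res <- list()
  internal <- tr$edge[, 1] > n_tip & tr$edge[, 2] > n_tip
  for (e in which(internal)) {
    a <- tr$edge[e, 1]
    b <- tr$edge[e, 2]
    kids_b <- tr$edge[tr$edge[, 1] == b, 2]
    other_a <- setdiff(c(tr$edge[tr$edge[, 1] == a, 2],
                         tr$edge[tr$edge[, 2] == a, 1]), b)
    if (length(kids_b) < 2 || length(other_a) < 1) next
    d <- other_a[1]
    for (ci in 1:2) {
      t2 <- tr
      i_c <- which(t2$edge[, 1] == b & t2$edge[, 2] == kids_b[ci])
      i_d <- which((t2$edge[, 1] == a & t2$edge[, 2] == d) |
                     (t2$edge[, 2] == a & t2$edge[, 1] == d))
      # swap subtree attachments c <-> d
      if (t2$edge[i_d, 1] == a) t2$edge[i_d, 1] <- b else t2$edge[i_d, 2] <- b
      t2$edge[i_c, 1] <- a
      t2 <- tryCatch(ape::read.tree(text = ape::write.tree(t2)),
                     error = function(e) NULL)
      if (!is.null(t2)) res <- c(res, list(t2))
    }
  }
  res
}

#' Gene-wise delta log-likelihoods between two topologies
#'
#' Branch lengths of each topology are optimized once on the full
#' concatenated matrix; per-site log-likelihoods are then summed within each
#' gene partition. Positive delta favors the unconstrained topology.
#'
#' @inheritParams site_log_likelihoods
#' @param partition data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open column ranges, jointly covering the matrix without
#'   overlap).
#' @param t_unconstrained,t_constrained topologies spanning the same taxa.
#' @return data frame with `gene_id`, `ll_unconstrained`, `ll_constrained`,
#'   `delta`; attributes `ll_unconstrained` / `ll_constrained` hold the
#'   full-matrix sums.
#' @export
gene_deltas <- function(alignment, partition, t_unconstrained, t_constrained,
                        model) {
  if (!setequal(t_unconstrained$tip.label, t_constrained$tip.label))
    stop_invalid("both trees must span the same taxa")
  idx <- rep(NA_integer_, ncol(alignment))
  for (g in seq_len(nrow(partition))) {
    cols <- (partition$start[g] + 1L):partition$end[g]
    if (any(!is.na(idx[cols])))
      stop_invalid("gene partitions overlap")
    idx[cols] <- g
  }
  if (any(is.na(idx)))
    stop_invalid("gene partitions must cover every column")
  fit_u <- optimize_branch_lengths(alignment, t_unconstrained, model)
  fit_c <- optimize_branch_lengths(alignment, t_constrained, model)
  ll_u <- site_log_likelihoods(alignment, fit_u, model)
  ll_c <- site_log_likelihoods(alignment, fit_c, model)
  out <- data.frame(
    gene_id = partition$gene_id,
    ll_unconstrained = as.numeric(tapply(ll_u, idx, sum)),
    ll_constrained = as.numeric(tapply(ll_c, idx, sum)))
  out$delta <- out$ll_unconstrained - out$ll_constrained
  attr(out, "ll_unconstrained") <- sum(ll_u)
  attr(out, "ll_constrained") <- sum(ll_c)
  attr(out, "tree_unconstrained") <- fit_u
  attr(out, "tree_constrained") <- fit_c
  out
}
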