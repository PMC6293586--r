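# Shared fixtures and independent oracles used across the suite.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mk_msa <- function(rows, gene_id = "g") {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  msa(m, gene_id)
}

# 20-state equal-rates closed form: probability two ends of a path of total
# length t differ.
jc20_pdiff <- function(t) 19 / 20 * (1 - exp(-20 * t / 19))

# Brute-force site log-likelihoods by enumerating all interior-node state
# assignments; independent of the pruning code path (dense eigen of Q,
# explicit sums). Only feasible for <= 3 interior nodes and few sites.
brute_force_loglik <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  rates <- if (is.null(model$gamma_shape)) 1 else
    discrete_gamma_rates(model$gamma_shape, model$n_categories)
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  ee <- eigen(model$Q)
  Pmat <- function(t) Re(ee$vectors %*% diag(exp(ee$values * t)) %*%
                           solve(ee$vectors))
  vapply(seq_len(ncol(aln)), function(site) {
    obs <- unclass(aln)[tr$tip.label, site]
    o <- obs[!(obs %in% c("-", "X", "?"))]
    pc <- if (!length(o)) 1
          else if (length(unique(o)) > 1) 0
          else model$frequencies[match(o[1], AA)]
    tipst <- match(obs, AA)
    catL <- vapply(rates, function(r) {
      Ps <- lapply(seq_len(nrow(tr$edge)),
                   function(e) Pmat(tr$edge.length[e] * r))
      grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
      tot <- 0
      for (k in seq_len(nrow(grid))) {
        full <- c(tipst, grid[k, ])
        pr <- model$frequencies[grid[k, root - ntip]]
        for (e in seq_len(nrow(tr$edge))) {
          cs <- full[tr$edge[e, 2]]
          if (is.na(cs)) next  # missing tip: sums to 1
          pr <- pr * Ps[[e]][full[tr$edge[e, 1]], cs]
        }
        tot <- tot + pr
      }
      tot
    }, numeric(1))
    pinv <- model$prop_invariant
    log(pinv * pc + (1 - pinv) * mean(catL))
  }, numeric(1))
}

# Floyd-Warshall all-pairs shortest paths on the weighted tree graph;
# independent route to patristic distances.
floyd_warshall_patristic <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]
    b <- tree$edge[e, 2]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  out <- d[seq_len(ape::Ntip(tree)), seq_len(ape::Ntip(tree))]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Independent induced-quartet classification: restrict by pruning tips with
# ape and read the split off the bipartitions.
oracle_quartet <- function(tree, four) {
  four <- sort(four)
  if (!all(four %in% tree$tip.label)) return(NA_integer_)
  sub <- ape::keep.tip(ape::unroot(tree), four)
  sub <- ape::unroot(sub)
  if (sub$Nnode < 2) return(0L)
  rooted <- ape::root(sub, outgroup = four[1], resolve.root = TRUE)
  # the cherry not containing four[1] defines the pairing
  for (pair in list(c(2, 3), c(2, 4), c(3, 4))) {
    if (ape::is.monophyletic(rooted, four[pair]))
      return(switch(paste(pair, collapse = ""),
                    "23" = 3L, "24" = 2L, "34" = 1L))
  }
  0L
}

# Clean counterpart of the contamination fixture: same tree and settings,
# no injected events.
fx_clean_config <- function(seed) {
  sim_config(n_taxa = 8, tree_height = 0.25, lineage_rate_sigma = 0,
             n_genes = 200, gene_length_range = c(400, 400),
             gene_rate_sigma = 0.35, occupancy_target = 1, seed = seed)
}

fx_contamination_tree <- function() {
  ape::read.tree(text = paste0(
    "((F:0.07,x1:0.07):0.27,((R2:0.015,D:0.015):0.255,",
    "((R1:0.09,x2:0.09):0.12,(x3:0.09,x4:0.09):0.12):0.06):0.06);"))
}
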