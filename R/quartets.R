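# Quartet decomposition of gene trees, the quartet-score criterion (the
# optimization target of quartet-based summary species-tree methods), exact
# species-tree search at desk scale, around-branch conflict frequencies, and
# the gene-subsampling experiment harness.
#
# Resolution codes for a sorted 4-taxon set {a < b < c < d}:
#   1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved, NA = taxon absent.

# Topological (unit-branch-length) leaf distance matrix.
topo_dist <- function(tree) {
  tr <- ape::unroot(tree)
  tr$edge.length <- rep(1, nrow(tr$edge))
  ape::cophenetic.phylo(tr)
}

quartet_code_from_dist <- function(D, four) {
  s <- c(D[four[1], four[2]] + D[four[3], four[4]],
         D[four[1], four[3]] + D[four[2], four[4]],
         D[four[1], four[4]] + D[four[2], four[3]])
  m <- min(s)
  if (sum(s == m) > 1) 0L else which.min(s)
}

#' Induced quartet of a tree
#'
#' The resolution of the tree restricted to four taxa: the pairing joined by
#' the internal edge of the restricted tree, `0` if the restriction is a
#' star, `NA` if any taxon is absent.
#'
#' @param tree a `phylo`.
#' @param four_taxa character vector of 4 taxon labels.
#' @return integer code (see file header), with a `pairing` attribute naming
#'   the joined pair for resolved quartets.
#' @export
induced_quartet <- function(tree, four_taxa) {
  four <- sort(four_taxa)
  if (!all(four %in% tree$tip.label)) return(NA_integer_)
  code <- quartet_code_from_dist(topo_dist(tree), four)
  if (code > 0)
    attr(code, "pairing") <- switch(code, c(1, 2), c(1, 3), c(1, 4))
  code
}

# Q x G matrix of quartet codes for all C(n,4) quartets of `taxa` across
# gene trees; rownames identify the quartet.
quartet_code_matrix <- function(gene_trees, taxa) {
  quartets <- combn(sort(taxa), 4)
  Q <- ncol(quartets)
  codes <- matrix(NA_integer_, Q, length(gene_trees))
  for (gi in seq_along(gene_trees)) {
    gt <- gene_trees[[gi]]
    present <- taxa %in% gt$tip.label
    D <- topo_dist(gt)
    for (q in seq_len(Q)) {
      four <- quartets[, q]
      if (!all(four %in% gt$tip.label)) next
      codes[q, gi] <- quartet_code_from_dist(D, four)
    }
  }
  rownames(codes) <- apply(quartets, 2, paste, collapse = "|")
  attr(codes, "quartets") <- quartets
  codes
}

#' Quartet count table over a set of gene trees
#'
#' For every 4-taxon subset of `taxa`, the number of gene trees inducing each
#' of the three resolutions, plus unresolved/absent counts.
#'
#' @param gene_trees list of `phylo` objects.
#' @param taxa taxon set; default the union over gene trees.
#' @return data frame with one row per quartet: `quartet`, `n1`, `n2`, `n3`,
#'   `n_unresolved`, `n_absent`.
#' @export
quartet_table <- function(gene_trees, taxa = NULL) {
  taxa <- taxa %||% sort(Reduce(union, lapply(gene_trees, `[[`, "tip.label")))
  codes <- quartet_code_matrix(gene_trees, taxa)
  data.frame(
    quartet = rownames(codes),
    n1 = rowSums(codes == 1L, na.rm = TRUE),
    n2 = rowSums(codes == 2L, na.rm = TRUE),
    n3 = rowSums(codes == 3L, na.rm = TRUE),
    n_unresolved = rowSums(codes == 0L, na.rm = TRUE),
    n_absent = rowSums(is.na(codes)))
}

#' Quartet score of a candidate species tree
#'
#' Number of (gene tree, 4-taxon set) pairs whose induced quartet matches the
#' candidate's; absent or unresolved gene-tree quartets contribute 0.
#'
#' @param candidate `phylo` spanning the union of gene-tree taxa.
#' @param gene_trees list of `phylo` objects.
#' @return integer score.
#' @export
quartet_score <- function(candidate, gene_trees) {
  taxa <- sort(Reduce(union, lapply(gene_trees, `[[`, "tip.label")))
  if (!all(taxa %in% candidate$tip.label))
    stop_invalid("candidate must span all gene-tree taxa")
  codes <- quartet_code_matrix(gene_trees, taxa)
  counts <- cbind(rowSums(codes == 1L, na.rm = TRUE),
                  rowSums(codes == 2L, na.rm = TRUE),
                  rowSums(codes == 3L, na.rm = TRUE))
  score_candidate(candidate, counts, attr(codes, "quartets"))
}

score_candidate <- function(candidate, counts, quartets) {
  D <- topo_dist(candidate)
  total <- 0L
  for (q in seq_len(ncol(quartets))) {
    code <- quartet_code_from_dist(D, quartets[, q])
    if (code > 0) total <- total + counts[q, code]
  }
  unname(total)
}

#' Exact quartet-score species-tree search
#'
#' Enumerates all `(2n-5)!!` unrooted topologies (4 <= n <= 8) and returns
#' every topology maximizing the quartet score against the gene trees — the
#' same objective quartet-based summary methods optimize, solved exactly at
#' desk scale.
#'
#' @param gene_trees list of `phylo` objects.
#' @param taxa taxon set; default the union over gene trees.
#' @return list with `trees` (all co-optimal topologies), `score`, and
#'   `n_topologies` enumerated.
#' @export
exact_quartet_search <- function(gene_trees, taxa = NULL) {
  taxa <- taxa %||% sort(Reduce(union, lapply(gene_trees, `[[`, "tip.label")))
  n <- length(taxa)
  if (n < 4) stop_invalid("need at least 4 taxa")
  if (n > 8)
    stop_invalid("exact search is limited to 8 taxa; use a heuristic for more")
  codes <- quartet_code_matrix(gene_trees, taxa)
  counts <- cbind(rowSums(codes == 1L, na.rm = TRUE),
                  rowSums(codes == 2L, na.rm = TRUE),
                  rowSums(codes == 3L, na.rm = TRUE))
  quartets <- attr(codes, "quartets")
  topos <- enumerate_topologies(taxa)
  scores <- vapply(topos, score_candidate, numeric(1),
                   counts = counts, quartets = quartets)
  best <- max(scores)
  list(trees = topos[scores == best], score = best,
       n_topologies = length(topos))
}

# Tip sets of the four subtrees around an internal edge of an unrooted
# binary tree: blocks A, B on the child side, C, D on the parent side.
branch_blocks <- function(tree) {
  tr <- ape::unroot(tree)
  n_tip <- ape::Ntip(tr)
  adj <- lapply(seq_len(n_tip + tr$Nnode), function(i) integer(0))
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]
    b <- tr$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp_tips <- function(start, avoid) {
    seen <- c(avoid)
    stack <- start
    tips <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v <= n_tip) tips <- c(tips, v)
      stack <- c(stack, setdiff(adj[[v]], seen))
    }
    tr$tip.label[tips]
  }
  internal <- which(tr$edge[, 1] > n_tip & tr$edge[, 2] > n_tip)
  lapply(internal, function(e) {
    a <- tr$edge[e, 1]
    b <- tr$edge[e, 2]
    nb_b <- setdiff(adj[[b]], a)
    nb_a <- setdiff(adj[[a]], b)
    blocks <- c(lapply(nb_b, comp_tips, avoid = b),
                lapply(nb_a, comp_tips, avoid = a))
    names(blocks) <- c("A", "B", "C", "D")[seq_along(blocks)]
    blocks
  })
}

#' Around-branch quartet frequencies
#'
#' For each internal branch of a binary species tree, the frequencies of the
#' three quartet arrangements around the branch, averaged over quartets with
#' one taxon in each of the four subtrees the branch defines (`f1` = the
#' arrangement matching the branch). Exact enumeration up to `max_quartets`
#' defining quartets, else a seeded uniform sample of that many.
#'
#' @param species_tree binary `phylo`.
#' @param gene_trees list of `phylo` objects.
#' @param max_quartets sampling cap per branch (default 500).
#' @param seed RNG seed for the sampling fallback.
#' @return data frame with `bipartition`, `f1`, `f2`, `f3`,
#'   `effective_genes` (mean number of resolved gene trees per quartet).
#' @export
branch_support_table <- function(species_tree, gene_trees,
                                 max_quartets = 500L, seed = 1L) {
  if (!ape::is.binary(ape::unroot(species_tree)))
    stop_invalid("species tree must be binary")
  blocks_list <- branch_blocks(species_tree)
  gdists <- lapply(gene_trees, topo_dist)
  rows <- lapply(seq_along(blocks_list), function(bi) {
    bl <- blocks_list[[bi]]
    sizes <- vapply(bl, length, 1L)
    n_q <- prod(sizes)
    pick <- if (n_q <= max_quartets) {
      expand.grid(a = bl$A, b = bl$B, c = bl$C, d = bl$D,
                  stringsAsFactors = FALSE)
    } else {
      with_seed(derive_seed(seed, bi), data.frame(
        a = sample(bl$A, max_quartets, replace = TRUE),
        b = sample(bl$B, max_quartets, replace = TRUE),
        c = sample(bl$C, max_quartets, replace = TRUE),
        d = sample(bl$D, max_quartets, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    freq <- matrix(0, nrow(pick), 3)
    eff <- numeric(nrow(pick))
    for (qi in seq_len(nrow(pick))) {
      qt <- unlist(pick[qi, ], use.names = FALSE)
      cnt <- c(0, 0, 0)
      for (gi in seq_along(gene_trees)) {
        D <- gdists[[gi]]
        if (!all(qt %in% rownames(D))) next
        # pairing relative to the blocks: AB|CD, AC|BD, AD|BC
        s <- c(D[qt[1], qt[2]] + D[qt[3], qt[4]],
               D[qt[1], qt[3]] + D[qt[2], qt[4]],
               D[qt[1], qt[4]] + D[qt[2], qt[3]])
        m <- min(s)
        if (sum(s == m) == 1) cnt[which.min(s)] <- cnt[which.min(s)] + 1
      }
      eff[qi] <- sum(cnt)
      if (sum(cnt) > 0) freq[qi, ] <- cnt / sum(cnt)
    }
    used <- eff > 0
    f <- if (any(used)) colMeans(freq[used, , drop = FALSE]) else c(NA, NA, NA)
    data.frame(
      bipartition = paste(paste(sort(c(bl$A, bl$B)), collapse = ","),
                          paste(sort(c(bl$C, bl$D)), collapse = ","),
                          sep = " | "),
      f1 = f[1], f2 = f[2], f3 = f[3],
      effective_genes = mean(eff))
  })
  do.call(rbind, rows)
}

has_clade <- function(tree, clade) {
  tips <- tree$tip.label
  if (!all(clade %in% tips)) return(FALSE)
  if (length(setdiff(tips, clade)) == 0) return(TRUE)
  satisfies_constraint(tree, list(clade))
}

#' Gene-subsampling species-tree experiment
#'
#' For each replicate subset of gene trees (drawn via [random_subsamples()]
#' from `pool`, default all genes), runs the exact quartet search and records
#' whether the focal clade appears as a bipartition of every co-optimal tree,
#' and the focal branch's `f1` when recovered.
#'
#' @param gene_trees list of `phylo` objects.
#' @param keep_fraction fraction of the pool kept per replicate.
#' @param n_replicates number of replicates.
#' @param focal_clade character vector, a proper subset of the taxa.
#' @param seed RNG seed.
#' @param pool indices of genes to sample from (default all).
#' @return list with `table` (per-replicate `recovered`, `f1`),
#'   `recovery_fraction`, and `mean_f1_recovered`.
#' @export
subsampling_experiment <- function(gene_trees, keep_fraction, n_replicates,
                                   focal_clade, seed = 1L, pool = NULL) {
  taxa <- sort(Reduce(union, lapply(gene_trees, `[[`, "tip.label")))
  if (!all(focal_clade %in% taxa) || length(focal_clade) >= length(taxa))
    stop_invalid("focal_clade must be a proper subset of the taxa")
  pool <- pool %||% seq_along(gene_trees)
  reps <- random_subsamples(as.character(pool), keep_fraction, n_replicates,
                            seed = seed)
  rows <- lapply(seq_len(n_replicates), function(r) {
    idx <- as.integer(reps[[r]])
    res <- exact_quartet_search(gene_trees[idx], taxa = taxa)
    recovered <- all(vapply(res$trees, has_clade, logical(1),
                            clade = focal_clade))
    f1 <- NA_real_
    if (recovered) {
      bs <- branch_support_table(res$trees[[1]], gene_trees[idx],
                                 seed = derive_seed(seed, r, 99L))
      hit <- vapply(strsplit(bs$bipartition, " \\| "), function(sides) {
        any(vapply(strsplit(sides, ","), setequal, logical(1),
                   y = focal_clade))
      }, logical(1))
      if (any(hit)) f1 <- bs$f1[which(hit)[1]]
    }
    data.frame(replicate = r, n_genes = length(idx), recovered = recovered,
               f1 = f1)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       recovery_fraction = mean(tab$recovered),
       mean_f1_recovered = if (any(tab$recovered))
         mean(tab$f1[tab$recovered], na.rm = TRUE) else NA_real_)
}
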