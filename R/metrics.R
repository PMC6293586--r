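# Alignment- and tree-level primitive statistics: p-distances, patristic
# distances, root-to-tip distances/variance, RCFV, missing data, Poisson
# distance correction, neighbor joining, posterior rate summaries.

#' Uncorrected p-distance between two aligned sequences
#'
#' Fraction of differing sites among sites where both symbols are informative
#' (non-gap, non-`X`). `NA` when no site is comparable.
#'
#' @param a,b equal-length character vectors (or single strings).
#' @return a fraction in `[0, 1]`, or `NA` if the comparable set is empty.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1 && nchar(a[1]) > 1) a <- strsplit(a, "")[[1]]
  if (length(b) == 1 && nchar(b[1]) > 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop_invalid("sequences differ in length")
  ok <- !(a %in% missing_symbols()) & !(b %in% missing_symbols())
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' All pairwise p-distances of an alignment
#'
#' @param alignment an [msa].
#' @return symmetric matrix with zero diagonal; entries are `NA` where no
#'   site is comparable.
#' @export
p_distance_matrix <- function(alignment) {
  taxa <- rownames(alignment)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  m <- unclass(alignment)
  informative <- !(m %in% missing_symbols())
  dim(informative) <- dim(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- informative[i, ] & informative[j, ]
    d[i, j] <- d[j, i] <-
      if (!any(ok)) NA_real_ else sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every leaf pair.
#'
#' @param tree a `phylo` with branch lengths and unique leaf labels.
#' @return symmetric matrix ordered by `tree$tip.label`.
#' @export
patristic_matrix <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop_invalid("duplicate leaf labels")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Root-to-tip distances and their variance
#'
#' The tree is rooted on the outgroup stem (midpoint rooting as fallback when
#' no outgroup is given or none survives), distances are measured from the
#' most recent common ancestor of the ingroup to each ingroup leaf, and the
#' variance is the sample variance (n-1 denominator) over ingroup leaves — a
#' clock-violation measure.
#'
#' @param tree a `phylo` with branch lengths.
#' @param outgroup optional character vector of outgroup taxa used to root.
#' @param ingroup taxa over which distances are taken; default all non-outgroup
#'   leaves.
#' @return list with `distances` (named vector over the ingroup) and
#'   `variance`.
#' @export
root_to_tip <- function(tree, outgroup = NULL, ingroup = NULL) {
  tips <- tree$tip.label
  outgroup <- intersect(outgroup %||% character(0), tips)
  ingroup <- ingroup %||% setdiff(tips, outgroup)
  ingroup <- intersect(ingroup, tips)
  if (!length(ingroup)) stop_invalid("no ingroup taxa left to measure")
  if (length(outgroup)) {
    tr <- ape::root(ape::unroot(tree), outgroup = outgroup,
                    resolve.root = TRUE)
    if (!ape::is.monophyletic(tr, ingroup))
      stop_invalid("ingroup not monophyletic after outgroup rooting")
  } else if (ape::is.rooted(tree) && setequal(ingroup, tips)) {
    tr <- tree
  } else {
    tr <- phangorn::midpoint(ape::unroot(tree))
    if (!ape::is.monophyletic(tr, ingroup))
      stop_invalid("ingroup not monophyletic after midpoint rooting")
  }
  mrca <- if (length(ingroup) == 1L) match(ingroup, tr$tip.label)
          else ape::getMRCA(tr, ingroup)
  dn <- ape::dist.nodes(tr)
  d <- dn[mrca, match(ingroup, tr$tip.label)]
  names(d) <- ingroup
  list(distances = d,
       variance = if (length(d) > 1) var(d) else 0)
}

#' Posterior summaries of root-to-tip rates
#'
#' Emulates posterior rate profiles: `n_draws` trees are sampled uniformly
#' with replacement from a posterior sample, root-to-tip distances from the
#' ingroup MRCA are collected, and per-taxon means with 2.5/97.5 percentile
#' intervals are reported. Draws in which the ingroup is not monophyletic
#' after rooting are skipped and counted.
#'
#' @param tree_samples list of `phylo` trees (posterior sample).
#' @param ingroup taxa to summarize.
#' @param outgroup taxa used to root each draw.
#' @param n_draws number of posterior draws (with replacement).
#' @param seed RNG seed.
#' @return data frame with `taxon`, `mean_root_to_tip`, `ci_low`, `ci_high`,
#'   `n_samples`; attribute `n_skipped` counts discarded draws.
#' @export
posterior_rate_summary <- function(tree_samples, ingroup, outgroup = NULL,
                                   n_draws = 2000L, seed = 1L) {
  if (n_draws < 1) stop_invalid("n_draws must be >= 1")
  draws <- with_seed(seed,
                     sample.int(length(tree_samples), n_draws, replace = TRUE))
  acc <- matrix(NA_real_, n_draws, length(ingroup),
                dimnames = list(NULL, ingroup))
  skipped <- 0L
  for (i in seq_len(n_draws)) {
    rt <- tryCatch(root_to_tip(tree_samples[[draws[i]]], outgroup, ingroup),
                   error = function(e) NULL)
    if (is.null(rt)) {
      skipped <- skipped + 1L
      next
    }
    acc[i, names(rt$distances)] <- rt$distances
  }
  used <- colSums(!is.na(acc))
  out <- data.frame(
    taxon = ingroup,
    mean_root_to_tip = colMeans(acc, na.rm = TRUE),
    ci_low = apply(acc, 2, quantile, probs = 0.025, na.rm = TRUE),
    ci_high = apply(acc, 2, quantile, probs = 0.975, na.rm = TRUE),
    n_samples = used, row.names = NULL)
  attr(out, "n_skipped") <- skipped
  out
}

#' Relative composition frequency variability (RCFV)
#'
#' With `f[t, s]` the frequency of state `s` among taxon `t`'s usable sites
#' and `fbar[s]` the unweighted mean over taxa,
#' `RCFV = sum_s sum_t |f[t, s] - fbar[s]| / n_taxa`. Zero iff all taxa share
#' the same composition. Taxa without usable sites are excluded (attribute
#' `excluded_taxa`).
#'
#' @param alignment an [msa].
#' @return non-negative scalar with attribute `excluded_taxa`.
#' @export
rcfv <- function(alignment) {
  keep <- usable_taxa(alignment)
  excluded <- setdiff(rownames(alignment), keep)
  if (length(keep) < 2)
    stop_invalid("RCFV needs at least two taxa with usable sites")
  ab <- aa_alphabet()
  f <- t(apply(unclass(alignment)[keep, , drop = FALSE], 1, function(r) {
    r <- r[!(r %in% missing_symbols())]
    tabulate(match(r, ab), nbins = length(ab)) / length(r)
  }))
  fbar <- colMeans(f)
  out <- sum(abs(sweep(f, 2, fbar))) / length(keep)
  attr(out, "excluded_taxa") <- excluded
  out
}

#' Fraction of missing cell content
#'
#' Absent-taxon cells plus gap/`X` cells, relative to the full
#' `|expected_taxa| x n_columns` grid.
#'
#' @param alignment an [msa].
#' @param expected_taxa taxa expected in the gene (superset of the rows).
#' @return a fraction in `[0, 1]`.
#' @export
missing_fraction <- function(alignment, expected_taxa = rownames(alignment)) {
  if (!all(rownames(alignment) %in% expected_taxa))
    stop_invalid("expected_taxa must contain all alignment taxa")
  n_cols <- ncol(alignment)
  absent <- length(setdiff(expected_taxa, rownames(alignment))) * n_cols
  gaps <- sum(unclass(alignment) %in% missing_symbols())
  (absent + gaps) / (length(expected_taxa) * n_cols)
}

#' Poisson (20-state) distance correction
#'
#' `d = -(19/20) ln(1 - (20/19) p)`; p at or above `cap` is capped first
#' (capped entries flagged via the `capped` attribute).
#'
#' @param p p-distance(s), possibly a matrix; `NA` passes through.
#' @param cap saturation cap on p (default 0.94).
#' @return corrected distance(s), same shape as `p`.
#' @export
correct_distance <- function(p, cap = 0.94) {
  if (any(p < 0, na.rm = TRUE)) stop_invalid("p-distances cannot be negative")
  capped <- !is.na(p) & p >= cap
  p2 <- ifelse(capped, cap, p)
  d <- -(19 / 20) * log(1 - (20 / 19) * p2)
  attributes(d) <- attributes(p)
  attr(d, "capped") <- which(capped)
  d
}

#' Neighbor-joining gene tree
#'
#' Standard NJ agglomeration (Q-criterion, via `ape::nj`); negative branch
#' estimates are clamped to zero and flagged. Matrices with unavailable
#' entries signal a skip (error of class `phylosieve_skip`) so callers can
#' drop the gene and log it.
#'
#' @param d symmetric distance matrix with labels.
#' @return a `phylo`; attribute `n_clamped` counts clamped branches.
#' @export
nj_gene_tree <- function(d) {
  if (any(is.na(d)))
    stop(structure(class = c("phylosieve_skip", "error", "condition"),
                   list(message = "distance matrix has unavailable entries; gene skipped",
                        call = NULL)))
  if (nrow(d) < 4) stop_invalid("neighbor joining needs at least 4 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}
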