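# The gene-exclusion procedure: saturation and root-to-tip variance are
# centered, scaled (z-scores) and added; the highest-ranking fraction of
# genes is excluded. Random subsampling replicates provide the matched
# control experiment.

#' Saturation statistic of a gene
#'
#' One minus the ordinary-least-squares slope of p-distances on patristic
#' distances over all unordered taxon pairs available in both matrices, so
#' that higher values correspond to increased saturation. Undefined (`NA`
#' with a `reason` attribute) with fewer than 3 usable pairs or zero variance
#' in the patristic distances.
#'
#' @param p symmetric p-distance matrix (e.g. [p_distance_matrix()]).
#' @param patristic symmetric patristic matrix (e.g. [patristic_matrix()]).
#' @return `1 - slope`, or flagged `NA`.
#' @export
saturation_statistic <- function(p, patristic) {
  shared <- intersect(rownames(p), rownames(patristic))
  if (length(shared) < 3) return(undefined_metric("fewer than 3 shared taxa"))
  pp <- p[shared, shared]
  xx <- patristic[shared, shared]
  lt <- lower.tri(pp)
  y <- pp[lt]
  x <- xx[lt]
  ok <- !is.na(y) & !is.na(x)
  if (sum(ok) < 3) return(undefined_metric("fewer than 3 usable pairs"))
  x <- x[ok]
  y <- y[ok]
  if (var(x) == 0) return(undefined_metric("zero variance in patristic distances"))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  1 - slope
}

undefined_metric <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Per-gene diagnostics table
#'
#' Convenience wrapper computing, for each gene, the saturation statistic,
#' root-to-tip variance (outgroup rooting with midpoint fallback), RCFV and
#' missing fraction.
#'
#' @param alignments list of [msa] objects.
#' @param gene_trees list of `phylo` gene trees, parallel to `alignments`.
#' @param outgroup outgroup taxa used for rooting (may be absent from some
#'   genes; midpoint fallback applies).
#' @param expected_taxa full taxon set of the supermatrix.
#' @return data frame with columns `gene_id`, `saturation`, `rt_variance`,
#'   `rcfv`, `missing_fraction`.
#' @export
gene_diagnostics <- function(alignments, gene_trees, outgroup = NULL,
                             expected_taxa = NULL) {
  expected_taxa <- expected_taxa %||%
    Reduce(union, lapply(alignments, rownames))
  rows <- lapply(seq_along(alignments), function(i) {
    aln <- alignments[[i]]
    tr <- gene_trees[[i]]
    sat <- rt <- NA_real_
    if (!is.null(tr)) {
      sat <- saturation_statistic(p_distance_matrix(aln), patristic_matrix(tr))
      og <- intersect(outgroup %||% character(0), tr$tip.label)
      rt <- tryCatch(
        root_to_tip(tr, outgroup = if (length(og)) og else NULL)$variance,
        error = function(e) NA_real_)
    }
    data.frame(gene_id = gene_id(aln),
               saturation = as.numeric(sat),
               rt_variance = rt,
               rcfv = tryCatch(as.numeric(rcfv(aln)),
                               error = function(e) NA_real_),
               missing_fraction = missing_fraction(aln, expected_taxa))
  })
  do.call(rbind, rows)
}

#' Standardize and combine gene diagnostics into a ranking
#'
#' Saturation and root-to-tip variance are each standardized to mean 0 and
#' sample SD 1 across the genes where they are defined, and summed into a
#' combined score. Genes are returned ordered by combined score descending
#' (worst first); ties break by ascending `gene_id`; genes with undefined
#' metrics rank last and are flagged, not dropped.
#'
#' @param diagnostics data frame as from [gene_diagnostics()] (needs
#'   `gene_id`, `saturation`, `rt_variance`).
#' @return the data frame with added `z_saturation`, `z_rt_variance`,
#'   `combined` and `defined` columns, ordered by the ranking.
#' @export
combine_and_rank <- function(diagnostics) {
  d <- diagnostics
  defined <- !is.na(d$saturation) & !is.na(d$rt_variance)
  if (sum(defined) < 2)
    stop_invalid("need at least 2 genes with defined saturation and rt_variance")
  zscore <- function(x) {
    s <- sd(x[defined])
    if (is.na(s) || s == 0) {
      warning("metric has zero spread; contributes 0 to the combined score")
      return(ifelse(defined, 0, NA_real_))
    }
    (x - mean(x[defined])) / s
  }
  d$z_saturation <- zscore(d$saturation)
  d$z_rt_variance <- zscore(d$rt_variance)
  d$combined <- d$z_saturation + d$z_rt_variance
  d$defined <- defined
  key <- ifelse(defined, -d$combined, Inf)
  d[order(key, d$gene_id), , drop = FALSE]
}

#' Exclude the highest-ranking fraction of genes
#'
#' The first `floor(q * n)` genes of the descending combined ranking are
#' excluded; the rest are retained in input order. With the study-scale input
#' (1040 genes, q = 0.66) this retains exactly 354.
#'
#' @param ranked data frame from [combine_and_rank()] (or any ranked order),
#'   or a character vector of ranked gene ids.
#' @param q exclusion fraction in `[0, 1)`.
#' @return object of class `filter_result`: list with `retained_ids`,
#'   `excluded_ids`, `q`, `n_input`.
#' @export
exclude_top_fraction <- function(ranked, q) {
  if (q < 0 || q >= 1) stop_invalid("exclusion fraction must lie in [0, 1)")
  ids <- if (is.character(ranked)) ranked else ranked$gene_id
  n <- length(ids)
  n_excl <- floor(q * n)
  structure(list(retained_ids = if (n_excl < n) ids[seq.int(n_excl + 1, n)]
                                else character(0),
                 excluded_ids = if (n_excl > 0) ids[seq_len(n_excl)]
                                else character(0),
                 q = q, n_input = n),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d/%d genes retained (q = %.3g excluded)\n",
              length(x$retained_ids), x$n_input, x$q))
  invisible(x)
}

#' Random gene subsamples
#'
#' Each replicate is a uniform random subset of size
#' `round(keep_fraction * n)`, sampled without replacement, independent
#' across replicates given the seed.
#'
#' @param gene_ids character vector of gene ids.
#' @param keep_fraction fraction in `(0, 1]`.
#' @param n_replicates number of replicate subsets.
#' @param seed RNG seed.
#' @return list of character vectors.
#' @export
random_subsamples <- function(gene_ids, keep_fraction, n_replicates, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_invalid("keep_fraction must lie in (0, 1]")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  n <- length(gene_ids)
  size <- round(keep_fraction * n)
  if (size < 1) stop_invalid("subset size is 0; increase keep_fraction")
  lapply(seq_len(n_replicates), function(r) {
    with_seed(derive_seed(seed, r),
              gene_ids[sort(sample.int(n, size))])
  })
}
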