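# Sequence-screening procedures: alien-index classification from best-hit
# E-value tables, cross-sample p-distance regression with an SD envelope,
# and a simplified gene-tree-diameter outlier screen (a deliberately reduced
# stand-in for full signal-to-noise outlier detection tools).

#' Alien index from best-hit E-values
#'
#' `AI = ln(e_expected + eps) - ln(e_other + eps)` with `eps = 1e-200`;
#' an absent hit is treated as E = 1. Sequences with `AI >= 45` are flagged
#' as of foreign origin (large positive AI means the expected-group hit is
#' much weaker than the foreign-group hit).
#'
#' @param e_expected,e_other best E-values against the expected and the
#'   other group's databases; `NA` = no hit. Vectorized.
#' @param threshold foreign-origin cutoff (default 45).
#' @return data frame with `ai` and `foreign`.
#' @export
alien_index <- function(e_expected, e_other, threshold = 45) {
  if (any(e_expected < 0, na.rm = TRUE) || any(e_other < 0, na.rm = TRUE))
    stop_invalid("E-values cannot be negative")
  eps <- 1e-200
  ee <- ifelse(is.na(e_expected), 1, e_expected)
  eo <- ifelse(is.na(e_other), 1, e_other)
  ai <- log(ee + eps) - log(eo + eps)
  data.frame(ai = ai, foreign = ai >= threshold)
}

#' Read a best-hit E-value table
#'
#' TSV with columns `sequence_id`, `e_expected`, `e_other`; `NA` marks an
#' absent hit.
#'
#' @param path TSV file.
#' @return data frame with the alien index appended (see [alien_index()]).
#' @export
read_hit_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "e_expected", "e_other")
  if (!all(need %in% names(d)))
    stop_invalid("hit table must have columns: ", paste(need, collapse = ", "))
  cbind(d, alien_index(d$e_expected, d$e_other))
}

#' Cross-sample p-distance residual screen
#'
#' Per gene where the focal taxon and both references are present,
#' `x = p(focal, ref1)` and `y = p(focal, ref2)`; an OLS line `y = a + b x`
#' is fitted over genes and genes whose residual exceeds
#' `threshold_sd * sqrt(SSE / (n - 2))` in absolute value are flagged as
#' candidate contaminants (sequences whose divergence pattern breaks the
#' lineage-wide relation). A degenerate (zero-SD) fit flags nothing.
#'
#' @param alignments list of [msa] objects.
#' @param focal focal taxon.
#' @param references two reference taxa; if `NULL`, two are drawn at random
#'   (seeded) from the taxa co-occurring with the focal taxon.
#' @param threshold_sd envelope width in residual SDs (default 3).
#' @param seed RNG seed for reference drawing.
#' @return data frame of class `residual_screen` rows: `gene_id`, `x`, `y`,
#'   `residual`, `flagged`; attributes `references`, `residual_sd`,
#'   `n_skipped`, `degenerate`.
#' @export
residual_screen <- function(alignments, focal, references = NULL,
                            threshold_sd = 3, seed = 1L) {
  if (is.null(references)) {
    cooccur <- table(unlist(lapply(alignments, function(a) {
      tx <- rownames(a)
      if (focal %in% tx) setdiff(tx, focal) else character(0)
    })))
    cands <- names(cooccur)[cooccur >= 10]
    if (length(cands) < 2)
      stop_invalid("not enough co-occurring taxa to draw references")
    references <- with_seed(derive_seed(seed, 1L), sample(cands, 2))
  }
  if (length(references) != 2 || focal %in% references)
    stop_invalid("need two reference taxa distinct from the focal taxon")

  rows <- list()
  n_skipped <- 0L
  for (aln in alignments) {
    tx <- rownames(aln)
    if (!all(c(focal, references) %in% tx)) next
    x <- p_distance(unclass(aln)[focal, ], unclass(aln)[references[1], ])
    y <- p_distance(unclass(aln)[focal, ], unclass(aln)[references[2], ])
    if (is.na(x) || is.na(y)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(gene_id = gene_id(aln),
                                            x = x, y = y)
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 10) {
    warning("fewer than 10 usable genes; residual screen skipped")
    return(structure(data.frame(gene_id = character(0), x = numeric(0),
                                y = numeric(0), residual = numeric(0),
                                flagged = logical(0)),
                     references = references, residual_sd = NA_real_,
                     n_skipped = n_skipped, degenerate = NA,
                     class = c("residual_screen", "data.frame")))
  }
  fit <- lm(y ~ x, data = d)
  res <- stats::residuals(fit)
  sdres <- sqrt(sum(res^2) / (nrow(d) - 2))
  # p-distances have resolution 1/L; an SD at float-noise level is a
  # numerically exact fit
  degenerate <- sdres < 1e-12
  d$residual <- as.numeric(res)
  d$flagged <- if (degenerate) FALSE else abs(d$residual) > threshold_sd * sdres
  structure(d, references = references, residual_sd = sdres,
            n_skipped = n_skipped, degenerate = degenerate,
            class = c("residual_screen", "data.frame"))
}

#' Gene-tree diameter outlier screen
#'
#' For each gene tree and each leaf, the proportional reduction in tree
#' diameter (maximum leaf-to-leaf patristic distance) after removing that
#' leaf, `r = (D - D_without) / D`, is pooled per species across genes; a
#' (gene, leaf) pair is flagged when its `r` exceeds both that species'
#' empirical `(1 - q)`-quantile and `min_impact`. A simplified variant of
#' signal-to-noise gene-tree shrinking tools.
#'
#' @param gene_trees list of `phylo` objects with >= 5 leaves each.
#' @param q per-species false-positive tolerance (default 0.02).
#' @param min_impact absolute floor on `r` (default 0.2) so near-clock trees
#'   are never flagged.
#' @return data frame with `gene`, `taxon`, `impact`, `flagged`; genes with
#'   zero diameter are skipped (attribute `skipped_genes`).
#' @export
diameter_outliers <- function(gene_trees, q = 0.02, min_impact = 0.2) {
  rows <- list()
  skipped <- integer(0)
  for (g in seq_along(gene_trees)) {
    tr <- gene_trees[[g]]
    if (ape::Ntip(tr) < 5) stop_invalid("each gene tree needs >= 5 leaves")
    D <- ape::cophenetic.phylo(tr)
    diam <- max(D)
    if (diam == 0) {
      skipped <- c(skipped, g)
      next
    }
    for (leaf in tr$tip.label) {
      keep <- setdiff(tr$tip.label, leaf)
      d2 <- max(D[keep, keep])
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, taxon = leaf, impact = (diam - d2) / diam)
    }
  }
  d <- do.call(rbind, rows)
  if (is.null(d)) stop_invalid("no usable gene trees")
  thr <- tapply(d$impact, d$taxon, quantile, probs = 1 - q, names = FALSE)
  d$flagged <- d$impact > thr[d$taxon] & d$impact > min_impact
  attr(d, "skipped_genes") <- skipped
  d
}
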