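# Synthetic phylogenomic datasets with the statistical structure the
# downstream analyses assume: a pure-birth species tree with lineage-specific
# rate multipliers (to plant slow and fast lineages), gene trees that either
# share the species-tree topology (concatenation regime, theta = 0) or are
# drawn from the multispecies coalescent (theta > 0), alignments simulated
# under a reversible model with gamma/invariant site rates, compositional
# bias, gene-by-taxon occupancy masking and injected cross-taxon
# contaminants. One master seed determines everything; child seeds are
# derived in a fixed enumeration order (genes, then taxa) so adding genes
# never changes earlier genes.

#' Simulation configuration
#'
#' @param n_taxa number of leaves (>= 4).
#' @param tree_height expected root-to-tip path length, substitutions/site,
#'   before rate multipliers.
#' @param lineage_rate_sigma SD of log-normal per-branch rate multipliers
#'   (mean 1); 0 gives a strict clock.
#' @param lineage_rate_overrides named numeric vector/list, taxon ->
#'   multiplier applied to that taxon's terminal branch (plants slow/fast
#'   lineages).
#' @param coalescent_theta population-mutation parameter for multispecies
#'   coalescent gene trees; 0 means every gene tree equals the species tree.
#' @param n_genes number of genes.
#' @param gene_length_range integer `[min, max]` alignment columns per gene.
#' @param gene_rate_sigma SD of the log-normal per-gene rate multiplier.
#' @param gamma_shape alpha of across-site gamma rates (`NULL` = none).
#' @param n_rate_categories discrete-gamma category count.
#' @param prop_invariant proportion of invariant sites in `[0, 1)`.
#' @param composition_bias list of `list(taxon=, target=, strength=)` entries;
#'   `target` is a 20-long frequency vector summing to 1, `strength` in
#'   `[0, 1]` the fraction of that taxon's sites resampled i.i.d. from it.
#' @param occupancy_target global gene-by-taxon occupancy fraction in
#'   `(0, 1]`.
#' @param contamination_events list of `list(gene=, victim=, donor=)`
#'   entries (gene index, victim taxon, donor taxon).
#' @param seed master seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, tree_height = 0.5,
                       lineage_rate_sigma = 0.3,
                       lineage_rate_overrides = list(),
                       coalescent_theta = 0, n_genes = 60L,
                       gene_length_range = c(100L, 500L),
                       gene_rate_sigma = 0.5, gamma_shape = 0.75,
                       n_rate_categories = 4L, prop_invariant = 0.1,
                       composition_bias = list(), occupancy_target = 0.70,
                       contamination_events = list(), seed = 1L) {
  if (n_taxa < 4) stop_invalid("n_taxa must be >= 4")
  if (coalescent_theta < 0) stop_invalid("coalescent_theta must be >= 0")
  if (prop_invariant < 0 || prop_invariant >= 1)
    stop_invalid("prop_invariant must lie in [0, 1)")
  if (occupancy_target <= 0 || occupancy_target > 1)
    stop_invalid("occupancy_target must lie in (0, 1]")
  if (tree_height <= 0) stop_invalid("tree_height must be positive")
  if (length(gene_length_range) != 2 || gene_length_range[1] > gene_length_range[2])
    stop_invalid("gene_length_range must be [min, max]")
  for (cb in composition_bias) {
    if (abs(sum(cb$target) - 1) > 1e-12)
      stop_invalid("composition-bias target frequencies must sum to 1")
    if (cb$strength < 0 || cb$strength > 1)
      stop_invalid("composition-bias strength must lie in [0, 1]")
  }
  structure(list(n_taxa = as.integer(n_taxa), tree_height = tree_height,
                 lineage_rate_sigma = lineage_rate_sigma,
                 lineage_rate_overrides = lineage_rate_overrides,
                 coalescent_theta = coalescent_theta,
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 gene_rate_sigma = gene_rate_sigma,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 prop_invariant = prop_invariant,
                 composition_bias = composition_bias,
                 occupancy_target = occupancy_target,
                 contamination_events = contamination_events,
                 seed = as.integer(seed)),
            class = "sim_config")
}

config_model <- function(config, frequencies = NULL) {
  poisson_model(gamma_shape = config$gamma_shape,
                n_categories = config$n_rate_categories,
                prop_invariant = config$prop_invariant,
                frequencies = frequencies)
}

#' Simulate the species tree
#'
#' Pure-birth topology, branch lengths rescaled so the mean root-to-tip path
#' equals `tree_height`, then each branch multiplied by its lineage rate
#' factor (log-normal with SD `lineage_rate_sigma`, mean 1; terminal-branch
#' overrides replace the random factor).
#'
#' @param config a [sim_config()].
#' @return rooted binary `phylo` with `n_taxa` leaves.
#' @export
simulate_species_tree <- function(config) {
  tr <- with_seed(derive_seed(config$seed, 1L),
                  ape::rphylo(config$n_taxa, birth = 1, death = 0))
  tr$tip.label <- sprintf("t%02d", seq_len(config$n_taxa))
  root <- ape::Ntip(tr) + 1L
  depth <- ape::dist.nodes(tr)[root, seq_len(ape::Ntip(tr))]
  tr$edge.length <- tr$edge.length * config$tree_height / mean(depth)
  mult <- rep(1, nrow(tr$edge))
  if (config$lineage_rate_sigma > 0) {
    s <- config$lineage_rate_sigma
    mult <- with_seed(derive_seed(config$seed, 1L, 2L),
                      exp(stats::rnorm(nrow(tr$edge), -s^2 / 2, s)))
  }
  ov <- config$lineage_rate_overrides
  if (length(ov)) {
    for (taxon in names(ov)) {
      i <- match(taxon, tr$tip.label)
      if (is.na(i)) stop_invalid("override taxon not in tree: ", taxon)
      mult[tr$edge[, 2] == i] <- as.numeric(ov[[taxon]])
    }
  }
  tr$edge.length <- tr$edge.length * mult
  tr
}

#' Simulate gene trees
#'
#' With `coalescent_theta = 0` every gene tree is the species tree with all
#' branch lengths multiplied by a per-gene log-normal rate; with
#' `theta > 0` gene trees are drawn by multispecies-coalescent simulation
#' (species-tree branch durations in coalescent units are `length / theta`),
#' node heights converted back to substitutions via `theta` and the gene
#' rate, with terminal-branch lineage overrides re-applied.
#'
#' @param species_tree rooted `phylo` from [simulate_species_tree()].
#' @param config a [sim_config()].
#' @return list of `n_genes` `phylo` objects; each carries a `gene_rate`
#'   attribute.
#' @export
simulate_gene_trees <- function(species_tree, config) {
  if (config$coalescent_theta < 0) stop_invalid("coalescent_theta must be >= 0")
  lapply(seq_len(config$n_genes), function(g) {
    sg <- derive_seed(config$seed, 2L, g)
    r <- if (config$gene_rate_sigma > 0)
      with_seed(sg, exp(stats::rnorm(1, -config$gene_rate_sigma^2 / 2,
                                     config$gene_rate_sigma)))
    else 1
    if (config$coalescent_theta == 0) {
      tr <- species_tree
      tr$edge.length <- tr$edge.length * r
    } else {
      tr <- msc_gene_tree(species_tree, config$coalescent_theta,
                          derive_seed(sg, 1L))
      tr$edge.length <- tr$edge.length * config$coalescent_theta * r
      ov <- config$lineage_rate_overrides
      for (taxon in names(ov)) {
        i <- match(taxon, tr$tip.label)
        if (!is.na(i))
          tr$edge.length[tr$edge[, 2] == i] <-
            tr$edge.length[tr$edge[, 2] == i] * as.numeric(ov[[taxon]])
      }
    }
    attr(tr, "gene_rate") <- r
    tr
  })
}

# One multispecies-coalescent gene tree; returned branch lengths are in
# coalescent units. Species-tree edge durations are length / theta.
msc_gene_tree <- function(species_tree, theta, seed) {
  sp <- ape::reorder.phylo(species_tree, "postorder")
  n_tip <- ape::Ntip(sp)
  with_seed(seed, {
    pool <- vector("list", n_tip + sp$Nnode)
    for (i in seq_len(n_tip))
      pool[[i]] <- list(list(nwk = sp$tip.label[i], blen = 0))
    run_edge <- function(lins, duration) {
      t <- 0
      k <- length(lins)
      while (k >= 2) {
        w <- rexp(1, rate = k * (k - 1) / 2)
        if (t + w > duration) break
        t <- t + w
        for (m in seq_len(k)) lins[[m]]$blen <- lins[[m]]$blen + w
        ij <- sample.int(k, 2)
        a <- lins[[ij[1]]]
        b <- lins[[ij[2]]]
        merged <- list(nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk, a$blen,
                                     b$nwk, b$blen),
                       blen = 0)
        lins <- c(lins[-ij], list(merged))
        k <- k - 1
      }
      if (is.finite(duration))
        for (m in seq_along(lins)) lins[[m]]$blen <- lins[[m]]$blen +
            (duration - t)
      lins
    }
    for (e in seq_len(nrow(sp$edge))) {
      child <- sp$edge[e, 2]
      parent <- sp$edge[e, 1]
      surv <- run_edge(pool[[child]], sp$edge.length[e] / theta)
      pool[[parent]] <- c(pool[[parent]] %||% list(), surv)
    }
    root <- n_tip + 1L
    final <- run_edge(pool[[root]], Inf)
    ape::read.tree(text = paste0(final[[1]]$nwk, ";"))
  })
}

#' Simulate an alignment on a tree
#'
#' The root state of each site is drawn from the stationary frequencies and
#' evolved along branches with transition matrices `exp(Q t r)`, the site
#' rate `r` drawn from the discrete-gamma / invariant mixture. Per-site rates
#' are recorded in the `site_rates` attribute.
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param model a [subst_model].
#' @param n_sites number of columns (>= 1).
#' @param seed RNG seed.
#' @param gene_id label for the resulting [msa].
#' @return an [msa] over the tree's leaves.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L,
                               gene_id = "gene") {
  if (ape::Ntip(tree) < 2) stop_invalid("tree must have >= 2 leaves")
  if (n_sites < 1) stop_invalid("n_sites must be >= 1")
  eg <- model_eigen(model)
  rates <- model_rates(model)
  ns <- length(model$alphabet)
  with_seed(seed, {
    site_rate <- rates[sample.int(length(rates), n_sites, replace = TRUE)]
    if (model$prop_invariant > 0) {
      inv <- runif(n_sites) < model$prop_invariant
      site_rate[inv] <- 0
    }
    tr <- ape::reorder.phylo(tree, "cladewise")
    n_nodes <- ape::Ntip(tr) + tr$Nnode
    states <- matrix(0L, n_nodes, n_sites)
    root <- ape::Ntip(tr) + 1L
    states[root, ] <- sample.int(ns, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    groups <- split(seq_len(n_sites), site_rate)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]
      chd <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      for (gname in names(groups)) {
        r <- as.numeric(gname)
        sites <- groups[[gname]]
        if (r == 0 || t == 0) {
          states[chd, sites] <- states[par, sites]
          next
        }
        P <- prob_matrix(eg, t * r)
        ps <- states[par, sites]
        for (s in unique(ps)) {
          at <- sites[ps == s]
          states[chd, at] <- sample.int(ns, length(at), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    m <- matrix(model$alphabet[states[seq_len(ape::Ntip(tr)), , drop = FALSE]],
                nrow = ape::Ntip(tr))
    rownames(m) <- tr$tip.label
    out <- msa(m, gene_id)
    attr(out, "site_rates") <- site_rate
    out
  })
}

#' Build a full synthetic dataset
#'
#' Species tree, gene trees, per-gene alignments (lengths uniform on
#' `gene_length_range`), then compositional bias, occupancy masking and
#' contaminant injection via [inject_bias_and_gaps()].
#'
#' @param config a [sim_config()].
#' @param species_tree optional fixed species tree (a `phylo` with branch
#'   lengths, `n_taxa` leaves); terminal-branch rate overrides from the
#'   config are applied to it. Default: simulated via
#'   [simulate_species_tree()].
#' @return object of class `synthetic_dataset`: list with `species_tree`,
#'   `gene_trees_true`, `alignments`, `occupancy_mask`, `contamination_log`,
#'   `config`.
#' @export
build_dataset <- function(config, species_tree = NULL) {
  sp <- if (is.null(species_tree)) {
    simulate_species_tree(config)
  } else {
    if (ape::Ntip(species_tree) != config$n_taxa)
      stop_invalid("species_tree leaf count must match n_taxa")
    tr <- species_tree
    for (taxon in names(config$lineage_rate_overrides)) {
      i <- match(taxon, tr$tip.label)
      if (is.na(i)) stop_invalid("override taxon not in tree: ", taxon)
      tr$edge.length[tr$edge[, 2] == i] <-
        tr$edge.length[tr$edge[, 2] == i] *
        as.numeric(config$lineage_rate_overrides[[taxon]])
    }
    tr
  }
  gts <- simulate_gene_trees(sp, config)
  model <- config_model(config)
  alns <- lapply(seq_len(config$n_genes), function(g) {
    len <- with_seed(derive_seed(config$seed, 3L, g),
                     sample(config$gene_length_range[1]:config$gene_length_range[2], 1))
    simulate_alignment(gts[[g]], model, len,
                       seed = derive_seed(config$seed, 4L, g),
                       gene_id = sprintf("g%04d", g))
  })
  mask <- matrix(TRUE, config$n_genes, config$n_taxa,
                 dimnames = list(vapply(alns, gene_id, ""), sp$tip.label))
  ds <- structure(list(species_tree = sp, gene_trees_true = gts,
                       alignments = alns, occupancy_mask = mask,
                       contamination_log = data.frame(
                         gene = integer(0), victim = character(0),
                         donor = character(0)),
                       config = config),
                  class = "synthetic_dataset")
  inject_bias_and_gaps(ds, config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d taxa, occupancy %.3f, %d contaminants\n",
              nrow(x$occupancy_mask), ncol(x$occupancy_mask),
              mean(x$occupancy_mask), nrow(x$contamination_log)))
  invisible(x)
}

#' Apply compositional bias, occupancy masking and contamination
#'
#' Composition bias resamples, per biased taxon, a fraction `strength` of its
#' sites i.i.d. from the target frequencies. The occupancy mask removes whole
#' gene-by-taxon cells uniformly at random (never a gene's last 4 taxa, never
#' cells involved in a contamination event) until global occupancy is at or
#' below the target. Contamination replaces the victim's sequence in the
#' stated gene with a fresh sequence evolved from the donor's sequence along
#' the donor's terminal branch.
#'
#' @param dataset a `synthetic_dataset` from [build_dataset()].
#' @param config its [sim_config()] (or an updated one).
#' @return the modified dataset.
#' @export
inject_bias_and_gaps <- function(dataset, config) {
  ds <- dataset
  taxa <- ds$species_tree$tip.label
  G <- length(ds$alignments)

  for (bi in seq_along(config$composition_bias)) {
    cb <- config$composition_bias[[bi]]
    if (cb$strength == 0) next
    for (g in seq_len(G)) {
      aln <- ds$alignments[[g]]
      if (!(cb$taxon %in% rownames(aln))) next
      nc <- ncol(aln)
      n_bias <- round(cb$strength * nc)
      if (n_bias == 0) next
      repl <- with_seed(derive_seed(config$seed, 5L, g, bi), {
        sites <- sample.int(nc, n_bias)
        list(sites = sites,
             sym = aa_alphabet()[sample.int(20, n_bias, replace = TRUE,
                                            prob = cb$target)])
      })
      aln[cb$taxon, repl$sites] <- repl$sym
      ds$alignments[[g]] <- aln
    }
  }

  protected <- matrix(FALSE, G, length(taxa),
                      dimnames = dimnames(ds$occupancy_mask))
  for (ev in config$contamination_events) {
    protected[ev$gene, ev$victim] <- TRUE
    protected[ev$gene, ev$donor] <- TRUE
  }

  mask <- ds$occupancy_mask
  total <- length(mask)
  if (config$occupancy_target < 1) {
    min_keep <- 4L
    if (config$occupancy_target * length(taxa) < min_keep)
      stop_invalid("occupancy_target too low to keep >= 4 taxa per gene")
    with_seed(derive_seed(config$seed, 6L), {
      while (sum(mask) / total > config$occupancy_target) {
        eligible <- which(mask & !protected &
                            (rowSums(mask)[row(mask)] > min_keep))
        if (!length(eligible))
          stop_invalid("occupancy_target infeasible: no removable cells left")
        drop <- eligible[sample.int(length(eligible), 1)]
        mask[drop] <- FALSE
      }
    })
  }
  for (g in seq_len(G)) {
    gone <- taxa[!mask[g, ]]
    if (length(gone)) {
      aln <- ds$alignments[[g]]
      keep <- setdiff(rownames(aln), gone)
      ds$alignments[[g]] <- msa(unclass(aln)[keep, , drop = FALSE],
                                gene_id(aln))
    }
  }
  ds$occupancy_mask <- mask

  log_rows <- list()
  model <- config_model(config)
  eg <- model_eigen(model)
  for (ei in seq_along(config$contamination_events)) {
    ev <- config$contamination_events[[ei]]
    aln <- ds$alignments[[ev$gene]]
    if (!all(c(ev$victim, ev$donor) %in% rownames(aln)))
      stop_invalid("contamination event ", ei,
                   ": victim or donor absent from gene ", ev$gene)
    gt <- ds$gene_trees_true[[ev$gene]]
    t_don <- gt$edge.length[gt$edge[, 2] == match(ev$donor, gt$tip.label)]
    donor_seq <- match(unclass(aln)[ev$donor, ], aa_alphabet())
    new_seq <- with_seed(derive_seed(config$seed, 7L, ei), {
      P <- prob_matrix(eg, max(t_don, 1e-9))
      vapply(donor_seq, function(s) {
        if (is.na(s)) return(NA_integer_)
        sample.int(20L, 1, prob = P[s, ])
      }, integer(1))
    })
    row <- unclass(aln)[ev$victim, ]
    row[!is.na(new_seq)] <- aa_alphabet()[new_seq[!is.na(new_seq)]]
    aln[ev$victim, ] <- row
    ds$alignments[[ev$gene]] <- aln
    log_rows[[ei]] <- data.frame(gene = ev$gene, victim = ev$victim,
                                 donor = ev$donor)
  }
  ds$contamination_log <- if (length(log_rows)) do.call(rbind, log_rows)
    else ds$contamination_log
  ds$config <- config
  ds
}

#' Write a synthetic dataset to disk
#'
#' Per-gene FASTA (masked taxa omitted), species tree and gene trees as
#' Newick (one per line), occupancy mask and contamination log as TSV, and a
#' JSON echo of the configuration.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  paths <- character(0)
  for (aln in dataset$alignments) {
    p <- file.path(dir, "genes", paste0(gene_id(aln), ".fasta"))
    write_fasta_msa(aln, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "species_tree.nwk")
  ape::write.tree(dataset$species_tree, p)
  paths <- c(paths, p)
  p <- file.path(dir, "gene_trees.nwk")
  writeLines(vapply(dataset$gene_trees_true, ape::write.tree, ""), p)
  paths <- c(paths, p)
  p <- file.path(dir, "occupancy_mask.tsv")
  write.table(data.frame(gene_id = rownames(dataset$occupancy_mask),
                         dataset$occupancy_mask, check.names = FALSE),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "contamination_log.tsv")
  write.table(dataset$contamination_log, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(dataset$config), p, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
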