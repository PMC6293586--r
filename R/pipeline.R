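# Pipeline orchestration: run the stages in dependency order from a single
# config with one master seed, write standard-format outputs plus a manifest
# of content hashes, and build the canned fixture scenarios used by the test
# suite. Column coordinates in tables are 0-based half-open; Newick branch
# lengths are substitutions/site.

pipeline_stage_order <- function() {
  c("simulate", "genetrees", "metrics", "filter", "quartets", "delta",
    "sowh", "screen")
}

#' Run the analysis pipeline
#'
#' Stages (in dependency order): `simulate` (synthetic dataset),
#' `genetrees` (NJ gene trees from Poisson-corrected p-distances),
#' `metrics` (per-gene diagnostics), `filter` (combined ranking + exclusion),
#' `quartets` (around-branch support; exact search when feasible),
#' `delta` (gene-wise delta on a small taxon subset), `sowh` (SOWH test on a
#' 4-taxon subset), `screen` (residual + diameter contamination screens).
#' Every output file is hashed into `manifest.tsv`; identical config + seed
#' reproduce identical hashes.
#'
#' @param config nested list; top-level keys must be among `stages`, `seed`,
#'   and the stage names. Each stage entry holds that stage's parameters
#'   (see the pipeline vignette).
#' @param outdir output directory.
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), outdir) {
  known <- c("stages", "seed", pipeline_stage_order())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  stages <- config$stages %||% pipeline_stage_order()
  bad <- setdiff(stages, pipeline_stage_order())
  if (length(bad)) stop_invalid("unknown stages: ", paste(bad, collapse = ", "))
  stages <- intersect(pipeline_stage_order(), stages)
  seed <- config$seed %||% 1L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  res <- list()

  if ("simulate" %in% stages) {
    sc_args <- config$simulate %||% list()
    sc_args$seed <- sc_args$seed %||% derive_seed(seed, 1L)
    sc <- do.call(sim_config, sc_args)
    note("simulate: seed ", sc$seed)
    res$dataset <- build_dataset(sc)
    write_dataset(res$dataset, file.path(outdir, "dataset"))
  }
  ds <- res$dataset
  if (is.null(ds) && length(setdiff(stages, "simulate")))
    stop_invalid("downstream stages need the simulate stage (or prior outputs)")

  if ("genetrees" %in% stages) {
    note("genetrees: NJ on Poisson-corrected p-distances")
    res$gene_trees <- estimate_nj_gene_trees(ds$alignments)
    ok <- !vapply(res$gene_trees, is.null, logical(1))
    note("genetrees: ", sum(ok), "/", length(ok), " genes with trees")
    writeLines(vapply(res$gene_trees[ok], ape::write.tree, ""),
               file.path(outdir, "gene_trees_nj.nwk"))
  }

  need <- function(what, stage) {
    if (is.null(what))
      stop_invalid("stage '", stage, "' requires an earlier stage that did not run")
    what
  }

  if ("metrics" %in% stages) {
    need(res$gene_trees, "metrics")
    og <- config$metrics$outgroup %||% ds$species_tree$tip.label[1]
    note("metrics: outgroup ", paste(og, collapse = ","))
    res$diagnostics <- gene_diagnostics(ds$alignments, res$gene_trees,
                                        outgroup = og,
                                        expected_taxa = ds$species_tree$tip.label)
    write_tsv(res$diagnostics, file.path(outdir, "gene_diagnostics.tsv"))
  }

  if ("filter" %in% stages) {
    q <- config$filter$q %||% 0.66
    ranked <- combine_and_rank(need(res$diagnostics, "filter"))
    res$filter <- exclude_top_fraction(ranked, q)
    note("filter: q = ", q, "; retained ", length(res$filter$retained_ids))
    ranked$retained <- ranked$gene_id %in% res$filter$retained_ids
    write_tsv(ranked, file.path(outdir, "filter_result.tsv"))
  }

  if ("quartets" %in% stages) {
    need(res$gene_trees, "quartets")
    ok <- !vapply(res$gene_trees, is.null, logical(1))
    gts <- res$gene_trees[ok]
    res$branch_support <- branch_support_table(ds$species_tree, gts,
                                               seed = derive_seed(seed, 5L))
    write_tsv(res$branch_support, file.path(outdir, "branch_support.tsv"))
    if (length(ds$species_tree$tip.label) <= 8) {
      srch <- exact_quartet_search(gts)
      note("quartets: exact search over ", srch$n_topologies, " topologies")
      ape::write.tree(srch$trees[[1]], file.path(outdir, "quartet_best_tree.nwk"))
      res$quartet_search <- srch
    } else {
      note("quartets: > 8 taxa; exact search skipped, branch support only")
    }
  }

  if ("delta" %in% stages) {
    res$deltas <- pipeline_delta_stage(ds, config$delta %||% list(),
                                       derive_seed(seed, 6L), note)
    write_tsv(res$deltas, file.path(outdir, "gene_deltas.tsv"))
  }

  if ("sowh" %in% stages) {
    res$sowh <- pipeline_sowh_stage(ds, config$sowh %||% list(),
                                    derive_seed(seed, 7L), note)
    jsonlite::write_json(
      list(delta_observed = res$sowh$delta_observed,
           p_value = res$sowh$p_value,
           n_replicates = res$sowh$n_replicates,
           constraint = res$sowh$constraint_label),
      file.path(outdir, "sowh_result.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("screen" %in% stages) {
    focal <- config$screen$focal %||% ds$species_tree$tip.label[2]
    refs <- config$screen$references
    res$residuals <- residual_screen(ds$alignments, focal, refs,
                                     seed = derive_seed(seed, 8L))
    write_tsv(as.data.frame(res$residuals),
              file.path(outdir, "residual_screen.tsv"))
    ok <- !vapply(res$gene_trees %||% list(), is.null, logical(1))
    if (any(ok)) {
      big <- vapply(res$gene_trees[ok], function(t) ape::Ntip(t) >= 5,
                    logical(1))
      res$diameter <- diameter_outliers(res$gene_trees[ok][big])
      write_tsv(res$diameter, file.path(outdir, "diameter_outliers.tsv"))
    }
    note("screen: focal ", focal)
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Estimate NJ gene trees for a set of alignments
#'
#' Poisson-corrected p-distances into neighbor joining; genes with
#' unavailable pairwise distances or fewer than 4 taxa yield `NULL` (skipped,
#' to be logged by the caller).
#'
#' @param alignments list of [msa] objects.
#' @return list of `phylo` or `NULL`, parallel to `alignments`.
#' @export
estimate_nj_gene_trees <- function(alignments) {
  lapply(alignments, function(aln) {
    if (nrow(aln) < 4) return(NULL)
    d <- correct_distance(p_distance_matrix(aln))
    tryCatch(nj_gene_tree(d), phylosieve_skip = function(e) NULL,
             error = function(e) NULL)
  })
}

pipeline_delta_stage <- function(ds, opts, seed, note) {
  taxa <- opts$taxa %||% {
    occ <- colSums(ds$occupancy_mask)
    sort(head(names(sort(occ, decreasing = TRUE)), 5))
  }
  gene_sub <- opts$genes %||% seq_along(ds$alignments)
  keep <- vapply(ds$alignments[gene_sub],
                 function(a) all(taxa %in% rownames(a)), logical(1))
  gene_sub <- gene_sub[keep]
  if (!length(gene_sub)) stop_invalid("delta stage: no gene covers the taxon subset")
  alns <- lapply(ds$alignments[gene_sub], function(a)
    msa(unclass(a)[taxa, , drop = FALSE], gene_id(a)))
  concat <- do.call(cbind, lapply(alns, unclass))
  rownames(concat) <- taxa
  concat <- msa(concat, "concat")
  lens <- vapply(alns, ncol, 1L)
  partition <- data.frame(gene_id = vapply(alns, gene_id, ""),
                          start = cumsum(c(0L, lens[-length(lens)])),
                          end = cumsum(lens))
  gts <- estimate_nj_gene_trees(alns)
  ok <- !vapply(gts, is.null, logical(1))
  srch <- exact_quartet_search(gts[ok], taxa = taxa)
  t_unc <- srch$trees[[1]]
  constraint <- opts$constraint %||% {
    pd <- patristic_matrix(ape::keep.tip(ds$species_tree, taxa))
    far <- arrayInd(which.max(pd), dim(pd))
    sort(rownames(pd)[as.vector(far)])
  }
  cands <- Filter(function(tr) satisfies_constraint(tr, list(constraint)),
                  enumerate_topologies(taxa))
  scores <- vapply(cands, function(tr) quartet_score(tr, gts[ok]), numeric(1))
  t_con <- cands[[which.max(scores)]]
  note("delta: ", length(gene_sub), " genes, taxa ",
       paste(taxa, collapse = ","), ", constraint ",
       paste(constraint, collapse = "+"))
  model <- config_model(ds$config)
  gene_deltas(concat, partition, t_unc, t_con, model)
}

pipeline_sowh_stage <- function(ds, opts, seed, note) {
  taxa <- opts$taxa %||% {
    occ <- colSums(ds$occupancy_mask)
    head(names(sort(occ, decreasing = TRUE)), 4)
  }
  n_rep <- opts$n_replicates %||% 19L
  gene_sub <- opts$genes %||% {
    covers <- which(vapply(ds$alignments,
                           function(a) all(taxa %in% rownames(a)), logical(1)))
    head(covers, 1)
  }
  alns <- Filter(function(a) all(taxa %in% rownames(a)),
                 ds$alignments[gene_sub])
  if (!length(alns)) stop_invalid("sowh stage: no gene covers the taxon subset")
  concat <- do.call(cbind, lapply(alns, function(a)
    unclass(a)[taxa, , drop = FALSE]))
  rownames(concat) <- taxa
  concat <- msa(concat, "sowh_input")
  constraint <- opts$constraint %||% sort(taxa)[1:2]
  note("sowh: ", ncol(concat), " sites, constraint ",
       paste(constraint, collapse = "+"), ", ", n_rep, " replicates")
  model <- config_model(ds$config)
  sowh_test(concat, model, list(constraint), n_replicates = n_rep,
            seed = seed)
}

#' Build a named fixture scenario
#'
#' Canned synthetic scenarios with a stated planted truth, used by the test
#' suite and as worked examples:
#' `clock` (strict clock: every gene tree has zero root-to-tip variance),
#' `rate_heterogeneity` (random branch rates plus planted slow 0.2x / fast
#' 5x terminals), `contamination` (5 cross-taxon contaminants among 200
#' genes; donor in the second reference's clade), `sowh_null` (4-taxon data
#' simulated under the constrained topology), `quartet_conflict` (planted
#' 0.2x/5x lineages with short genes, for the gene-tree-error rescue
#' experiment).
#'
#' @param name one of the scenario names above.
#' @param dir optional directory to write the dataset into (a `README.md`
#'   stating the planted truth is included).
#' @param seed master seed.
#' @return list with `dataset`, `config`, and scenario extras (e.g.
#'   `focal_clade`, `references`, `constraint`).
#' @export
make_fixtures <- function(name = c("clock", "rate_heterogeneity",
                                   "contamination", "sowh_null",
                                   "quartet_conflict"),
                          dir = NULL, seed = 1L) {
  name <- match.arg(name)
  fx <- switch(name,
    clock = {
      cfg <- sim_config(n_taxa = 8, tree_height = 0.4,
                        lineage_rate_sigma = 0, n_genes = 20,
                        gene_length_range = c(200, 200),
                        occupancy_target = 1, seed = seed)
      list(dataset = build_dataset(cfg), config = cfg,
           truth = "strict clock: all gene-tree root-to-tip variances are 0")
    },
    rate_heterogeneity = {
      cfg <- sim_config(n_taxa = 10, tree_height = 0.5,
                        lineage_rate_sigma = 0.4,
                        lineage_rate_overrides = list(t03 = 0.2, t07 = 5),
                        n_genes = 40, gene_length_range = c(150, 300),
                        occupancy_target = 1, seed = seed)
      list(dataset = build_dataset(cfg), config = cfg,
           slow = "t03", fast = "t07",
           truth = "t03 terminal branch x0.2, t07 terminal branch x5")
    },
    contamination = {
      sp <- ape::read.tree(text = paste0(
        "((F:0.07,x1:0.07):0.27,((R2:0.015,D:0.015):0.255,",
        "((R1:0.09,x2:0.09):0.12,(x3:0.09,x4:0.09):0.12):0.06):0.06);"))
      events <- lapply(c(11L, 53L, 101L, 149L, 197L), function(g)
        list(gene = g, victim = "F", donor = "D"))
      cfg <- sim_config(n_taxa = 8, tree_height = 0.25,
                        lineage_rate_sigma = 0, n_genes = 200,
                        gene_length_range = c(400, 400),
                        gene_rate_sigma = 0.35, occupancy_target = 1,
                        contamination_events = events, seed = seed)
      list(dataset = build_dataset(cfg, species_tree = sp), config = cfg,
           focal = "F", references = c("R1", "R2"), donor = "D",
           contaminated_genes = vapply(events, `[[`, 1L, "gene"),
           truth = "genes 11,53,101,149,197: F replaced by a D-derived sequence")
    },
    sowh_null = {
      sp <- ape::read.tree(
        text = "((t01:0.2,t02:0.2):0.1,(t03:0.2,t04:0.2):0.1);")
      cfg <- sim_config(n_taxa = 4, tree_height = 0.3,
                        lineage_rate_sigma = 0, n_genes = 1,
                        gene_length_range = c(300, 300), gene_rate_sigma = 0,
                        gamma_shape = NULL, prop_invariant = 0,
                        occupancy_target = 1, seed = seed)
      list(dataset = build_dataset(cfg, species_tree = sp), config = cfg,
           constraint = c("t01", "t02"),
           truth = "data simulated under the topology satisfying the t01+t02 constraint")
    },
    quartet_conflict = {
      sp <- ape::read.tree(text = paste0(
        "(out:0.45,(mid:0.35,(slow:0.12,(fast:0.12,",
        "(s1:0.12,s2:0.12):0.1):0.08):0.08):0.1);"))
      cfg <- sim_config(n_taxa = 6, tree_height = 0.5,
                        lineage_rate_sigma = 0,
                        lineage_rate_overrides = list(slow = 0.2, fast = 5),
                        n_genes = 150, gene_length_range = c(100, 100),
                        gene_rate_sigma = 0.8, occupancy_target = 1,
                        seed = seed)
      list(dataset = build_dataset(cfg, species_tree = sp), config = cfg,
           focal_clade = c("fast", "s1", "s2"), outgroup = "out",
           truth = "species tree places fast inside (fast,(s1,s2)); slow x0.2 and fast x5 planted")
    })
  if (!is.null(dir)) {
    write_dataset(fx$dataset, dir)
    writeLines(c(paste0("# Fixture: ", name), "", fx$truth),
               file.path(dir, "README.md"))
  }
  fx
}
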