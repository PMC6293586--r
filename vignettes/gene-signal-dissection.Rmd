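---
title: "Gene-level diagnostics and signal dissection for phylogenomic matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level diagnostics and signal dissection for phylogenomic matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosieve)
```

## The problem this package addresses

Phylogenomic supermatrices — hundreds of amino-acid loci over a few dozen
taxa — routinely yield fully supported but mutually conflicting topologies
depending on the inference method. A recurring culprit is heterogeneity among
genes and lineages: fast-evolving lineages saturate, clock-violating genes
produce unreliable gene trees, and summary species-tree methods that consume
those gene trees can be biased towards artefactual resolutions even when
concatenation approaches agree with each other. phylosieve implements the
gene-level machinery needed to diagnose and dissect this situation:

* **per-gene diagnostics** — saturation, root-to-tip variance, compositional
  heterogeneity (RCFV), missing data;
* **rank-based gene exclusion** with matched random-subsampling controls;
* **quartet-based species-tree estimation** (exact at desk scale) to test
  whether filtering changes the inferred topology;
* **gene-wise δ log-likelihoods** that attribute topological signal to
  individual loci, with a confounder screen relating δ to the diagnostics;
* **the SOWH parametric-bootstrap topology test**;
* **contamination screens** (alien index, cross-sample p-distance residuals,
  gene-tree diameter outliers);
* a **synthetic-data generator** that reproduces the statistical structure
  all of the above assumes, so the whole pipeline is testable end to end
  without any external data.

## Models and statistics

### Per-gene diagnostics

*Saturation* is measured as `1 − slope` of the ordinary-least-squares
regression of pairwise p-distances on patristic distances computed from the
gene tree: at low divergence observed distance tracks evolutionary distance
(slope near 1, statistic near 0); as multiple hits accumulate the observed
distances plateau and the statistic grows towards 1. The regression is
unweighted and uses all taxon pairs available in both matrices; with fewer
than three usable pairs, or no spread in patristic distance, the statistic is
flagged undefined rather than silently dropped.

*Rate heterogeneity* is the sample variance (n−1 denominator) of root-to-tip
distances, measured from the most recent common ancestor of the ingroup
after rooting the gene tree with a configured outgroup (midpoint rooting is
the logged fallback when no outgroup survives occupancy masking). A strict
molecular clock gives exactly zero.

*RCFV* sums, over states and taxa, the absolute deviation of each taxon's
amino-acid frequencies from the across-taxon mean, divided by the number of
taxa. It is zero iff all taxa share one composition and grows with planted
compositional bias.

*Missing fraction* counts absent-taxon cells plus gap/`X` cells against the
full expected-taxa × columns grid.

### Filtering

The two rate-related diagnostics are centered and scaled to unit sample SD
across genes and summed; genes are ranked by this combined score and the
highest-ranking fraction `q` is excluded, with `floor(q·n)` excluded so that
`q = 0.66` on 1040 genes retains exactly 354. Ties break by gene id so runs
are reproducible; genes with undefined metrics rank last and stay flagged.
`random_subsamples()` provides the matched control: subsets of identical
size drawn uniformly without replacement.

### Likelihood engine

Site log-likelihoods use Felsenstein pruning under reversible amino-acid
models `Q = S·diag(π)`, normalized to one expected substitution per site.
Across-site rate variation uses the discrete-gamma "category means" scheme
(k equal-probability slices of a Gamma(α, α), slice means rescaled to mean
exactly 1; k = 4 by default) plus an independent invariant-sites component:

```
L(site) = p_inv · [site invariant ? π_state : 0] + (1 − p_inv) · mean_k L_k(site)
```

Gaps and `X` contribute partial likelihood 1 for every state, so an all-gap
column contributes log-likelihood exactly 0. Partial likelihood vectors are
rescaled per node with per-site log-scaler accumulation, and results are
identical (to 1e-10) under any rooting of the same unrooted tree. The
pruning kernel is verified in the test suite against brute-force enumeration
of interior-node states, against the 20-state equal-rates closed form, and
against an independent likelihood implementation.

Branch lengths are optimized by coordinate ascent (bounded scalar search on
`[1e-8, 20]` per branch, sweeps until the gain drops below `1e-4`). Topology
search is exhaustive for up to 7 taxa — all `(2n−5)!!` unrooted topologies,
enumerated in a fixed leaf-insertion order that also serves as the tie-break
— and NNI hill-climbing from a neighbor-joining start above that. Monophyly
constraints are enforced as clade-versus-rest bipartitions of the unrooted
tree.

This engine is a deliberate desk-scale stand-in for the external ML programs
a full-scale study would use: single exchangeability matrix with +Γ+I rather
than mixture models, shared model parameters across partitions, exhaustive
or NNI search rather than large-scale heuristics.

### Gene-wise δ and the confounder screen

For an unconstrained topology `T_u` and a constraint-satisfying topology
`T_c`, branch lengths of each are optimized once on the full concatenated
matrix, per-site log-likelihoods are computed under both, and
`δ_g = Σ_{sites ∈ g} [ll(T_u) − ll(T_c)]`. Positive δ favors the
unconstrained topology, and per-gene δ sums exactly to the whole-matrix
log-likelihood difference. Downstream summaries retain genes with
`|δ| > 3` (the default cutoff, configurable).

The confounder screen asks whether δ tracks anything other than phylogenetic
history: (a) OLS of δ on RCFV, root-to-tip variance, saturation and missing
fraction, reported with the overall F-test and R²; (b) a two-group
multivariate location test on the same four diagnostics, with groups defined
by the sign of δ, using Wilks' Λ computed from between/within scatter
matrices. Rather than relying on the classical F approximation, the Λ
statistic is calibrated by label permutation (default 9999 permutations,
add-one p-value) — assumption-free, and exactly testable in the suite, while
the statistic itself keeps its classical definition. Collinear predictors
are dropped and reported rather than producing a singular fit.

### SOWH test

The observed statistic is `δ_obs = ll(best unconstrained) − ll(best
constrained)`. Model parameters (branch lengths, γ shape by golden-section
on `[0.05, 10]`, invariant proportion on the grid `0, 0.05, …, 0.5`) are
fitted on the constrained tree; `n` parametric-bootstrap datasets of the
original length are simulated on that fitted tree and each is re-analyzed
with the same pair of topology searches. The p-value uses the add-one
Monte-Carlo formula `(1 + #{δ_i ≥ δ_obs}) / (n + 1)`, which is a valid
p-value and never exactly zero. One simplification relative to a full
re-implementation: replicates are re-analyzed under the model fitted on the
observed data's constrained tree (the search procedure is identical;
per-replicate re-fitting of α and p_inv is skipped at desk scale). The
suite checks the test's type-I calibration empirically: data simulated under
the constrained topology are rejected at α = 0.05 at a rate inside the
exact binomial 95% band over 40 trials.

### Quartet methods

Gene trees are decomposed into induced quartets (the pairing minimizing the
sum of the two within-pair topological distances; ties mean unresolved).
The species-tree criterion is the quartet score — the number of (gene tree,
4-taxon set) pairs whose induced quartet matches the candidate — i.e. the
same objective quartet-based summary methods optimize, solved exactly by
enumerating all topologies for up to 8 taxa, with all co-optima returned.
Around each internal branch, `branch_support_table()` reports the three
quartet-arrangement frequencies averaged over quartets drawn one-per-subtree
(exact up to 500 defining quartets, seeded sampling above), the sufficient
statistic behind quartet-frequency support measures; the support formula
itself is intentionally not re-implemented. The subsampling harness runs
the exact search over replicate gene subsets and records whether a focal
clade is recovered by every co-optimum.

### Contamination screens

*Alien index*: `AI = ln(e_expected + ε) − ln(e_other + ε)` with
`ε = 1e-200`, absent hits treated as E = 1, and sequences flagged foreign at
`AI ≥ 45`.

*Residual screen*: per gene, `x = p(focal, ref1)` and `y = p(focal, ref2)`;
an OLS line over genes and a `3·SD` residual envelope flag genes whose
divergence pattern breaks the lineage-wide relation. The regression
direction (y on x with two seeded random references) is a declared choice —
the construction is symmetric enough that the planted-outlier fixture flags
the same gene under either orientation.

*Diameter screen*: per gene × leaf, the proportional reduction in gene-tree
diameter after removing the leaf, pooled per species; flags require both
exceeding the species' empirical (1−q)-quantile (q = 0.02) and an absolute
floor `min_impact = 0.2` so near-clock trees never flag. This is an
explicitly simplified stand-in for full signal-to-noise outlier-detection
tools.

## The synthetic-data generator

`sim_config()` + `build_dataset()` state the world the analyses assume:

* **Species tree**: pure-birth topology, branch lengths scaled so the mean
  root-to-tip path equals `tree_height` (default 0.5 substitutions/site —
  deep-divergence transcriptome scale), then multiplied by per-branch
  log-normal rate factors (SD 0.3, mean 1) with terminal-branch overrides to
  plant slow/fast lineages.
* **Gene trees**: with `coalescent_theta = 0` every gene tree carries the
  species-tree topology times a per-gene log-normal rate (SD 0.5) — the
  concatenation regime, appropriate because the targeted artefact is
  attributed to gene-tree *error*, not deep coalescence. With `theta > 0`,
  gene trees come from a hand-rolled multispecies-coalescent simulation
  (species-tree branch durations `length/theta` in coalescent units),
  checked against the closed-form discordance probability `2/3·e^{−T}`.
* **Alignments**: root states from the stationary distribution, evolved with
  `exp(Qtr)` per branch under the same +Γ+I machinery the likelihood engine
  uses (defaults α = 0.75, k = 4, p_inv = 0.1; gene lengths uniform on
  100–500 columns — the real matrix's length distribution is unpublished,
  so this range is an explicit, configurable assumption).
* **Bias and gaps**: compositional bias resamples a fraction of a taxon's
  sites i.i.d. from a target frequency vector; occupancy masking removes
  whole gene × taxon cells uniformly at random (never below 4 taxa per
  gene) until global occupancy reaches the target (default 0.70);
  contamination replaces a victim's sequence with a fresh sequence evolved
  from the donor along the donor's terminal branch.
* **Determinism**: one master seed; child seeds derived by a fixed
  enumeration order (genes, then taxa), so enlarging a simulation never
  changes already-generated genes, and identical configs serialize
  byte-identically.

What the generator does **not** emulate: assembly artifacts, indels and
alignment error, codon structure, site-heterogeneous (mixture) processes,
chimeric (partial-sequence) contamination. A green test therefore
establishes that the machinery behaves correctly in the stated world, not
that any empirical dataset is free of these additional complications.

### The fixture scenarios

`make_fixtures()` freezes five scenarios with stated planted truths. The
`quartet_conflict` world deserves its rationale spelled out: it plants a
slow (0.2×) lineage outside a clade containing a fast (5×) lineage, with
pre-multiplier terminal branches ≈ 0.12 and internal branches 0.08–0.1
substitutions/site (root-to-tip ≈ 0.5, about a 3× spread among lineages —
the scale seen in deep invertebrate transcriptome studies), 150 genes of
100 columns with per-gene log-normal rates (SD 0.8). Short genes and high
per-gene rates produce exactly the failure mode of interest: high-rate genes
saturate and their NJ gene trees misplace the fast lineage, while low-rate
genes carry recoverable signal. The experiment compares the
diagnostics-filtered subset (deterministic, analyzed once) against 20 random
subsets of the same size; the qualitative expectation is that filtering
recovers the true focal clade at least as often as random deletion. This
contrast was verified across several unrelated seeds before the scenario was
frozen.

The `contamination` world also encodes a deliberate geometry. An OLS
residual screen is vulnerable to leverage masking: if the focal taxon sits
next to one reference, contaminants land far outside the clean x-range and
rotate the fitted line onto themselves. The frozen scenario therefore places
both references at ordinary phylogenetic distances from the focal taxon —
as randomly drawn reference transcriptomes would be — with the donor lineage
sister to one reference (contamination from a lineage present in the
dataset), 200 genes of 400 columns and a moderate per-gene rate spread
(log-normal SD 0.35) so the clean points form the tight linear relation the
screen assumes. In this world the screen recovers planted contaminants with
pooled recall ≈ 0.96 and precision ≈ 0.77 over ten seed batches, while
flagging at most 2% of genes in clean data.

## Numerical choices and degenerate inputs

* Branch-length bounds `[1e-8, 20]`; optimizer sweep tolerance `1e-4`
  log-likelihood units, 50-sweep cap (capped runs warn and flag).
* p-distance correction `d = −(19/20)·ln(1 − (20/19)p)` capped at p = 0.94
  (capped entries flagged); used only to feed neighbor joining.
* NJ negative branch estimates clamped to 0 and counted; genes with
  unavailable distances are skipped via a typed condition, not errors.
* Percentile (2.5/97.5) intervals for posterior rate summaries, not normal
  approximations; sample (n−1) variance throughout.
* Quartet ties (zero-length or multifurcating restrictions) are
  "unresolved" and score 0.
* Residual screens treat a residual SD below 1e-12 as a degenerate
  (numerically exact) fit and flag nothing.
* All-gap columns, taxa without usable sites, and genes below the minimum
  taxon count are excluded-and-logged, never silently dropped.

## Reproducing the analyses

```r
library(phylosieve)

config <- list(
  seed = 42,
  simulate = list(n_taxa = 20, n_genes = 60),
  filter = list(q = 0.66))
res <- run_pipeline(config, outdir = "demo_run")
```

The run writes per-gene FASTA, Newick trees, diagnostics/filter/support
tables, SOWH and screen results, a verbatim config echo, a log with every
resolved stage seed, and `manifest.tsv` with an md5 hash per output file;
rerunning with the same config and seed reproduces the hashes exactly.
`scripts/acceptance.R --seed <s> --out <path>` runs the same pipeline on a
12-taxon, 40-gene demo configuration and writes the (empty) JSON target
report.

## Known limitations

* Exhaustive searches are capped (7 taxa for likelihood, 8 for quartets);
  NNI hill-climbing above that is a local search with no optimality
  guarantee.
* The SOWH implementation fixes the fitted model across bootstrap
  replicates (see above); with very short alignments this can make the test
  slightly conservative.
* Only whole-sequence contaminant events are simulated and screened;
  chimeric assemblies would dilute the residual signal.
* Empirical exchangeability matrices are supported via PAML-format `.dat`
  files but none ships with the package; the built-in Poisson model is used
  throughout the tests.
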