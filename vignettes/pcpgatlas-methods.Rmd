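---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pcpgatlas re-implements, as a tested pipeline, the computational analysis
behind a combined single-nuclei and bulk-transcriptome atlas of
pheochromocytoma and paraganglioma (PCPG). This vignette is the package's own
account of the science: the models and their assumptions, the tunable
parameters with their defaults and units, what the synthetic-data generators
do and do not emulate, and the design choices made where the design was
genuinely open. Nothing stated here as an empirical result goes beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## 1. Single-nuclei quality control

All QC statistics are robust z-scores ("MAD scores"):
`(x - median) / (1.4826 * MAD)`, the 1.4826 consistency constant making the
MAD estimate the normal SD. When the MAD degenerates to zero the filter
operations fall back to mean-absolute-deviation scaling (constant
`sqrt(pi/2)`), so a gross outlier in an otherwise constant score vector is
still caught; the bare `mad_score()` contract returns zeros with a
degeneracy flag instead.

Three per-cell criteria are conjoined by `mad_filter_cells()`:

* **doublet score** — externally computed scores (the pipeline never
  recomputes them from counts) are MAD-normalized per sample and cells with
  score \>= 2 are removed. The protocol wording this mirrors ("removed ...
  with MAD values \<2") literally removes *low*-score cells, which
  contradicts doublet-detection logic; we remove high-score outliers and
  expose `direction = "low"` for the literal reading.
* **mitochondrial fraction** — MAD score \<= 5.
* **total counts** — on natural-log total counts, lower-tail only: MAD score
  \>= -4 for lymphoid lineages (B, T, mast, NK cells: their nuclei genuinely
  carry less RNA) and \>= -2.5 otherwise. The log base is immaterial (MAD
  scores are affine-invariant); two-sided filtering is available behind a
  config switch but off by default.

## 2. Normalization and variable genes

`lognormalize()` is the standard depth normalization
`ln(1 + 10^4 * count / total)`. The variance-stabilizing transform is an
analytic **Pearson-residual** normalization (`pearson_residuals()`): under a
null in which every cell expresses gene *g* at its global share *p~g~* of
the cell's depth, residuals `(x - mu) / sqrt(mu + mu^2/theta)` with fixed
`theta = 100` and clipping at `sqrt(n_cells)` stabilize variance; per-gene
residual variance drives variable-gene selection (threshold 1.3, or top-3000
mode for classification). This is a deliberate, documented surrogate for
regularized-NB VST fitting: it reproduces the variance-stabilizing role at a
fraction of the complexity, and the covariate step (mitochondrial fraction,
cell-cycle module scores as non-regularized latent variables) is realized by
per-gene least-squares residualization afterwards (`residualize_covariates()`,
then re-selection of variable genes).

Clustering is the standard kNN pipeline: PCA on standardized variable genes
(20 PCs, sign fixed by the largest-magnitude loading), exact cosine kNN
(k = 20), shared-nearest-neighbour Jaccard weights (prune 1/15), Louvain
modularity at resolution 0.8 (igraph; seeded, first-improvement tie-break),
and a uwot UMAP (cosine, 20 neighbours, single-threaded SGD for
determinism).

A note on the embedding's guarantees: on the bundled fixture the cell types
are tight NB-noise balls in PC space, so the *identity* of a cell's 10
nearest neighbours within its own cluster is essentially noise — no
embedding can preserve it. The suite therefore asserts fine-grained 10-NN
overlap well above chance (\>= 0.15 vs ~0.03) and near-perfect coarse
(cluster-level) neighbourhood preservation (\>= 0.95), rather than a larger
fine-grained constant that no method would attain on such data.

## 3. Reference-centroid cell typing and module scores

References are collapsed to per-type centroids by the mean of log-normalized
expression. Cells are scored against each centroid by **Spearman
correlation** over the intersection of highly variable genes (minimum
overlap 50), making calls invariant to any strictly monotone per-cell
transform; ties break alphabetically with a flag. Per-cluster labels are the
mode of member calls (ties to the higher mean correlation); clusters whose
mean best-correlation falls below 0.2 are labelled `unassigned` rather than
forced — the floor is our choice (the original workflow resolved such
clusters by manual curation) and sits in the config. We standardize on
log-normalized values on both sides of the correlation; rank correlation
makes the difference from raw-count scoring immaterial.

`module_score()` bins genes into 24 equal-frequency bins of mean expression
and, for each set gene, draws 100 control genes from its bin (with
replacement if the bin is small, set genes excluded); the score is the mean
set expression minus the mean control expression, per cell. Only `n_ctrl =
100` is inherited from the original method; the equal-frequency binning at
`n_bins = 24` is our fixed choice.

## 4. Expression-inferred copy number

`infer_cnv_profiles()` implements the windowed-mean core of reference-based
CNV inference: restrict to genes with mean count \>= 0.1; transform to
`log2(1 + CPM/10)`; subtract the per-gene mean over diploid reference cells;
cap at ±3 reference SDs; order genes genomically (0-based BED coordinates
throughout); smooth with a 101-gene centred moving average that never
crosses chromosome boundaries (windows shrink symmetrically at the edges);
re-centre each cell by its median. The published tool's HMM/denoising layers
are out of scope. Defaults (window 101, floor 0.1, ±3 SD) follow that tool's
conventions.

Two properties shape the tests: (i) the per-gene *mean* reference profile is
nearly zero (RMS \< 0.05 on the fixture; individual genes at chromosome
edges reach ~0.03 because shrunk windows interact with the median
re-centering skew); (ii) per-cell median re-centering makes calls relative —
a clone carrying a large deletion shows a small positive offset on its
unaffected chromosomes. Arm-level calls (`summarize_arm_events()`,
thresholds ±0.05) therefore read best as contrasts between clones.
Expression can only support copy-loss calls, not loss of heterozygosity:
copy-neutral LOH is invisible here, and the package deliberately reports
losses, not "LOH".

Subclones are Ward (`ward.D2`) hierarchical clusters of Euclidean distances
between smoothed profiles, cut at `k` or at a height.

## 5. The bulk compendium: harmonization and batch model

Microarray batches are merged and quantile normalized together (classic
rank-mean QN; ties take the mean of their spanned quantiles; with missing
values each column maps through the mean quantile function on a common
grid). Their pooled distribution becomes the **quantile target**; RNA-seq
and pseudo-bulk batches are log-transformed (`log2(x + 0.5)` — the original
protocol does not state the pre-QN transform for counts; QN makes any
monotone choice equivalent) and mapped onto the target by rank.

The **batch model** is a per-gene weighted least-squares fit
`y = mu_g + beta_batch + gamma_genotype + e` on the samples observing the
gene (missingness is constrained to whole gene-by-batch blocks; partial
missingness is promoted with a warning). Batch is sum-to-zero coded over the
batches observing the gene, genotype treatment-coded against the
alphabetically first genotype, and samples with unknown genotype (plus any
explicitly listed set, e.g. a confounded cluster) carry zero weight — they
never inform the fit but are still corrected, since their batch term is
defined. Correction subtracts only the batch term; genotype effects are the
biology and stay. The refit loops of the original analysis (dropping a bad
batch, zero-weighting a confounded cluster) are expressed as config-driven
reruns via `zero_weight_samples` and exclusion lists, not automated.
Replicates are removed after correction, keeping the first sample id per
replicate group.

Only the batch-mean-centred shifts are identifiable (the intercept absorbs
any common component), so parameter-recovery checks compare against
observed-batch-centred truth; with noise SD 0.1 and ~30 samples per batch
the per-gene estimate carries ~0.02–0.05 absolute error, and the acceptance
check is on the mean absolute error (\<= 0.05).

## 6. Consensus subtyping and PAC

`consensus_cluster()` re-implements subsampled consensus clustering (the
reference implementation is not available in this environment, and the
machinery is central here): per repetition, `ceiling(0.7 N)` samples without
replacement; Ward (`ward.D2`) clustering of `1 - Pearson r` distances on
mean-centred variable genes (variable = coefficient of variation more than
3 MADs above the median CV among complete genes); cut at every k in
2..maxK; consensus = co-clustering count over co-sampling count; final
assignment = Ward on `1 - M_k`. The recorded-parameter distance (`pearson`)
is the default even though the surrounding prose mentions cosine; both are
implemented and the discrepancy is documented rather than resolved. Genes
are never subsampled (pItem semantics); the ambiguity bounds (0.1, 0.9) for
the **PAC** (proportion of ambiguously clustered pairs) are the
conventional ones.

`select_k_pac()` returns the smallest k whose PAC is within `tol = 0.01` of
every larger k's; with cleanly separated subtypes the PAC curve drops to ~0
at the true k but bounces above `tol` for larger k (oversplitting a clean
cluster is ambiguous), so the documented fallback — argmin PAC with a
`no_plateau` flag — is the path that fires, and it returns the true k on
the synthetic compendium. Manual overrides and manual cluster merges
(`merge_clusters()`, audit-logged) mirror the original workflow's curation
steps.

## 7. Projection of new samples

`project_new_samples()` chains: QN onto the stored target → estimate and
subtract the new batch's per-gene coefficients → impute missing variable
genes by 15-NN cosine means against the final bulk matrix → subtract the
stored per-gene centring means → uwot out-of-sample transform. The
new-batch coefficient is the mean over new samples of
`y - mu - gamma(genotype)`; subtracting the intercept `mu` is our addition
(exposed as a switch) — without it the coefficient absorbs the global mean
and projection collapses. This step is also what removes the systematic
platform baseline of pseudo-bulk profiles, which is why new samples should
be projected as a batch spanning subtypes rather than one at a time.

The acceptance check reproduces the qualitative pattern that motivated the
original NEO-only re-clustering: pseudo-bulks of all cells (the fixture's
samples are ~60% stroma) land near chance, while neoplastic-only
pseudo-bulks recover \>= 80% nearest-centroid agreement with their truth
subtype.

## 8. Differential expression, gene sets, abundance

`fit_de()` is a blockwise linear-model with empirical-Bayes moderated t:
genes are grouped by missingness block and fitted by OLS against
`~ 0 + group (+ covariates)`; contrasts are formed over group levels
(one-vs-rest by default; a contrast touching a group absent from a gene's
block yields a flagged `NA`). Variance moderation pools all fitted genes:
prior df and (optionally expression-trended) prior variance come from the
classical moment-matching estimators via `limma::squeezeVar`; the moderated
t is `log2FC / (SE * s_tilde)` on `d0 + d_g` df. Setting `d0 = 0` recovers
the ordinary t exactly — asserted to 1e-10 — and the full path matches
`limma::eBayes(trend = TRUE)` on complete matrices, which serves as an
independent cross-check, never as the implementation. Pseudo-bulk DE runs
on TMM log2-CPM values (edgeR) with the limma-trend-style moderation rather
than count-level GLMs. BH adjustment is implemented from its definition and
oracle-checked. The ambient-RNA mitigations of the original analysis are
reduced to (i) an optional within-sample centering flag and (ii) a post-hoc
gene exclusion list; the full duplicate-correlation mixed model is out of
scope.

`geneset_scores()` is a mean-of-z single-sample score (z across samples,
mean over set genes) — a documented surrogate for rank-kernel enrichment:
for group-level comparisons of set activity, the mean-z is a valid
statistic, and that is all the pipeline asks of it.

`differential_abundance()` tests logit-transformed cell-type proportions
(half-count continuity correction) with equal-variance two-sample t-tests
per type (each-vs-rest beyond two groups) and BH across types.

## 9. The synthetic world

The generators state one fixed world; their defaults are not tuned to tests.

* **Bulk compendium** (`bulk_sim_config()`): 2,000 genes; subtypes C1A/C1B
  (pseudohypoxic) and C2A/C2B (kinase/Wnt-altered) with driver genotypes
  mapped as in the PCPG literature (SDHx → C1A, VHL/EPAS1 → C1B, RET/NF1/
  HRAS → C2A, MAML3 → C2B); 3 batches × 30 samples (two microarray-like,
  one RNA-seq-like with a monotone `2^(z/2)` platform warp so target-QN has
  real work to do); 50 disjoint DE genes per subtype at |log2FC| = 2 with
  random signs; per-gene additive batch shifts N(0, 0.5); 5–10% of genes
  missing per batch; residual noise SD 0.1; 10% unknown genotypes. Every
  tumor sample is admixed with a shared stromal profile at a fraction
  drawn from U(0.1, 0.4) — bulk tumors are never pure — which is also the
  main driver of residual batch-coefficient error.
* **Single-nuclei sample** (`sn_sim_config()`): 3,000 cells in 6 types (a
  neoplastic chromaffin-like "NEO" type, sustentacular/SCLC-like,
  endothelial, fibroblast, myeloid, T cells; T cells at half depth),
  NB counts with `variance = mu + mu^2/50` around depth-scaled type
  centroids (lognormal depth, median 15,000 — scaled so per-gene coverage
  over a 2,000-gene universe is comparable to real snRNA-seq over ~20,000
  genes), 40 disjoint 8x marker genes per type, 5% ambient contamination
  toward the dataset-mean rate vector, 6% doublets (rate-vector mixtures at
  1.5x depth, with simulated logistic doublet scores), 2% planted
  high-mito and 2% collapsed-depth QC outliers, and two CNV clones: a
  shared 250-gene chr1 0.5x deletion, plus a clone-specific 250-gene chr3
  1.5x gain (fractions 0.6/0.4 of neoplastic cells). Genes lie on 5
  synthetic chromosomes so planted segments exceed twice the 101-gene
  window.
* **Cohorts** (`simulate_sn_cohort()`) share one transcriptome structure
  (base rates, marker assignment, under a common structure seed) while the
  NEO centroid carries each sample's bulk-subtype DE signature — the link
  that makes pseudo-bulk projection meaningful.
* **Abundance counts** (`simulate_abundance_counts()`): Dirichlet-multinomial
  compositions (concentration 100, i.e. ~40% compositional CV for a 5%
  type) with a 3x enrichment of a 5% cell type in one group. The
  concentration was set a priori by power analysis: the logit effect log 3
  ≈ 1.1 against per-sample logit SD ~0.45 at n = 8 per group is detectable,
  while the compositional displacement of null types (~ -0.08) stays well
  inside the noise.

What a green suite does *not* establish: the generators draw independent
genes (no co-expression modules beyond the planted signatures), no
cell-cycle continuum, no ambient-RNA gene bias (ambient is type-mixture
only), no batch structure within the single-nuclei cohort, and platform
warps that are exactly monotone. Results on real data depend on departures
from all of these.

## 10. Numerical choices and degenerate inputs

* Quantile-normalization ties take the exact mean of their spanned
  quantiles (`ave` within tied groups), matching the definitional oracle
  used in tests.
* All seeds are explicit function arguments; derived sub-seeds stay below
  2^31. Stochastic steps (UMAP, Louvain, consensus subsampling, control-gene
  draws) are single-threaded and seeded.
* Degenerate inputs fail fast with classed conditions
  (`pcpg_validation_error`, `pcpg_format_error`, `pcpg_config_error`, ...),
  and every reader enforces its invariants (unique ids, coordinate sanity,
  per-batch missingness promotion).
* `fit_de` flags rather than drops: rank-deficient blocks and
  missing-group contrasts yield `NA` with a `flag` value.

## 11. Known limitations

* Pearson residuals with fixed theta under-shrink very highly expressed
  genes relative to a regularized per-gene NB fit.
* The windowed CNV core cannot see focal events shorter than about half a
  window, and clone-relative baselines (Section 4) make isolated arm calls
  on single-clone data hard to interpret.
* The moderated-t pipeline assumes approximately Gaussian log-scale
  expression within blocks; very small units (few nuclei) violate this.
* The mean-z gene-set score ignores gene-gene correlation within sets; its
  p-values are only as good as the group-level permutation structure of the
  design.
* Out-of-sample UMAP coordinates are an approximation: transform quality
  degrades for samples far from the training manifold, which is why the
  projection path estimates and removes new-batch structure first.
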