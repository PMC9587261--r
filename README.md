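# pcpgatlas

Pheochromocytoma and paraganglioma (PCPG) are rare neuroendocrine tumors of
chromaffin and paraganglial tissue whose expression subtypes (pseudohypoxic
C1 vs kinase/Wnt-altered C2, refined into finer groups) track driver
genotype and microenvironment. Profiling them at scale means combining two
awkward data worlds: single-nuclei RNA-seq of frozen tumors, and a bulk
compendium stitched together from many microarray and RNA-seq studies.

`pcpgatlas` is a tested, reusable R implementation of that combined
analysis, for computational biologists who want to run, audit, or extend
each stage:

* **Single-nuclei QC** — robust MAD-score filters on doublet scores,
  mitochondrial fraction, and (lineage-aware) total counts:
  `score = (x - median) / (1.4826 * MAD)`, with cutoffs 2 / 5 / −4
  (lymphoid) / −2.5 (other).
* **Normalization and clustering** — log-normalization, analytic Pearson
  residuals `(x − μ)/√(μ + μ²/θ)` as the variance-stabilizing transform,
  residual-variance HVG selection, PCA → SNN → Louvain, uwot UMAP.
* **Cell typing** — reference centroids (per-type means), Spearman-correlation
  classification over HVGs, cluster-majority collapse, and
  control-gene-matched module scores.
* **Copy-number inference** — the windowed-mean core of expression CNV:
  reference-centred `log2(1 + CPM/10)`, ±3 SD caps, 101-gene within-chromosome
  smoothing, per-cell median recentering; Ward subclones and arm-level calls.
* **Compendium harmonization** — probe collapse, quantile normalization with
  a microarray target distribution, and a per-gene weighted linear batch
  model `y = μ_g + β_batch + γ_genotype + ε` (sum-to-zero batches,
  zero-weighted unknown genotypes), fitted blockwise over gene×batch
  missingness.
* **Consensus subtyping** — subsampled Ward consensus clustering
  (pItem = 0.7, 1 − Pearson r distance) with PAC-based selection of the
  cluster number.
* **Projection** — out-of-sample placement of new (e.g. pseudo-bulk) samples:
  target-QN → new-batch coefficient removal → 15-NN cosine gene imputation →
  mean-centring → UMAP transform.
* **Differential expression and abundance** — blockwise OLS with
  empirical-Bayes moderated t (limma-trend style), BH adjustment, mean-z
  gene-set scores, logit-proportion abundance tests.
* **Cell–cell signaling** — ligand–receptor edge weights (mean ligand ×
  mean receptor expression per sample and type pair) with the >10-cell,
  0.1-detection-rate and 2-sample filters.

The study's raw patient data are restricted-access, so the package ships
seeded synthetic-data generators (`simulate_bulk_compendium()`,
`simulate_snrnaseq()`, `simulate_sn_cohort()`, ...) that state a fixed,
documented world with ground truth; every stage is exercised end-to-end on
them. See `vignettes/pcpgatlas-methods.Rmd` for the models, parameters and
design decisions.

## Worked example

```r
library(pcpgatlas)

# a synthetic multi-platform bulk compendium with 4 subtypes
bulk <- simulate_bulk_compendium(bulk_sim_config(seed = 1))
harm <- harmonize_compendium(bulk$bulk)
hvgs <- select_variable_genes_bulk(harm$bulk)

# consensus subtyping with PAC-based k selection
cr <- consensus_cluster(harm$bulk, genes = hvgs, reps = 100, maxK = 8, seed = 1)
(k <- select_k_pac(cr))
#> [1] 4
truth <- bulk$truth$samples
adjusted_rand_index(cr$assignments[, as.character(k)],
                    truth$subtype[match(rownames(cr$assignments),
                                        truth$sample_id)])
#> [1] 1

# single-nuclei sample: QC, typing
sn <- simulate_snrnaseq(sn_sim_config(seed = 1))
qc <- mad_filter_cells(sn$cm)
sum(qc$keep)
#> [1] 2499
```

The selected `k = 4` is the number of planted subtypes; the adjusted Rand
index of 1 means the consensus assignment reproduces the planted subtype
partition exactly. The QC step keeps 2,499 of 3,000 nuclei, removing the
simulated doublets, high-mitochondrial and collapsed-depth cells (plus a
small tail of legitimate cells near the count threshold).

A thin command-line wrapper over the same functions is installed at
`inst/cli/atlas.R` (subcommands `simulate`, `qc`, `classify`, `cnv`,
`harmonize`, `cluster`, `de`, `abundance`, `interactions`).

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end to end from scratch against
the installed package — simulate → harmonize → consensus subtype → embed →
single-nuclei QC/typing → CNV → pseudo-bulk projection → differential
expression/abundance → signaling edges — under a caller-supplied seed, and
writes its (empty) machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
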