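## High-level workflows composing the module operations end to end.

#' Harmonize a multi-platform bulk compendium
#'
#' The merging workflow: microarray batches are quantile-normalized
#' together and define the target distribution; RNA-seq-like batches
#' (including pseudo-bulk) are log-transformed (`log2(x + prior)`) and
#' quantile-normalized onto that target; the batch model is then fitted
#' (unknown-genotype samples at zero weight) and batch effects removed;
#' replicate samples are dropped last.
#'
#' @param bm A [bulk_matrix] whose metadata has `platform` and `genotype`.
#' @param log_rnaseq Log-transform RNA-seq-like batches before target
#'   normalization (default TRUE; set FALSE if they are already on log
#'   scale).
#' @param prior_count Prior for the RNA-seq log transform (default 0.5).
#' @param zero_weight_samples Extra samples to zero-weight in the model.
#' @return List: `bulk` (corrected [bulk_matrix]), `normalized`
#'   (pre-correction), `model` (`batch_model`), `target`
#'   (`quantile_target`).
#' @export
harmonize_compendium <- function(bm, log_rnaseq = TRUE, prior_count = 0.5,
                                 zero_weight_samples = character()) {
  stopifnot(inherits(bm, "bulk_matrix"))
  meta <- bm$sample_meta
  platform <- meta$platform %||% rep("microarray", nrow(meta))
  v <- bm$values
  is_array <- platform == "microarray"
  if (!any(is_array)) stop_validation("no microarray batch to define the target")
  v[, is_array] <- quantile_normalize(v[, is_array, drop = FALSE])
  target <- quantile_target(v[, is_array, drop = FALSE])
  if (any(!is_array)) {
    x <- v[, !is_array, drop = FALSE]
    if (log_rnaseq) x <- log2(x + prior_count)
    v[, !is_array] <- quantile_normalize_to_target(x, target)
  }
  normalized <- bulk_matrix(v, meta, promote_partial_missingness = FALSE)
  model <- fit_batch_model(normalized, zero_weight_samples = zero_weight_samples)
  corrected <- drop_replicates(remove_batch_effects(normalized, model))
  list(bulk = corrected, normalized = normalized, model = model, target = target)
}

#' Simulate a single-nuclei cohort linked to the bulk subtypes
#'
#' One snRNA-seq sample per requested subtype replicate: every sample shares
#' the cohort transcriptome structure (base rates, markers) but its
#' neoplastic cells carry the bulk subtype's DE signature, so pseudo-bulk
#' profiles are projectable into the bulk embedding.
#'
#' @param bulk_sim Output of [simulate_bulk_compendium()].
#' @param samples_per_subtype Replicates per subtype (default 2).
#' @param cells_scale Multiplier on the default per-type cell counts
#'   (default 1).
#' @param seed Base seed; per-sample seeds are derived from it.
#' @param ... Further arguments to [sn_sim_config()].
#' @return List: `sims` (list of [simulate_snrnaseq()] outputs, named by
#'   sample id), `samples` (tibble `sample_id`, `subtype`).
#' @export
simulate_sn_cohort <- function(bulk_sim, samples_per_subtype = 2,
                               cells_scale = 1, seed = 1, ...) {
  de <- bulk_sim$truth$de_genes
  subtypes <- unique(de$subtype)
  types <- default_sn_cell_types()
  types$n_cells <- as.integer(ceiling(types$n_cells * cells_scale))
  grid <- tidyr::expand_grid(subtype = subtypes,
                             rep = seq_len(samples_per_subtype))
  sims <- vector("list", nrow(grid))
  ids <- sprintf("sn_%s_%d", grid$subtype, grid$rep)
  for (i in seq_len(nrow(grid))) {
    cfg <- sn_sim_config(
      n_genes = length(bulk_sim$truth$base_mu),
      cell_types = types,
      subtype_de = de[de$subtype == grid$subtype[i],
                      c("gene_idx", "sign", "log2fc")],
      reserved_gene_idx = unique(de$gene_idx),
      sample_id = ids[i],
      seed = derive_seed(seed, i),
      structure_seed = derive_seed(seed, 0L),
      ...)
    sims[[i]] <- simulate_snrnaseq(cfg)
  }
  names(sims) <- ids
  list(sims = sims,
       samples = tibble(sample_id = ids, subtype = grid$subtype))
}

#' Pseudo-bulk expression matrix of a single-nuclei cohort
#'
#' Per sample, counts are summed over all cells or over neoplastic cells
#' only (using simulation truth or a supplied assignment), then TMM
#' log2-CPM normalized — the expression matrix handed to
#' [project_new_samples()].
#'
#' @param cohort Output of [simulate_sn_cohort()] (or a named list of
#'   [simulate_snrnaseq()] outputs).
#' @param cells `"all"` or `"neo"` (neoplastic truth cells only).
#' @param neoplastic_type Type treated as neoplastic (default "NEO").
#' @param exclude_doublets Drop truth doublets before summing (default
#'   TRUE).
#' @return Genes-by-samples matrix of log2 CPM values.
#' @export
cohort_pseudobulk <- function(cohort, cells = c("all", "neo"),
                              neoplastic_type = "NEO",
                              exclude_doublets = TRUE) {
  cells <- match.arg(cells)
  sims <- if (!is.null(cohort$sims)) cohort$sims else cohort
  counts <- vapply(sims, function(sim) {
    truth <- sim$truth$cells
    keep <- if (exclude_doublets) !truth$is_doublet else rep(TRUE, nrow(truth))
    if (cells == "neo") keep <- keep & truth$cell_type == neoplastic_type
    as.numeric(Matrix::rowSums(sim$cm$counts[, keep, drop = FALSE]))
  }, numeric(nrow(sims[[1L]]$cm$counts)))
  rownames(counts) <- rownames(sims[[1L]]$cm$counts)
  tmm_log2cpm(counts)
}

#' Assign embedded samples to the nearest training-subtype centroid
#'
#' Training samples' 2-D coordinates are averaged per label; each query
#' point gets the label of its nearest centroid (Euclidean).
#'
#' @param coords Query coordinates (matrix or tibble with `umap_1`,
#'   `umap_2`).
#' @param training_embedding Training samples-by-2 coordinates.
#' @param training_labels Per-training-sample labels.
#' @return Character vector of assigned labels.
#' @export
nearest_embedding_centroid <- function(coords, training_embedding,
                                       training_labels) {
  if (is.data.frame(coords))
    coords <- as.matrix(coords[, c("umap_1", "umap_2")])
  cent <- rowsum(as.matrix(training_embedding), training_labels) /
    as.vector(table(training_labels)[sort(unique(training_labels))])
  d2 <- outer(rowSums(coords^2), rowSums(cent^2), "+") -
    2 * tcrossprod(coords, cent)
  rownames(cent)[apply(d2, 1L, which.min)]
}
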