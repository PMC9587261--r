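#' Fit the bulk-compendium UMAP embedding bundle
#'
#' Fits a 2-D UMAP on the mean-centred variable-gene submatrix of the
#' harmonized compendium and packages everything needed to project new
#' samples later: the fitted model, the gene list, the per-gene centring
#' means, the final expression matrix (for kNN imputation), the quantile
#' target and the batch model.
#'
#' @param bm Harmonized [bulk_matrix] (post batch correction).
#' @param genes Variable genes (must be complete across samples).
#' @param batch_model The fitted `batch_model` of the compendium.
#' @param target The `quantile_target` used during harmonization.
#' @param n_neighbors,min_dist,metric,n_epochs UMAP parameters (defaults 15,
#'   0.1, cosine, 1000).
#' @param seed RNG seed.
#' @return An `embedding_bundle` with element `embedding` (samples-by-2).
#' @export
fit_bulk_embedding <- function(bm, genes, batch_model = NULL, target = NULL,
                               n_neighbors = 15, min_dist = 0.1,
                               metric = "cosine", n_epochs = 1000, seed = 42) {
  v <- if (inherits(bm, "bulk_matrix")) bm$values else as.matrix(bm)
  genes <- intersect(genes, rownames(v))
  if (length(genes) < 2L) stop_validation("need at least 2 embedding genes")
  x <- v[genes, , drop = FALSE]
  if (anyNA(x)) stop_validation("embedding genes must be complete across samples")
  if (ncol(x) < n_neighbors + 1L) stop_validation("need more samples than n_neighbors")
  gene_means <- rowMeans(x)
  xc <- t(x - gene_means)                              # samples x genes
  model <- withr::with_seed(seed,
    uwot::umap(xc, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = metric, n_epochs = n_epochs, ret_model = TRUE,
               n_threads = 1, n_sgd_threads = 0))
  emb <- model$embedding
  rownames(emb) <- colnames(x)
  colnames(emb) <- c("umap_1", "umap_2")
  structure(list(model = model, embedding = emb, genes = genes,
                 gene_means = gene_means, reference_values = x,
                 batch_model = batch_model, target = target,
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               metric = metric, n_epochs = n_epochs,
                               seed = seed)),
            class = "embedding_bundle")
}

#' @export
print.embedding_bundle <- function(x, ...) {
  cat(sprintf("<embedding_bundle> %d training samples, %d genes, metric '%s'\n",
              nrow(x$embedding), length(x$genes), x$params$metric))
  invisible(x)
}

#' Estimate batch coefficients for a new batch of samples
#'
#' For projection of samples from a batch the model never saw: per gene,
#' the new batch coefficient is the mean over new samples of the expression
#' value minus the model intercept and the genotype coefficient of each
#' sample's genotype. Samples with unknown genotype contribute a zero
#' genotype term (flagged). Genes unfit in the model get `NA` (excluded
#' downstream).
#'
#' @param new_samples Genes-by-samples matrix (or [bulk_matrix]),
#'   quantile-normalized to the model's target scale.
#' @param model A `batch_model`.
#' @param genotypes Per-sample genotype character vector (NA = unknown);
#'   taken from metadata when `new_samples` is a [bulk_matrix].
#' @param subtract_intercept Subtract the per-gene intercept (default TRUE;
#'   without it the coefficient absorbs the global mean and projection
#'   collapses).
#' @return Named per-gene coefficient vector with attribute
#'   `unknown_genotype` (count).
#' @export
estimate_new_batch_coefficients <- function(new_samples, model, genotypes = NULL,
                                            subtract_intercept = TRUE) {
  v <- if (inherits(new_samples, "bulk_matrix")) {
    genotypes <- genotypes %||% new_samples$sample_meta$genotype
    new_samples$values
  } else as.matrix(new_samples)
  genes <- intersect(rownames(v), names(model$mu)[!is.na(model$mu)])
  if (!length(genes)) stop_validation("no gene overlap with the batch model")
  if (is.null(genotypes)) genotypes <- rep(NA_character_, ncol(v))
  gmat <- matrix(0, length(genes), ncol(v))
  known <- !is.na(genotypes) & genotypes %in% colnames(model$gamma)
  for (s in which(known)) gmat[, s] <- model$gamma[genes, genotypes[s]]
  resid <- v[genes, , drop = FALSE] - gmat
  if (subtract_intercept) resid <- resid - model$mu[genes]
  beta_new <- rowMeans(resid, na.rm = TRUE)
  beta_new[is.nan(beta_new)] <- NA_real_
  structure(setNames(beta_new, genes), unknown_genotype = sum(!known))
}

#' k-nearest-neighbour imputation of missing genes
#'
#' For each new sample, neighbours among the reference samples are found by
#' cosine distance over the variable genes observed in both; each missing
#' variable gene is filled with the mean of the k neighbours' values.
#'
#' @param new_samples Genes-by-samples matrix (NA = missing).
#' @param reference Genes-by-samples complete reference matrix (the final
#'   bulk expression matrix).
#' @param hvgs Variable genes to consider (default: reference rownames).
#' @param k Neighbours (default 15; shrunk with a warning when the reference
#'   is smaller).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param min_shared Minimum shared observed genes per sample (default 100).
#' @return The new-sample matrix restricted to `hvgs` with missing entries
#'   imputed.
#' @export
knn_impute_genes <- function(new_samples, reference, hvgs = NULL, k = 15,
                             metric = "cosine", min_shared = 100) {
  reference <- as.matrix(reference)
  hvgs <- hvgs %||% rownames(reference)
  ref <- reference[intersect(hvgs, rownames(reference)), , drop = FALSE]
  if (k > ncol(ref)) {
    warn(sprintf("k = %d exceeds %d reference samples; shrunk", k, ncol(ref)))
    k <- ncol(ref)
  }
  new_samples <- as.matrix(new_samples)
  out <- matrix(NA_real_, nrow(ref), ncol(new_samples),
                dimnames = list(rownames(ref), colnames(new_samples)))
  common <- intersect(rownames(ref), rownames(new_samples))
  out[common, ] <- new_samples[common, , drop = FALSE]
  for (s in seq_len(ncol(out))) {
    obs <- rownames(ref)[!is.na(out[, s])]
    if (length(obs) < min_shared)
      stop_validation(sprintf("sample %d shares only %d observed variable genes",
                              s, length(obs)))
    miss <- is.na(out[, s])
    if (!any(miss)) next
    nn <- knn_index(matrix(out[obs, s], nrow = 1L), t(ref[obs, , drop = FALSE]),
                    k = k, metric = metric, self = TRUE)
    out[miss, s] <- rowMeans(ref[miss, nn[1L, ], drop = FALSE])
  }
  out
}

#' Project new samples into the bulk embedding
#'
#' The out-of-sample path: quantile-normalize each new sample to the
#' bundle's target distribution, estimate and subtract the new batch's
#' per-gene coefficients, impute missing variable genes by kNN against the
#' final bulk matrix, subtract the bundle's per-gene centring means, and run
#' the UMAP out-of-sample transform.
#'
#' @param new_samples Genes-by-samples matrix or [bulk_matrix] (log-scale
#'   expression; NA = missing).
#' @param bundle An `embedding_bundle` with `batch_model` and `target`.
#' @param genotypes Optional per-sample genotypes (NA = unknown).
#' @param seed RNG seed for the transform.
#' @return Tibble `sample_id`, `umap_1`, `umap_2` with diagnostics attribute
#'   (`imputed_genes`, `batch_coef_norm`, `unknown_genotype`).
#' @export
project_new_samples <- function(new_samples, bundle, genotypes = NULL, seed = 42) {
  stopifnot(inherits(bundle, "embedding_bundle"))
  v <- if (inherits(new_samples, "bulk_matrix")) {
    genotypes <- genotypes %||% new_samples$sample_meta$genotype
    new_samples$values
  } else as.matrix(new_samples)
  if (!is.null(bundle$target)) v <- quantile_normalize_to_target(v, bundle$target)
  beta_new <- NULL
  if (!is.null(bundle$batch_model)) {
    beta_new <- estimate_new_batch_coefficients(v, bundle$batch_model,
                                                genotypes = genotypes)
    genes <- names(beta_new)[!is.na(beta_new)]
    v[genes, ] <- v[genes, , drop = FALSE] - beta_new[genes]
  }
  n_missing <- sum(is.na(v[intersect(bundle$genes, rownames(v)), , drop = FALSE])) +
    length(setdiff(bundle$genes, rownames(v))) * ncol(v)
  x <- knn_impute_genes(v, bundle$reference_values, hvgs = bundle$genes,
                        k = bundle$params$n_neighbors,
                        metric = bundle$params$metric)
  xc <- t(x - bundle$gene_means)
  coords <- withr::with_seed(seed,
    uwot::umap_transform(xc, bundle$model, n_threads = 1, n_sgd_threads = 0))
  out <- tibble(sample_id = colnames(x) %||% as.character(seq_len(nrow(xc))),
                umap_1 = coords[, 1L], umap_2 = coords[, 2L])
  attr(out, "diagnostics") <- list(
    imputed_genes = n_missing,
    batch_coef_norm = if (!is.null(beta_new)) sqrt(mean(beta_new^2, na.rm = TRUE)) else NA_real_,
    unknown_genotype = if (!is.null(beta_new)) attr(beta_new, "unknown_genotype") else NA_integer_)
  out
}
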