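#' PCA embedding of cells
#'
#' PCA on the gene-standardized (centred, unit-variance) submatrix of the
#' selected genes, cells as observations. PCs are ordered by decreasing
#' explained variance; sign convention: the largest-magnitude gene loading of
#' each PC is positive.
#'
#' @param nm A `normalized_matrix` (or genes-by-cells numeric matrix).
#' @param genes Genes to use (default: all rows).
#' @param n_pcs Number of components (default 20); truncated with a warning
#'   if above the matrix rank.
#' @return Cells-by-PCs matrix with attributes `explained_variance` and
#'   `loadings`.
#' @export
pca_embed <- function(nm, genes = NULL, n_pcs = 20) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  v <- as.matrix(v)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(v))
    v <- v[genes, , drop = FALSE]
  }
  x <- t(v)                                   # cells x genes
  sds <- apply(x, 2L, sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-10)
  if (n_pcs > rank) {
    warn(sprintf("n_pcs = %d exceeds rank %d; truncated", n_pcs, rank))
    n_pcs <- rank
  }
  keep <- seq_len(n_pcs)
  rot <- pc$rotation[, keep, drop = FALSE]
  emb <- pc$x[, keep, drop = FALSE]
  ## sign convention
  for (j in keep) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; emb[, j] <- -emb[, j] }
  }
  rownames(emb) <- colnames(v)
  structure(emb,
            explained_variance = pc$sdev[keep]^2 / sum(pc$sdev^2),
            loadings = rot)
}

snn_graph <- function(pcs, k_neighbors = 20, metric = "cosine", prune = 1 / 15) {
  n <- nrow(pcs)
  if (n < k_neighbors + 1L)
    stop_validation("fewer cells than k_neighbors + 1")
  idx <- knn_index(pcs, pcs, k = k_neighbors, metric = metric, self = FALSE)
  ## adjacency including self, then Jaccard of neighbourhoods
  i <- rep(seq_len(n), each = ncol(idx) + 1L)
  j <- as.integer(t(cbind(seq_len(n), idx)))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  ksz <- k_neighbors + 1L
  shared <- as(shared, "TsparseMatrix")
  jac <- shared@x / (2 * ksz - shared@x)
  keep <- jac >= prune & shared@i < shared@j
  igraph::graph_from_data_frame(
    data.frame(from = shared@i[keep] + 1L, to = shared@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' Graph-based clustering of cells
#'
#' Shared-nearest-neighbour graph (Jaccard edge weights over k-nearest
#' neighbourhoods, cosine metric by default) followed by Louvain modularity
#' optimization at the given resolution. Deterministic given `seed`.
#'
#' @param pcs Cells-by-PCs matrix (from [pca_embed()]).
#' @param k_neighbors Neighbours per cell (default 20).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed (default 0).
#' @return Tibble with `cell`, `cluster` (integer factor) and an attribute
#'   `params`.
#' @export
cluster_cells <- function(pcs, k_neighbors = 20, metric = "cosine",
                          resolution = 0.8, seed = 0) {
  g <- snn_graph(pcs, k_neighbors = k_neighbors, metric = metric)
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  member <- igraph::membership(cl)
  out <- tibble(cell = rownames(pcs) %||% as.character(seq_len(nrow(pcs))),
                cluster = as.integer(member))
  attr(out, "params") <- list(k_neighbors = k_neighbors, metric = metric,
                              resolution = resolution, seed = seed)
  out
}

#' UMAP embedding of cells
#'
#' Thin wrapper around `uwot::umap` with the pipeline's defaults (cosine
#' metric, 20 neighbours); deterministic given `seed` (single-threaded SGD).
#'
#' @param pcs Cells-by-PCs matrix.
#' @param n_neighbors Neighbours (default 20).
#' @param metric Distance metric (default `"cosine"`).
#' @param seed RNG seed.
#' @param ... Passed on to `uwot::umap`.
#' @return Cells-by-2 coordinate matrix.
#' @export
umap_embed <- function(pcs, n_neighbors = 20, metric = "cosine", seed = 42, ...) {
  if (nrow(pcs) < n_neighbors + 1L)
    stop_validation("fewer rows than n_neighbors + 1")
  emb <- withr::with_seed(seed,
    uwot::umap(pcs, n_neighbors = n_neighbors, metric = metric,
               n_threads = 1, n_sgd_threads = 0, ...))
  rownames(emb) <- rownames(pcs)
  colnames(emb) <- c("umap_1", "umap_2")
  emb
}
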