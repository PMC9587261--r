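#' Collapse a labelled reference to per-type expression centroids
#'
#' `centroid(g, t)` is the mean log-normalized expression of gene `g` over
#' reference cells labelled `t`.
#'
#' @param ref_matrix Genes-by-cells matrix of log-normalized reference
#'   expression (or a `normalized_matrix`).
#' @param ref_labels Character labels, one per reference cell.
#' @return Genes-by-types numeric matrix of class `reference_centroids`.
#' @export
build_centroids <- function(ref_matrix, ref_labels) {
  v <- if (inherits(ref_matrix, "normalized_matrix")) ref_matrix$values else ref_matrix
  v <- as.matrix(v)
  if (length(ref_labels) != ncol(v))
    stop_validation("one label per reference cell required")
  if (any(is.na(ref_labels))) stop_validation("reference labels must be complete")
  types <- sort(unique(ref_labels))
  empty <- types[!types %in% ref_labels]
  if (length(empty)) stop_validation("label level(s) with zero cells")
  cent <- vapply(types, function(t) rowMeans(v[, ref_labels == t, drop = FALSE]),
                 numeric(nrow(v)))
  rownames(cent) <- rownames(v)
  structure(cent, class = c("reference_centroids", class(cent)))
}

#' Classify cells against reference centroids by Spearman correlation
#'
#' Each cell is scored against every centroid by Spearman rank correlation
#' over the intersection of the supplied highly variable genes with both gene
#' universes; the best-correlated type wins (ties broken alphabetically, with
#' a tie flag). Rank correlation makes the classification invariant to any
#' strictly monotone per-cell transform of expression.
#'
#' @param expr Genes-by-cells matrix of log-normalized expression (or
#'   `normalized_matrix`).
#' @param centroids Genes-by-types centroid matrix ([build_centroids()]).
#' @param hvgs Genes to correlate over; the three-way intersection must hold
#'   at least `min_overlap` genes.
#' @param min_overlap Minimum usable gene overlap (default 50).
#' @return Tibble: `cell`, `best_type`, `best_correlation`, `margin`
#'   (runner-up gap), `tie`; the full correlation matrix is attached as the
#'   `correlations` attribute.
#' @export
classify_cells <- function(expr, centroids, hvgs = NULL, min_overlap = 50) {
  v <- if (inherits(expr, "normalized_matrix")) expr$values else expr
  v <- as.matrix(v)
  centroids <- centroids[, order(colnames(centroids)), drop = FALSE]
  hvgs <- hvgs %||% rownames(v)
  genes <- intersect(intersect(hvgs, rownames(v)), rownames(centroids))
  if (length(genes) < min_overlap)
    stop_validation(sprintf("gene overlap %d below required %d",
                            length(genes), min_overlap))
  rho <- suppressWarnings(
    cor(v[genes, , drop = FALSE], centroids[genes, , drop = FALSE],
        method = "spearman"))
  rho[is.na(rho)] <- -1
  best <- apply(rho, 1L, function(r) {
    top <- which(r == max(r))
    top[1L]                                  # columns sorted; alphabetical tiebreak
  })
  tie <- apply(rho, 1L, function(r) sum(r == max(r)) > 1L)
  margin <- apply(rho, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (length(s) > 1L) s[1L] - s[2L] else NA_real_
  })
  out <- tibble(cell = colnames(v),
                best_type = colnames(rho)[best],
                best_correlation = rho[cbind(seq_len(nrow(rho)), best)],
                margin = margin, tie = tie)
  attr(out, "correlations") <- rho
  out
}

#' Collapse per-cell type calls to one label per cluster
#'
#' Cluster label = mode of member cell labels; ties are broken in favour of
#' the tied label with the higher mean best-correlation. Clusters whose mean
#' best-correlation falls below `unassigned_floor` are labelled
#' `"unassigned"` rather than forced onto a reference type.
#'
#' @param assignment Tibble from [classify_cells()].
#' @param clusters Tibble from [cluster_cells()] (or vector of cluster ids
#'   aligned with `assignment`).
#' @param unassigned_floor Correlation floor (default 0.2); `-Inf` disables.
#' @return Tibble: `cluster`, `label`, `majority_fraction`,
#'   `mean_correlation`, `n_cells`.
#' @export
majority_vote_clusters <- function(assignment, clusters, unassigned_floor = 0.2) {
  cl <- if (is.data.frame(clusters)) {
    m <- match(assignment$cell, clusters$cell)
    if (anyNA(m)) stop_validation("every cell needs a cluster")
    clusters$cluster[m]
  } else clusters
  df <- mutate(assignment, cluster = cl)
  summarise(group_by(df, .data$cluster),
            label = {
              tab <- table(.data$best_type)
              top <- names(tab)[tab == max(tab)]
              if (length(top) > 1L) {
                mc <- vapply(top, function(t)
                  mean(.data$best_correlation[.data$best_type == t]), 0)
                top <- top[which.max(mc)]
              }
              top
            },
            majority_fraction = max(table(.data$best_type)) / dplyr::n(),
            mean_correlation = mean(.data$best_correlation),
            n_cells = dplyr::n(), .groups = "drop") |>
    mutate(label = ifelse(.data$mean_correlation < unassigned_floor,
                          "unassigned", .data$label))
}

#' Gene-module score with expression-matched control genes
#'
#' Scores each cell by the average expression of a gene set minus the
#' average expression of control genes sampled from the same
#' average-expression bins: genes are cut into `n_bins` equal-frequency bins
#' of mean expression; each set gene contributes `n_ctrl` control genes drawn
#' from its bin (with replacement if the bin is small), excluding set genes.
#'
#' @param nm A `normalized_matrix` (or genes-by-cells matrix).
#' @param gene_set Character vector of gene ids (or a named list of sets).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return Tibble `cell`, one score column per gene set.
#' @export
module_score <- function(nm, gene_set, n_bins = 24, n_ctrl = 100, seed = 0) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values else nm
  v <- as.matrix(v)
  sets <- if (is.list(gene_set)) gene_set else list(score = gene_set)
  avg <- rowMeans(v)
  ## equal-frequency bins on mean expression
  br <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1L)))
  bins <- if (length(br) < 2L) rep(1L, length(avg))
          else cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- tibble(cell = colnames(v))
  for (nm_set in names(sets)) {
    genes <- intersect(sets[[nm_set]], rownames(v))
    if (!length(genes))
      stop_validation(sprintf("gene set '%s' has no genes in the matrix", nm_set))
    ctrl <- withr::with_seed(derive_seed(seed, match(nm_set, names(sets))), {
      unlist(lapply(genes, function(g) {
        pool <- rownames(v)[bins == bins[match(g, rownames(v))]]
        pool <- setdiff(pool, genes)
        if (!length(pool)) return(character())
        sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
      }))
    })
    set_mean <- colMeans(v[genes, , drop = FALSE])
    ctrl_mean <- if (length(ctrl)) colMeans(v[ctrl, , drop = FALSE]) else 0
    out[[nm_set]] <- set_mean - ctrl_mean
  }
  out
}
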