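#' Select variable genes of the bulk compendium
#'
#' Among the genes with no missing values across all samples, the
#' coefficient of variation `CV = SD / |mean|` is computed and genes with
#' `CV > median(CV) + mad_multiplier * MAD(CV)` (MAD with the 1.4826
#' constant) are selected.
#'
#' @param bm A [bulk_matrix] (or genes-by-samples matrix).
#' @param mad_multiplier Outlierness multiplier (default 3).
#' @return Character vector of gene ids.
#' @export
select_variable_genes_bulk <- function(bm, mad_multiplier = 3) {
  v <- if (inherits(bm, "bulk_matrix")) bm$values else as.matrix(bm)
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete)) stop_validation("no genes complete across all samples")
  vc <- v[complete, , drop = FALSE]
  cv <- apply(vc, 1L, sd) / abs(rowMeans(vc))
  cutoff <- median(cv) + mad_multiplier * mad(cv)   # mad() uses 1.4826
  names(cv)[cv > cutoff]
}

consensus_distance <- function(x, distance) {
  ## columns of x are samples
  switch(distance,
    pearson = as.dist(1 - cor(x, use = "pairwise.complete.obs")),
    cosine = as.dist(cosine_distance(t(x))),
    euclidean = dist(t(x)),
    stop_parameter(sprintf("unknown distance '%s'", distance))
  )
}

#' Consensus clustering with subsampling
#'
#' For each of `reps` repetitions, `ceiling(pItem * N)` samples are drawn
#' without replacement, hierarchically clustered (Ward linkage on
#' 1 - Pearson correlation by default) and cut at every `k` in `2..maxK`.
#' The consensus matrix `M_k(i,j)` is the fraction of co-clustering events
#' among co-sampling events; the final assignment at each `k` is Ward
#' clustering of `1 - M_k` cut at `k`. The PAC (proportion of ambiguously
#' clustered pairs) is the fraction of off-diagonal consensus entries
#' strictly inside `(lower, upper)`.
#'
#' Gene values are mean-centred per gene before clustering.
#'
#' @param bm A [bulk_matrix] or genes-by-samples matrix.
#' @param genes Genes to cluster on (default: all).
#' @param pItem Subsampling fraction (default 0.7).
#' @param reps Repetitions (default 1000).
#' @param maxK Largest k (default 12).
#' @param distance `"pearson"` (default, the recorded parameter), `"cosine"`
#'   or `"euclidean"`.
#' @param linkage Hierarchical linkage (default `"ward.D2"`).
#' @param pac_bounds Ambiguity bounds (default `c(0.1, 0.9)`).
#' @param seed RNG seed.
#' @return A `consensus_result`: list with `consensus` (list of matrices by
#'   k), `assignments` (samples-by-k matrix), `pac` (named vector), and
#'   `params`.
#' @export
consensus_cluster <- function(bm, genes = NULL, pItem = 0.7, reps = 1000,
                              maxK = 12, distance = "pearson",
                              linkage = "ward.D2", pac_bounds = c(0.1, 0.9),
                              seed = 1) {
  v <- if (inherits(bm, "bulk_matrix")) bm$values else as.matrix(bm)
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  n <- ncol(v)
  if (n < maxK + 2L) stop_validation("need at least maxK + 2 samples")
  n_sub <- ceiling(pItem * n)
  if (n_sub < maxK) stop_parameter("pItem * N below maxK")
  v <- v - rowMeans(v, na.rm = TRUE)                # mean-centre per gene
  ks <- 2:maxK
  conn <- lapply(ks, function(k) matrix(0, n, n))
  names(conn) <- ks
  cosample <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      d <- consensus_distance(v[, idx, drop = FALSE], distance)
      hc <- hclust(d, method = linkage)
      cosample[idx, idx] <- cosample[idx, idx] + 1
      for (ki in seq_along(ks)) {
        cl <- cutree(hc, k = ks[ki])
        co <- outer(cl, cl, "==") * 1
        conn[[ki]][idx, idx] <- conn[[ki]][idx, idx] + co
      }
    }
  })
  samples <- colnames(v) %||% as.character(seq_len(n))
  consensus <- lapply(conn, function(m) {
    M <- ifelse(cosample > 0, m / pmax(cosample, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(samples, samples)
    M
  })
  assignments <- vapply(seq_along(ks), function(ki) {
    hc <- hclust(as.dist(1 - consensus[[ki]]), method = linkage)
    cutree(hc, k = ks[ki])
  }, integer(n))
  dimnames(assignments) <- list(samples, ks)
  off <- upper.tri(consensus[[1L]])
  pac <- vapply(consensus, function(M)
    mean(M[off] > pac_bounds[1L] & M[off] < pac_bounds[2L]), 0)
  names(pac) <- ks
  structure(list(consensus = consensus, assignments = assignments, pac = pac,
                 params = list(pItem = pItem, reps = reps, maxK = maxK,
                               distance = distance, linkage = linkage,
                               pac_bounds = pac_bounds, seed = seed,
                               genes = rownames(v))),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d samples, k = 2..%d, reps = %d\n",
              nrow(x$assignments), x$params$maxK, x$params$reps))
  cat("PAC:", paste(sprintf("k%s=%.3f", names(x$pac), x$pac), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of clusters from the PAC curve
#'
#' Returns the smallest `k` whose PAC differs by less than `tol` from the
#' PAC at every larger `k` (the point where the proportion of ambiguously
#' clustered pairs stops changing). If no such plateau exists the `k` with
#' minimal PAC is returned with a `no_plateau` flag. A manual override wins
#' when given.
#'
#' @param cr A `consensus_result`.
#' @param tol Plateau tolerance (default 0.01).
#' @param override Optional manually chosen k.
#' @return Integer k with attribute `no_plateau`.
#' @export
select_k_pac <- function(cr, tol = 0.01, override = NULL) {
  if (!is.null(override)) return(structure(as.integer(override), no_plateau = FALSE))
  pac <- cr$pac
  ks <- as.integer(names(pac))
  for (i in seq_along(ks)) {
    later <- pac[seq_along(ks) > i]
    if (!length(later)) break
    if (all(abs(pac[i] - later) < tol))
      return(structure(ks[i], no_plateau = FALSE))
  }
  structure(ks[which.min(pac)], no_plateau = TRUE)
}

#' Merge clusters manually
#'
#' Relabels an assignment according to a list of cluster-id groups to merge
#' (mirroring manual merges justified by embedding proximity); labels are
#' canonically relabelled to consecutive integers and the merge is recorded
#' in an `audit` attribute.
#'
#' @param assignment Integer cluster labels (vector, possibly named).
#' @param merge_spec List of integer vectors, each a group of cluster ids to
#'   merge.
#' @return Relabelled integer vector with an `audit` attribute.
#' @export
merge_clusters <- function(assignment, merge_spec = list()) {
  labs <- as.integer(assignment)
  for (grp in merge_spec) {
    if (!all(grp %in% labs)) stop_validation("unknown cluster id in merge_spec")
    labs[labs %in% grp] <- min(grp)
  }
  relab <- as.integer(factor(labs, levels = sort(unique(labs))))
  names(relab) <- names(assignment)
  structure(relab, audit = list(merged = merge_spec, time = Sys.time()))
}
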