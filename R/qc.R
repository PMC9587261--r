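#' Robust MAD score
#'
#' `(x - median(x)) / (1.4826 * median(|x - median(x)|))`, the robust z-score
#' used throughout the single-nuclei QC stage. The 1.4826 consistency
#' constant makes the MAD estimate the normal SD under normality.
#'
#' If the MAD is zero the score is degenerate. The default behaviour returns
#' all zeros and sets a `degenerate` attribute; `fallback = "meanad"`
#' rescales by the mean absolute deviation instead (consistency constant
#' `sqrt(pi/2)` = 1.2533), which the QC filters use so that gross outliers in
#' otherwise constant score vectors are still caught.
#'
#' @param x Numeric vector, length >= 2.
#' @param fallback `"zeros"` (contract default) or `"meanad"`.
#' @return Numeric vector of scores with logical attribute `degenerate`.
#' @export
mad_score <- function(x, fallback = c("zeros", "meanad")) {
  fallback <- match.arg(fallback)
  if (length(x) < 2L) stop_validation("mad_score needs at least 2 values")
  med <- median(x)
  dev <- x - med
  s <- 1.4826 * median(abs(dev))
  degenerate <- FALSE
  if (s == 0) {
    degenerate <- TRUE
    if (fallback == "meanad") s <- sqrt(pi / 2) * mean(abs(dev))
    if (s == 0) return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  structure(dev / s, degenerate = degenerate)
}

#' Doublet-score filter
#'
#' Cells whose MAD-normalized doublet score is an extreme outlier are flagged
#' as doublets. The default removes high-score outliers (MAD score >=
#' `cutoff`). The source protocol's wording ("removed ... with MAD values
#' <2") literally removes low-score cells, which contradicts doublet
#' detection logic; the direction is therefore exposed as a switch.
#'
#' @param scores Per-cell raw doublet scores.
#' @param cutoff MAD-score cutoff (default 2).
#' @param direction `"high"` removes cells with score >= cutoff (default);
#'   `"low"` removes cells with score < cutoff (the literal reading).
#' @return Logical keep mask (TRUE = keep).
#' @export
filter_doublets <- function(scores, cutoff = 2, direction = c("high", "low")) {
  direction <- match.arg(direction)
  z <- mad_score(scores, fallback = "meanad")
  if (direction == "high") z < cutoff else z >= cutoff
}

#' Per-cell QC filtering on doublet score, mitochondrial fraction and counts
#'
#' Mito criterion: MAD score of mito fraction <= `mito_mad_cutoff` (default
#' 5). Count criterion on natural-log total counts, lower-tail: MAD score >=
#' -4 for lymphoid lineages (B, T, mast, NK cells) and >= -2.5 otherwise —
#' lymphoid nuclei genuinely carry less RNA, so they get the more permissive
#' floor. Doublet criterion as in [filter_doublets()]. The final keep flag is
#' the conjunction of the three criteria.
#'
#' @param cm A [count_matrix] whose `cell_meta` has `doublet_score`,
#'   `mito_fraction` and `total_counts`.
#' @param labels Optional per-cell lineage labels (character, one per cell);
#'   unlabeled cells are treated as "other". Defaults to
#'   `cell_meta$lineage_label` when present.
#' @param thresholds List overriding the defaults (see
#'   `atlas_defaults()$sn_qc$mad_filter`).
#' @return A tibble QC report, one row per barcode: MAD scores, per-criterion
#'   pass flags, and `keep`.
#' @export
mad_filter_cells <- function(cm, labels = NULL, thresholds = list()) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) == 0L) stop_validation("empty count matrix")
  th <- modifyList(atlas_defaults()$sn_qc$mad_filter, thresholds)
  meta <- cm$cell_meta
  if (is.null(labels))
    labels <- if ("lineage_label" %in% names(meta)) meta$lineage_label
              else rep(NA_character_, nrow(meta))
  labels[is.na(labels)] <- "other"
  if (length(labels) != nrow(meta))
    stop_validation("labels must have one entry per cell")
  lymphoid <- labels %in% th$lymphoid_labels

  doublet_mad <- mad_score(meta$doublet_score, fallback = "meanad")
  pass_doublet <- if (th$doublet_direction == "high")
    doublet_mad < th$doublet_mad_cutoff else doublet_mad >= th$doublet_mad_cutoff
  mito_mad <- mad_score(meta$mito_fraction, fallback = "meanad")
  pass_mito <- mito_mad <= th$mito_mad_cutoff
  count_mad <- mad_score(log(pmax(meta$total_counts, 1)), fallback = "meanad")
  cutoff <- ifelse(lymphoid, th$count_mad_cutoff_lymphoid, th$count_mad_cutoff_other)
  pass_counts <- count_mad >= cutoff
  if (isTRUE(th$count_two_sided)) pass_counts <- pass_counts & (count_mad <= -cutoff)

  tibble(
    barcode = meta$barcode, lineage = labels, lymphoid = lymphoid,
    doublet_mad = as.numeric(doublet_mad), mito_mad = as.numeric(mito_mad),
    count_mad = as.numeric(count_mad),
    pass_doublet = pass_doublet, pass_mito = pass_mito, pass_counts = pass_counts,
    keep = pass_doublet & pass_mito & pass_counts
  )
}

#' Subset a count matrix to kept cells
#' @param cm A [count_matrix].
#' @param keep Logical mask or barcode character vector.
#' @return A [count_matrix].
#' @export
subset_cells <- function(cm, keep) {
  if (is.character(keep)) keep <- colnames(cm$counts) %in% keep
  count_matrix(cm$counts[, keep, drop = FALSE], sample_id = cm$sample_id,
               cell_meta = cm$cell_meta[keep, , drop = FALSE])
}

new_normalized_matrix <- function(values, method, residual_variance = NULL,
                                  scale_factor = NULL) {
  structure(list(values = values, method = method,
                 residual_variance = residual_variance,
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells, method '%s'\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Depth log-normalization
#'
#' `value(g,c) = ln(1 + scale * count(g,c) / total(c))` — the standard
#' log-normalization, invariant to per-cell depth rescaling.
#'
#' @param cm A [count_matrix].
#' @param scale_factor Scale factor (default 10,000).
#' @return A `normalized_matrix` with method `"lognorm"` (values sparse).
#' @export
lognormalize <- function(cm, scale_factor = 10000) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) == 0L || nrow(cm$counts) == 0L)
    stop_validation("empty count matrix")
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0))
    stop_validation(sprintf("cells with zero total counts: %s",
                            paste(head(colnames(cm$counts)[totals == 0], 5), collapse = ", ")))
  v <- cm$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(cm$counts)
  new_normalized_matrix(v, "lognorm", scale_factor = scale_factor)
}

#' Analytic Pearson-residual normalization
#'
#' A variance-stabilizing surrogate for regularized-NB transforms: under the
#' null model `mu(g,c) = total(c) * p(g)` with `p(g)` the gene's share of the
#' grand total, residuals `r = (x - mu) / sqrt(mu + mu^2/theta)` are clipped
#' to `±clip` and the per-gene residual variance is recorded for variable
#' gene selection.
#'
#' @param cm A [count_matrix].
#' @param theta NB dispersion of the null model (default 100).
#' @param clip Clipping bound (default `sqrt(n_cells)`).
#' @return A `normalized_matrix` with method `"pearson"` (dense values) and
#'   per-gene `residual_variance`.
#' @export
pearson_residuals <- function(cm, theta = 100, clip = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- as.matrix(cm$counts)
  totals <- colSums(x)
  grand <- sum(totals)
  if (grand == 0) stop_validation("grand total of counts is zero")
  if (is.null(clip)) clip <- sqrt(ncol(x))
  p <- rowSums(x) / grand
  mu <- outer(p, totals)                     # genes x cells
  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[denom == 0] <- 0
  r <- pmin(pmax(r, -clip), clip)
  dimnames(r) <- dimnames(cm$counts)
  rv <- apply(r, 1L, var)
  rv[is.na(rv)] <- 0
  new_normalized_matrix(r, "pearson", residual_variance = rv)
}

#' Residualize covariates out of a normalized matrix
#'
#' Per-gene least-squares residualization against per-cell covariates
#' (e.g. mitochondrial fraction, cell-cycle scores), the surrogate for
#' treating them as non-regularized latent variables in the VST model.
#'
#' @param nm A `normalized_matrix`.
#' @param covariates Numeric matrix/data frame, one row per cell.
#' @return A `normalized_matrix` of the same method with covariate effects
#'   removed and residual variances recomputed.
#' @export
residualize_covariates <- function(nm, covariates) {
  stopifnot(inherits(nm, "normalized_matrix"))
  X <- cbind(1, as.matrix(covariates))
  v <- as.matrix(nm$values)
  if (nrow(X) != ncol(v)) stop_validation("one covariate row per cell required")
  beta <- solve(crossprod(X), crossprod(X, t(v)))
  res <- v - t(X %*% beta)
  rv <- apply(res, 1L, var)
  new_normalized_matrix(res, nm$method, residual_variance = rv,
                        scale_factor = nm$scale_factor)
}

#' Select highly variable genes by residual variance
#'
#' Threshold mode (`residual variance > threshold`, default 1.3) or top-n
#' mode (`top_n` by residual variance, ties broken by gene id ascending).
#' Exactly one mode must be set.
#'
#' @param nm A `normalized_matrix` with `residual_variance` (or a named
#'   numeric vector of residual variances).
#' @param threshold Residual-variance threshold (default 1.3 when `top_n` is
#'   `NULL`).
#' @param top_n Number of genes to take, or `NULL`.
#' @return Character vector of gene ids.
#' @export
select_hvgs <- function(nm, threshold = NULL, top_n = NULL) {
  rv <- if (inherits(nm, "normalized_matrix")) nm$residual_variance else nm
  if (is.null(rv)) stop_parameter("residual variances unavailable; use pearson_residuals()")
  if (!is.null(threshold) && !is.null(top_n))
    stop_parameter("set either threshold or top_n, not both")
  if (is.null(threshold) && is.null(top_n)) threshold <- 1.3
  ids <- names(rv)
  if (!is.null(top_n)) {
    if (top_n > length(rv)) top_n <- length(rv)
    ord <- order(-rv, ids)
    return(ids[ord][seq_len(top_n)])
  }
  ids[rv > threshold]
}
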