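#' Aggregate single-nuclei counts into pseudo-bulk units
#'
#' Per (sample, cell type) unit, gene-wise sums of the member cells' counts.
#' Units with fewer than `min_cells` cells are dropped (defaults in the
#' pipeline: 10 for broad-type tumor-vs-normal analyses, 50 for per-sample
#' subtype aggregation, 300 total nuclei for subset-level analyses).
#'
#' @param cms A [count_matrix] or list of them (one per sample).
#' @param assignments Tibble with columns `cell`, `cell_type` covering all
#'   cells (matched by barcode).
#' @param min_cells Minimum cells per unit (default 10).
#' @return A `pseudobulk` object: `counts` (genes-by-units), `unit_meta`
#'   tibble (`unit`, `sample_id`, `cell_type`, `n_cells`).
#' @export
pseudobulk <- function(cms, assignments, min_cells = 10) {
  if (inherits(cms, "count_matrix")) cms <- list(cms)
  blocks <- list(); meta <- list()
  for (cm in cms) {
    idx <- match(colnames(cm$counts), assignments$cell)
    if (anyNA(idx)) stop_validation("assignments do not cover all cells")
    types <- assignments$cell_type[idx]
    for (t in sort(unique(types))) {
      sel <- types == t
      if (sum(sel) < min_cells) next
      unit <- paste(cm$sample_id, t, sep = "|")
      blocks[[unit]] <- Matrix::rowSums(cm$counts[, sel, drop = FALSE])
      meta[[unit]] <- tibble(unit = unit, sample_id = cm$sample_id,
                             cell_type = t, n_cells = sum(sel))
    }
  }
  if (!length(blocks)) stop_validation("no unit passed the min_cells filter")
  counts <- do.call(cbind, blocks)
  colnames(counts) <- names(blocks)
  structure(list(counts = counts, unit_meta = bind_rows(meta)),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d units (%d samples, %d cell types)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$unit_meta$sample_id)),
              length(unique(x$unit_meta$cell_type))))
  invisible(x)
}

#' TMM-normalized log2 CPM
#'
#' Trimmed-mean-of-M-values normalization factors (30% M-trim, 5% A-trim,
#' reference library closest to the upper-quartile mean) followed by log2
#' CPM with a prior count, via edgeR.
#'
#' @param pb A `pseudobulk`, or a genes-by-units count matrix.
#' @param prior_count Prior count for the log transform (default 0.5).
#' @return Genes-by-units matrix of log2 CPM values with the normalization
#'   factors attached as attribute `norm_factors`.
#' @export
tmm_log2cpm <- function(pb, prior_count = 0.5) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  if (ncol(counts) < 2L) stop_validation("need at least 2 units")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    warn(sprintf("%d zero-library unit(s) dropped", sum(lib == 0)))
    counts <- counts[, lib > 0, drop = FALSE]
  }
  dge <- edgeR::DGEList(counts = as.matrix(counts))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  out <- edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
  attr(out, "norm_factors") <- setNames(dge$samples$norm.factors,
                                        colnames(counts))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' `adj_(i) = min_{j >= i} min(1, p_(j) * n / j)` mapped back to input
#' order; NAs are carried through.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_validation("p-values outside [0,1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  }
  out
}

#' One-vs-rest contrasts over group levels
#'
#' For each group `g`: +1 on `g` and `-1/(G-1)` on every other group, so
#' every contrast sums to zero.
#'
#' @param groups Character vector of group levels (or factor whose levels
#'   are used).
#' @return Named list of named contrast vectors.
#' @export
one_vs_rest_contrasts <- function(groups) {
  levels <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  if (length(levels) < 2L) stop_validation("need at least 2 groups")
  out <- lapply(levels, function(g) {
    v <- setNames(rep(-1 / (length(levels) - 1), length(levels)), levels)
    v[g] <- 1
    v
  })
  setNames(out, paste0(levels, "_vs_rest"))
}

#' Blockwise linear-model differential expression with moderated t
#'
#' Per missingness block (set of samples where a gene is observed), genes
#' are fitted by ordinary least squares against `~ 0 + group (+ covariates)`
#' and contrasts over the group levels are formed. Residual variances are
#' shrunk by empirical Bayes: the prior df `d0` and prior variance `s0^2`
#' are estimated by moment matching of the log sample variances to a scaled
#' F distribution (with `s0^2` an expression trend when `trend = TRUE`, the
#' limma-trend approach); the moderated t is
#' `log2FC / (unscaled SE * s_tilde)` with
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` on `d0 + d_g` df.
#'
#' Contrasts whose groups are unobserved in a gene's block yield `NA` and
#' are flagged; rank-deficient blocks flag their genes rather than silently
#' dropping them.
#'
#' @param mat Genes-by-samples numeric matrix (log scale; NA = missing,
#'   per gene-by-group blocks).
#' @param meta Tibble with one row per sample/unit.
#' @param group Name of the group column in `meta`.
#' @param covariates Names of additional factor columns (e.g. sex, batch).
#' @param contrasts Named list of contrast vectors over group levels
#'   (default: one-vs-rest over all levels). Each must sum to 0.
#' @param trend Use an expression trend for the prior variance (default
#'   TRUE).
#' @param d0 Override the prior df (0 = ordinary t; Inf = fully shrunk).
#' @param lowess_span Span of the trend smoother (default 0.5).
#' @return A `de_result` tibble: `gene`, `contrast`, `log2fc`, `avg_expr`,
#'   `t`, `p`, `adj_p`, `df_total`, `block`, `flag`; attributes `d0` and
#'   `s02`.
#' @export
fit_de <- function(mat, meta, group = "group", covariates = character(),
                   contrasts = NULL, trend = TRUE, d0 = NULL,
                   lowess_span = 0.5) {
  mat <- as.matrix(mat)
  meta <- as_tibble(meta)
  if (nrow(meta) != ncol(mat)) stop_validation("one metadata row per column required")
  gvec <- as.character(meta[[group]])
  glev <- sort(unique(gvec))
  if (is.null(contrasts)) contrasts <- one_vs_rest_contrasts(glev)
  for (nm in names(contrasts)) {
    if (abs(sum(contrasts[[nm]])) > 1e-8)
      stop_validation(sprintf("contrast '%s' does not sum to 0", nm))
  }

  pattern <- apply(ifelse(is.na(mat), "0", "1"), 1L, paste, collapse = "")
  rows <- list()
  sig2 <- df_resid <- amean <- rep(NA_real_, nrow(mat))
  est <- vector("list", nrow(mat))
  for (pat in unique(pattern)) {
    genes <- which(pattern == pat)
    samp <- which(strsplit(pat, "")[[1L]] == "1")
    if (length(samp) < 3L) next
    bg <- factor(gvec[samp], levels = intersect(glev, gvec[samp]))
    dat <- data.frame(.group = bg)
    for (cv in covariates) dat[[cv]] <- factor(meta[[cv]][samp])
    dat <- droplevels(dat)
    base_term <- if (nlevels(bg) > 1L) "~ 0 + .group" else "~ 1"
    form <- paste(base_term,
                  paste(vapply(covariates, function(cv)
                    if (nlevels(dat[[cv]]) > 1L) paste("+", cv) else "", ""),
                    collapse = " "))
    X <- model.matrix(stats::as.formula(form), data = dat)
    Y <- t(mat[genes, samp, drop = FALSE])
    fit <- lm.fit(X, Y)
    rank <- fit$rank
    dfr <- length(samp) - rank
    if (dfr < 1L) next
    coefs <- matrix(fit$coefficients, ncol = length(genes),
                    dimnames = list(colnames(X), NULL))
    res <- matrix(fit$residuals, ncol = length(genes))
    s2 <- colSums(res^2) / dfr
    XtXi <- if (rank == ncol(X))
      tryCatch(solve(crossprod(X)), error = function(e) NULL) else NULL
    ## map contrasts to design columns
    cname <- paste0(".group", levels(bg))
    for (ci in seq_along(contrasts)) {
      cv <- contrasts[[ci]]
      present <- names(cv)[cv != 0] %in% levels(bg)
      cvec <- setNames(rep(0, ncol(X)), colnames(X))
      flag <- NA_character_
      if (!all(present)) {
        flag <- "group_missing_in_block"
        lfc <- se_unscaled <- rep(NA_real_, length(genes))
      } else {
        cvec[cname] <- cv[levels(bg)]
        if (is.null(XtXi)) {
          flag <- "rank_deficient"
          se_unscaled <- rep(NA_real_, length(genes))
          lfc <- rep(NA_real_, length(genes))
        } else {
          lfc <- as.numeric(crossprod(cvec, coefs))
          se1 <- sqrt(as.numeric(crossprod(cvec, XtXi %*% cvec)))
          se_unscaled <- rep(se1, length(genes))
        }
      }
      rows[[paste(pat, ci)]] <- tibble(
        gene = rownames(mat)[genes], contrast = names(contrasts)[ci],
        log2fc = lfc, se_unscaled = se_unscaled,
        block = pat, flag = flag)
    }
    sig2[genes] <- s2
    df_resid[genes] <- dfr
    amean[genes] <- colMeans(Y)
  }
  if (!length(rows)) stop_validation("no block could be fitted")

  ## empirical Bayes moderation pooled over all fitted genes
  fitted_genes <- which(!is.na(sig2))
  if (is.null(d0)) {
    sq <- limma::squeezeVar(sig2[fitted_genes], df_resid[fitted_genes],
                            covariate = if (trend) amean[fitted_genes] else NULL)
    d0_hat <- sq$df.prior
    s2_post <- sq$var.post
    s02 <- sq$var.prior
  } else if (d0 == 0) {
    d0_hat <- 0; s2_post <- sig2[fitted_genes]; s02 <- NA_real_
  } else if (is.infinite(d0)) {
    s02 <- mean(sig2[fitted_genes])
    d0_hat <- Inf; s2_post <- rep(s02, length(fitted_genes))
  } else {
    s02 <- mean(sig2[fitted_genes])
    d0_hat <- d0
    s2_post <- (d0 * s02 + df_resid[fitted_genes] * sig2[fitted_genes]) /
      (d0 + df_resid[fitted_genes])
  }
  post <- rep(NA_real_, nrow(mat)); post[fitted_genes] <- s2_post
  d0_vec <- if (length(d0_hat) == 1L) rep(d0_hat, nrow(mat)) else {
    tmp <- rep(NA_real_, nrow(mat)); tmp[fitted_genes] <- d0_hat; tmp
  }

  out <- bind_rows(rows)
  gi <- match(out$gene, rownames(mat))
  out$avg_expr <- amean[gi]
  s_tilde <- sqrt(post[gi])
  out$t <- out$log2fc / (out$se_unscaled * s_tilde)
  out$df_total <- df_resid[gi] + pmin(d0_vec[gi], 1e9)
  out$p <- 2 * pt(-abs(out$t), df = out$df_total)
  out <- group_by(out, .data$contrast) |>
    mutate(adj_p = bh_adjust(.data$p)) |>
    ungroup() |>
    select("gene", "contrast", "log2fc", "avg_expr", "t", "p", "adj_p",
           "df_total", "block", "flag")
  structure(out, d0 = d0_hat, s02 = s02, class = c("de_result", class(out)))
}

#' Threshold a DE result into significant gene lists
#'
#' @param res A `de_result` (or compatible tibble).
#' @param lfc Absolute log2 fold-change cutoff (default 0.5; use 3 for the
#'   marker / receptor-ligand selection rule).
#' @param fdr BH-adjusted p cutoff (default 0.05).
#' @return Tibble of passing rows with a `direction` column (`up`/`down`).
#' @export
threshold_de <- function(res, lfc = 0.5, fdr = 0.05) {
  filter(res, !is.na(.data$log2fc), !is.na(.data$adj_p),
         abs(.data$log2fc) > lfc, .data$adj_p < fdr) |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
}

#' Single-sample gene-set scores (mean of z-scored expression)
#'
#' A documented surrogate for rank-kernel single-sample enrichment: each
#' gene is z-scored across samples and a set's score in a sample is the mean
#' z of its member genes. Valid for group-level comparisons of set activity.
#'
#' @param mat Genes-by-samples matrix.
#' @param gene_sets Named list of gene-id vectors.
#' @return Sets-by-samples score matrix; attribute `n_missing` counts set
#'   genes absent from the matrix.
#' @export
geneset_scores <- function(mat, gene_sets) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 1L, sd)
  z <- (mat - rowMeans(mat)) / ifelse(sds > 0, sds, 1)
  miss <- vapply(gene_sets, function(g) sum(!g %in% rownames(mat)), 0L)
  if (any(miss > 0))
    inform(sprintf("%d gene-set gene(s) absent from matrix", sum(miss)))
  scores <- t(vapply(gene_sets, function(g) {
    genes <- intersect(g, rownames(z))
    if (!length(genes)) stop_validation("gene set with empty intersection")
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(mat))))
  dimnames(scores) <- list(names(gene_sets), colnames(mat))
  attr(scores, "n_missing") <- miss
  scores
}

#' Differential cell-type abundance on logit-transformed proportions
#'
#' Per sample, cell-type proportions are computed with a half-count
#' continuity correction, logit-transformed, and compared between groups by
#' two-sample t-tests per cell type (each group vs rest when more than two
#' groups), with BH adjustment across cell types.
#'
#' @param counts Samples-by-types matrix of cell counts (rownames = sample
#'   ids).
#' @param groups Per-sample group labels.
#' @return Tibble: `cell_type`, `comparison`, `mean_logit_in`,
#'   `mean_logit_out`, `t`, `p`, `adj_p`.
#' @export
differential_abundance <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != nrow(counts))
    stop_validation("one group label per sample required")
  small <- names(table(groups))[table(groups) < 2]
  if (length(small))
    stop_validation(sprintf("group(s) with a single sample: %s",
                            paste(small, collapse = ", ")))
  n_types <- ncol(counts)
  tot <- rowSums(counts)
  prop <- (counts + 0.5) / (tot + 0.5 * n_types)
  lg <- qlogis(prop)
  lev <- sort(unique(groups))
  comparisons <- if (length(lev) == 2L) {
    setNames(list(groups == lev[1L]), paste0(lev[1L], "_vs_", lev[2L]))
  } else {
    setNames(lapply(lev, function(g) groups == g), paste0(lev, "_vs_rest"))
  }
  out <- purrr::map_dfr(names(comparisons), function(cmp) {
    inn <- comparisons[[cmp]]
    purrr::map_dfr(seq_len(n_types), function(j) {
      tt <- t.test(lg[inn, j], lg[!inn, j], var.equal = TRUE)
      tibble(cell_type = colnames(counts)[j], comparison = cmp,
             mean_logit_in = mean(lg[inn, j]),
             mean_logit_out = mean(lg[!inn, j]),
             t = unname(tt$statistic), p = tt$p.value)
    }) |> mutate(adj_p = bh_adjust(.data$p))
  })
  out
}
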