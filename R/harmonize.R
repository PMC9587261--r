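#' Collapse probe-level expression to gene level
#'
#' Gene value = mean of its mapped probes' values; unmapped probes are
#' dropped with a logged count.
#'
#' @param probe_matrix Probes-by-samples numeric matrix with probe rownames.
#' @param probe_to_gene_map Tibble/data frame with columns `probe`, `gene`
#'   (each probe mapped to at most one gene).
#' @return Genes-by-samples matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene_map) {
  map <- as_tibble(probe_to_gene_map)
  if (!all(c("probe", "gene") %in% names(map)))
    stop_validation("mapping needs 'probe' and 'gene' columns")
  if (nrow(map) == 0L) stop_validation("empty probe-to-gene mapping")
  if (anyDuplicated(map$probe)) stop_validation("probe mapped to more than one gene")
  probe_matrix <- as.matrix(probe_matrix)
  idx <- match(rownames(probe_matrix), map$probe)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0) inform(sprintf("%d unmapped probe(s) dropped", unmapped))
  keep <- !is.na(idx)
  m <- probe_matrix[keep, , drop = FALSE]
  genes <- map$gene[idx[keep]]
  out <- rowsum(m, group = genes) / as.vector(table(genes)[sort(unique(genes))])
  out[order(rownames(out)), , drop = FALSE]
}

qn_rank_means <- function(x) {
  ## classical quantile normalization of a complete matrix: each column's
  ## values replaced by the cross-column mean order statistic at its rank;
  ## ties receive the mean of their spanned quantiles.
  ref <- rowMeans(apply(x, 2L, sort))
  apply(x, 2L, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    stats::ave(assigned, col, FUN = mean)
  })
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the common distribution of mean order
#' statistics. Missing entries are excluded per sample: with missing values
#' the reference distribution is the mean of the per-column empirical
#' quantile functions on a common probability grid, and each column is
#' mapped through it at its observed ranks.
#'
#' @param x Genes-by-samples numeric matrix (NA = missing).
#' @return Matrix of the same shape; missing entries stay missing.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_validation("need at least 2 samples")
  if (!anyNA(x)) return(qn_rank_means(x))
  n_obs <- colSums(!is.na(x))
  grid <- seq(0, 1, length.out = max(n_obs))
  qf <- vapply(seq_len(ncol(x)), function(j)
    quantile(x[, j], probs = grid, na.rm = TRUE, names = FALSE, type = 7),
    numeric(length(grid)))
  ref <- rowMeans(qf)
  out <- x
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]))
    n <- length(obs)
    p <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
    assigned <- numeric(n)
    assigned[order(x[obs, j])] <- approx(grid, ref, xout = p, rule = 2)$y
    out[obs, j] <- stats::ave(assigned, x[obs, j], FUN = mean)
  }
  out
}

#' Quantile normalization onto a target distribution
#'
#' Each sample's sorted values are mapped onto the target quantile vector
#' (linear interpolation when lengths differ); ranks are preserved and ties
#' receive the mean of their spanned target values. This is how RNA-seq
#' batches and projected pseudo-bulk samples are forced onto the microarray
#' compendium's intensity distribution.
#'
#' @param x Genes-by-samples matrix (NA = missing) or a single numeric
#'   vector.
#' @param target Nondecreasing numeric vector of target quantiles (a
#'   `quantile_target`).
#' @return Object of the same shape as `x`.
#' @export
quantile_normalize_to_target <- function(x, target) {
  target <- as.numeric(target)
  if (!length(target)) stop_validation("empty quantile target")
  if (is.unsorted(target)) stop_validation("target must be nondecreasing")
  map_col <- function(col) {
    obs <- which(!is.na(col))
    n <- length(obs)
    if (!n) return(col)
    p <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
    tp <- seq(0, 1, length.out = length(target))
    mapped <- if (length(target) == 1L) rep(target, n) else approx(tp, target, xout = p)$y
    assigned <- numeric(n)
    assigned[order(col[obs])] <- mapped
    col[obs] <- stats::ave(assigned, col[obs], FUN = mean)
    col
  }
  if (is.matrix(x)) apply(x, 2L, map_col) else map_col(x)
}

#' Extract a quantile target from a matrix
#'
#' The sorted vector of cross-sample mean order statistics of a (typically
#' microarray) matrix, used as the target distribution when merging other
#' platforms.
#' @param x Genes-by-samples matrix (complete rows only are used when NAs
#'   are present).
#' @return Sorted numeric vector of class `quantile_target`.
#' @export
quantile_target <- function(x) {
  x <- as.matrix(x)
  cc <- complete.cases(x)
  ref <- rowMeans(apply(x[cc, , drop = FALSE], 2L, sort))
  structure(sort(ref), class = c("quantile_target", "numeric"))
}

#' Fit the compendium batch model
#'
#' Per gene, a weighted least-squares fit on the samples where the gene is
#' observed: `y = mu_g + beta_batch + gamma_genotype + noise`, with batch
#' coefficients sum-to-zero coded over the batches observing the gene and
#' genotype treatment-coded against a reference genotype. Samples with
#' unknown genotype (and any explicitly listed samples) get zero weight —
#' they do not inform the fit but are still corrected. Genes observed in
#' fewer than two batches are flagged unfit (batch coefficients zero).
#'
#' @param bm A [bulk_matrix]; `sample_meta$genotype` may contain NA
#'   (= unknown).
#' @param zero_weight_samples Additional sample ids to zero-weight (e.g. a
#'   confounded cluster).
#' @return A `batch_model`: list with per-gene `mu`, `beta`
#'   (genes-by-batches, NA where the gene is unobserved in a batch), `gamma`
#'   (genes-by-genotypes, reference column zero), `weights`, `fitted`,
#'   `aliased` flags, `reference_genotype`, `batches`.
#' @export
fit_batch_model <- function(bm, zero_weight_samples = character()) {
  stopifnot(inherits(bm, "bulk_matrix"))
  meta <- bm$sample_meta
  v <- bm$values
  batches <- sort(unique(meta$batch))
  genotype <- meta$genotype %||% rep(NA_character_, nrow(meta))
  geno_levels <- sort(unique(genotype[!is.na(genotype)]))
  if (!length(geno_levels)) geno_levels <- "unknown"
  ref_geno <- geno_levels[1L]
  w <- as.numeric(!is.na(genotype) & !(meta$sample_id %in% zero_weight_samples))
  if (sum(w) < 2L) stop_validation("fewer than 2 weighted samples")

  mu <- setNames(rep(NA_real_, nrow(v)), rownames(v))
  beta <- matrix(NA_real_, nrow(v), length(batches),
                 dimnames = list(rownames(v), batches))
  gamma <- matrix(0, nrow(v), length(geno_levels),
                  dimnames = list(rownames(v), geno_levels))
  fitted <- setNames(rep(FALSE, nrow(v)), rownames(v))
  aliased <- setNames(rep(FALSE, nrow(v)), rownames(v))

  ## group genes by missingness block (set of batches observing the gene)
  obs_batch <- vapply(batches, function(b)
    colSums(!is.na(t(v[, meta$batch == b, drop = FALSE]))) > 0, # nolint
    logical(nrow(v)))
  if (nrow(v) == 1L) obs_batch <- matrix(obs_batch, nrow = 1L,
                                         dimnames = list(rownames(v), batches))
  pattern <- apply(obs_batch, 1L, paste, collapse = "")
  n_aliased <- 0L
  for (pat in unique(pattern)) {
    genes <- which(pattern == pat)
    bset <- batches[obs_batch[genes[1L], ]]
    if (!length(bset)) next
    samp <- which(meta$batch %in% bset & w > 0)
    if (length(samp) < 2L) next
    bf <- factor(meta$batch[samp], levels = bset)
    gf <- factor(ifelse(is.na(genotype[samp]), ref_geno, genotype[samp]),
                 levels = geno_levels)
    gf <- droplevels(gf)
    terms <- "1"
    if (nlevels(bf) > 1L) terms <- c(terms, "bf")
    if (nlevels(gf) > 1L) terms <- c(terms, "gf")
    X <- model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                      data = data.frame(bf = bf, gf = gf),
                      contrasts.arg = c(
                        if (nlevels(bf) > 1L) list(bf = "contr.sum"),
                        if (nlevels(gf) > 1L) list(gf = "contr.treatment")))
    Y <- t(v[genes, samp, drop = FALSE])
    fit <- lm.fit(X, Y)
    coefs <- matrix(fit$coefficients, ncol = length(genes))
    rownames(coefs) <- colnames(X)
    bad <- apply(coefs, 2L, anyNA)
    if (any(bad)) {
      n_aliased <- n_aliased + sum(bad)
      aliased[genes[bad]] <- TRUE
      coefs[is.na(coefs)] <- 0
    }
    mu[genes] <- coefs["(Intercept)", ]
    if (nlevels(bf) > 1L) {
      brows <- grep("^bf", rownames(coefs))
      bcoef <- coefs[brows, , drop = FALSE]               # B-1 x genes
      full <- rbind(bcoef, -colSums(bcoef))               # sum-to-zero completion
      beta[genes, bset] <- t(full)
      fitted[genes] <- TRUE
    } else {
      beta[genes, bset] <- 0
    }
    if (nlevels(gf) > 1L) {
      grows <- grep("^gf", rownames(coefs))
      glev <- sub("^gf", "", rownames(coefs)[grows])
      gamma[genes, glev] <- t(coefs[grows, , drop = FALSE])
    }
  }
  if (n_aliased > 0)
    warn(sprintf("%d gene(s) had aliased (confounded) coefficients set to zero",
                 n_aliased), class = "pcpg_aliased_warning")
  structure(list(mu = mu, beta = beta, gamma = gamma,
                 weights = setNames(w, meta$sample_id),
                 fitted = fitted, aliased = aliased,
                 reference_genotype = ref_geno, batches = batches,
                 genotypes = geno_levels),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("<batch_model> %d genes, %d batches (%s), reference genotype '%s', %d zero-weight sample(s)\n",
              length(x$mu), length(x$batches),
              paste(x$batches, collapse = ", "), x$reference_genotype,
              sum(x$weights == 0)))
  invisible(x)
}

#' Remove batch effects using a fitted batch model
#'
#' `y'(g,s) = y(g,s) - beta(g, batch(s))`. Genotype effects are *not*
#' removed (they carry the biology); zero-weight and unknown-genotype
#' samples are corrected too, since their batch term is defined.
#'
#' @param bm A [bulk_matrix].
#' @param model A `batch_model` fitted on the same gene/batch universe.
#' @return A corrected [bulk_matrix].
#' @export
remove_batch_effects <- function(bm, model) {
  stopifnot(inherits(bm, "bulk_matrix"), inherits(model, "batch_model"))
  unknown_batches <- setdiff(unique(bm$sample_meta$batch), model$batches)
  if (length(unknown_batches))
    stop_validation(sprintf("batch(es) absent from model: %s",
                            paste(unknown_batches, collapse = ", ")))
  v <- bm$values
  genes <- intersect(rownames(v), names(model$mu))
  for (b in unique(bm$sample_meta$batch)) {
    cols <- which(bm$sample_meta$batch == b)
    shift <- model$beta[genes, b]
    shift[is.na(shift)] <- 0
    v[genes, cols] <- v[genes, cols, drop = FALSE] - shift
  }
  bulk_matrix(v, bm$sample_meta, promote_partial_missingness = FALSE)
}

#' Drop replicate samples, keeping the first by sample id
#'
#' Metadata-driven replicate removal: within each `replicate_group`, only
#' the lexicographically first sample id is kept. Applied after batch-effect
#' removal.
#' @param bm A [bulk_matrix] whose metadata has a `replicate_group` column
#'   (NA = not replicated).
#' @return A filtered [bulk_matrix].
#' @export
drop_replicates <- function(bm) {
  meta <- bm$sample_meta
  if (!"replicate_group" %in% names(meta)) return(bm)
  keep <- meta |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$replicate_group) |>
    filter(is.na(.data$replicate_group) | .data$sample_id == min(.data$sample_id)) |>
    ungroup() |>
    pull(.data$.row)
  keep <- sort(keep)
  bulk_matrix(bm$values[, keep, drop = FALSE], meta[keep, , drop = FALSE],
              promote_partial_missingness = FALSE)
}
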