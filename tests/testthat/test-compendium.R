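test_that("probe collapse averages mapped probes and drops the rest", {
  pm <- matrix(c(3, 5, 7, 2, 4, 6), 3, 2,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- tibble::tibble(probe = c("p1", "p2"), gene = c("G", "G"))
  out <- collapse_probes(pm, map)
  expect_equal(out["G", "s1"], 4)                      # mean(3, 5)
  expect_equal(out["G", "s2"], 3)                      # mean(2, 4)
  expect_equal(nrow(out), 1)                           # unmapped p3 dropped

  ## single-probe genes unchanged; probe order permutation invariant
  map2 <- tibble::tibble(probe = c("p3", "p1"), gene = c("A", "B"))
  o1 <- collapse_probes(pm, map2)
  o2 <- collapse_probes(pm[c(3, 1, 2), ], map2)
  expect_equal(o1["A", ], pm["p3", ])
  expect_equal(o1, o2)

  expect_error(collapse_probes(pm, tibble::tibble(probe = character(),
                                                  gene = character())),
               class = "pcpg_validation_error")
  expect_error(collapse_probes(pm, tibble::tibble(probe = c("p1", "p1"),
                                                  gene = c("A", "B"))),
               class = "pcpg_validation_error")
})

## independent distance oracle for the degenerate consensus check
consensus_distance_oracle <- function(x) {
  xc <- x - rowMeans(x)
  as.dist(1 - cor(xc))
}

qn_oracle <- function(x) {
  ## brute-force definitional quantile normalization (complete matrices):
  ## mean order statistic per rank, ties = mean of spanned quantiles
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r_min <- rank(x[, j], ties.method = "min")
    r_max <- rank(x[, j], ties.method = "max")
    out[, j] <- vapply(seq_len(nrow(x)), function(i)
      mean(ref[r_min[i]:r_max[i]]), 0)
  }
  out
}

test_that("quantile normalization matches the definition, oracle and limma", {
  x <- cbind(c(1, 3), c(4, 2))
  dimnames(x) <- list(c("g1", "g2"), c("s1", "s2"))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, 1]), c(1.5, 3.5))
  expect_equal(unname(qn[, 2]), c(3.5, 1.5))

  ## identical columns unchanged; all columns share sorted values
  y <- matrix(rep(c(5, 1, 9), 3), 3)
  expect_equal(quantile_normalize(y), y)
  withr::with_seed(1, {
    z <- matrix(rnorm(50 * 4), 50)
    qz <- quantile_normalize(z)
    for (j in 2:4) expect_equal(sort(qz[, j]), sort(qz[, 1]))
    ## oracle equivalence on many random matrices, with and without ties
    for (i in 1:50) {
      w <- matrix(sample(1:8, 24, replace = TRUE), 6)   # heavy ties
      expect_equal(quantile_normalize(w), qn_oracle(w))
      w2 <- matrix(rnorm(24), 6)
      expect_equal(quantile_normalize(w2), qn_oracle(w2))
    }
    ## independent cross-check against limma
    v <- matrix(rnorm(200), 50)
    expect_equal(unname(quantile_normalize(v)),
                 unname(limma::normalizeQuantiles(v)), tolerance = 1e-10)
  })
})

test_that("target quantile normalization maps ranks onto the target", {
  expect_equal(unname(quantile_normalize_to_target(
    matrix(c(10, 20, 30), 3), c(1, 2, 3))[, 1]), c(1, 2, 3))
  ## target = own sorted values leaves a sample unchanged
  x <- c(4, 1, 9, 2)
  expect_equal(unname(quantile_normalize_to_target(matrix(x, 4), sort(x))[, 1]), x)
  ## monotonicity: output order equals input order
  withr::with_seed(2, {
    s <- rnorm(40); tg <- sort(rnorm(25))
    out <- quantile_normalize_to_target(matrix(s, 40), tg)[, 1]
    expect_equal(order(out), order(s))
  })
  ## ties get the mean of spanned target values
  out2 <- quantile_normalize_to_target(matrix(c(5, 5, 7), 3), c(0, 1, 2))[, 1]
  expect_equal(out2, c(0.5, 0.5, 2))
  expect_error(quantile_normalize_to_target(matrix(1), numeric()),
               class = "pcpg_validation_error")
})

test_that("batch model recovers constructed and simulated effects", {
  ## balanced two-batch design with a +2 shift on batch B, no noise
  genes <- paste0("g", 1:5)
  gene_mu <- withr::with_seed(13, rnorm(5, 8, 2))
  geno_eff <- c(g1 = 0, g2 = 1.5)
  meta <- tibble::tibble(sample_id = paste0("s", 1:8),
                         batch = rep(c("A", "B"), each = 4),
                         genotype = rep(c("g1", "g2"), 4))
  ## noiseless: value = gene effect + genotype effect (+ batch shift below)
  base <- outer(gene_mu, geno_eff[meta$genotype])
  dimnames(base) <- list(genes, meta$sample_id)
  base <- base + gene_mu
  shifted <- base; shifted[, 5:8] <- shifted[, 5:8] + 2
  bm <- bulk_matrix(shifted, meta)
  model <- fit_batch_model(bm)
  expect_equal(unname(model$beta[, "A"]), rep(-1, 5), tolerance = 1e-8)
  expect_equal(unname(model$beta[, "B"]), rep(1, 5), tolerance = 1e-8)
  corrected <- remove_batch_effects(bm, model)
  gap <- rowMeans(corrected$values[, 5:8]) - rowMeans(corrected$values[, 1:4])
  expect_lt(max(abs(gap)), 1e-8)

  ## single batch: beta = 0, correction is the identity
  meta1 <- meta; meta1$batch <- "A"
  m1 <- fit_batch_model(bulk_matrix(shifted, meta1))
  expect_true(all(m1$beta == 0))
  expect_equal(remove_batch_effects(bulk_matrix(shifted, meta1), m1)$values,
               shifted)

  ## all-zero model is the identity
  model0 <- model; model0$beta[] <- 0
  expect_equal(remove_batch_effects(bm, model0)$values, bm$values)
  ## unknown batch rejected
  meta_bad <- meta; meta_bad$batch[1] <- "C"
  expect_error(remove_batch_effects(bulk_matrix(shifted, meta_bad), model),
               class = "pcpg_validation_error")

  ## synthetic compendium: shifts recovered within tolerance; genotype
  ## (subtype) structure preserved after correction
  h <- fx_harmonized()
  truth <- fx_bulk()$truth
  fitted <- names(h$model$fitted)[h$model$fitted]
  err <- vapply(fitted, function(g) {
    obs <- !is.na(h$model$beta[g, ])
    tr <- truth$batch_shifts[g, obs] - mean(truth$batch_shifts[g, obs])
    mean(abs(h$model$beta[g, obs] - tr))
  }, 0)
  expect_lt(mean(err), 0.05)
})

test_that("zero-weight samples are excluded from fitting but still corrected", {
  genes <- paste0("g", 1:4)
  gene_mu <- withr::with_seed(14, rnorm(4, 8, 2))
  base <- matrix(gene_mu, 4, 9, dimnames = list(genes, paste0("s", 1:9)))
  shifted <- base
  shifted[, 4:6] <- shifted[, 4:6] + 1
  ## samples 7-9 are wildly off but have unknown genotype -> zero weight
  shifted[, 7:9] <- shifted[, 7:9] + 100
  meta <- tibble::tibble(sample_id = paste0("s", 1:9),
                         batch = rep(c("A", "B", "A"), each = 3),
                         genotype = c(rep("g1", 6), rep(NA, 3)))
  model <- fit_batch_model(bulk_matrix(shifted, meta))
  expect_equal(unname(model$weights), c(rep(1, 6), rep(0, 3)))
  ## the contaminated zero-weight samples do not distort batch estimates
  expect_equal(unname(model$beta[, "B"] - model$beta[, "A"]), rep(1, 4),
               tolerance = 1e-8)
})

test_that("bulk variable genes are CV outliers among complete genes", {
  withr::with_seed(5, {
    v <- matrix(rnorm(100 * 20, mean = 10, sd = 0.2), 100)
  })
  dimnames(v) <- list(paste0("g", 1:100), paste0("s", 1:20))
  v["g1", ] <- 10 + rnorm(20, sd = 3)                 # CV outlier
  v["g2", ] <- 10 + rnorm(20, sd = 5)
  v["g2", 1] <- NA                                    # incomplete
  meta <- tibble::tibble(sample_id = paste0("s", 1:20), batch = "b")
  hv <- select_variable_genes_bulk(
    bulk_matrix(v, meta, promote_partial_missingness = FALSE))
  expect_true("g1" %in% hv)
  expect_false("g2" %in% hv)                          # missing => never selected
  ## identical CVs: empty selection
  expect_length(select_variable_genes_bulk(matrix(rep(c(1, 2, 3), 10), 3,
    dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))), 0)
  expect_error(select_variable_genes_bulk(matrix(NA_real_, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))), class = "pcpg_validation_error")
})

test_that("consensus clustering produces calibrated matrices and PAC", {
  ## three clusters with distinct gene signatures (Pearson distance is
  ## invariant to uniform sample offsets, so separation must be gene-wise)
  withr::with_seed(6, {
    x <- matrix(rnorm(40 * 30), 40)
    x[1:13, 1:10] <- x[1:13, 1:10] + 6
    x[14:26, 11:20] <- x[14:26, 11:20] + 6
    x[27:40, 21:30] <- x[27:40, 21:30] + 6
  })
  dimnames(x) <- list(paste0("g", 1:40), paste0("s", 1:30))
  truth <- rep(1:3, each = 10)
  cr <- consensus_cluster(x, reps = 100, maxK = 6, seed = 2)
  M3 <- cr$consensus[["3"]]
  expect_true(isSymmetric(M3))
  expect_true(all(diag(M3) == 1))
  expect_true(all(M3 >= 0 & M3 <= 1))
  expect_lt(cr$pac[["3"]], 0.02)
  expect_equal(adjusted_rand_index(cr$assignments[, "3"], truth), 1)

  ## pItem = 1, reps = 1 degenerates to the 0/1 co-membership of one Ward cut
  cr1 <- consensus_cluster(x, pItem = 1, reps = 1, maxK = 4, seed = 1)
  d <- consensus_distance_oracle(x)
  hc <- hclust(d, method = "ward.D2")
  co <- outer(cutree(hc, 3), cutree(hc, 3), "==") * 1
  expect_equal(unname(cr1$consensus[["3"]]), unname(co))

  expect_error(consensus_cluster(x[, 1:10], maxK = 12),
               class = "pcpg_validation_error")
})

test_that("PAC-based k selection follows the plateau rule with fallback", {
  fake <- structure(list(pac = c(`2` = 0.5, `3` = 0.3, `4` = 0.02, `5` = 0.02,
                                 `6` = 0.02, `7` = 0.025)),
                    class = "consensus_result")
  k <- select_k_pac(fake)
  expect_equal(as.integer(k), 4)
  expect_false(attr(k, "no_plateau"))

  ## strictly decreasing, no plateau: argmin + flag
  fake2 <- structure(list(pac = c(`2` = 0.5, `3` = 0.4, `4` = 0.3, `5` = 0.25)),
                     class = "consensus_result")
  k2 <- select_k_pac(fake2)
  expect_equal(as.integer(k2), 5)
  expect_true(attr(k2, "no_plateau"))

  ## manual override wins
  expect_equal(as.integer(select_k_pac(fake2, override = 3)), 3)
})

test_that("manual cluster merges relabel canonically", {
  expect_equal(as.integer(merge_clusters(c(1, 2, 3, 2), list(c(2, 3)))),
               c(1, 2, 2, 2))
  expect_equal(as.integer(merge_clusters(c(1, 2, 3, 2), list())), c(1, 2, 3, 2))
  expect_equal(as.integer(merge_clusters(c(1, 2, 3), list(1:3))), c(1, 1, 1))
  expect_error(merge_clusters(c(1, 2), list(c(2, 9))),
               class = "pcpg_validation_error")
  expect_named(attributes(merge_clusters(c(1, 2), list(c(1, 2)))),
               c("audit"), ignore.order = TRUE)
})

test_that("bulk embedding is deterministic and separates subtypes", {
  emb <- fx_embedding()
  emb2 <- fit_bulk_embedding(fx_harmonized()$bulk, fx_harmonized()$hvgs,
                             batch_model = fx_harmonized()$model,
                             target = fx_harmonized()$target, seed = 7)
  expect_equal(emb$embedding, emb2$embedding)

  lab <- subtype_of(rownames(emb$embedding))
  d <- dist(emb$embedding)
  sil <- cluster::silhouette(as.integer(factor(lab)), d)
  expect_gt(mean(sil[, 3]), 0.3)

  ## training-sample transform lands on the training coordinates
  h <- fx_harmonized()
  x <- h$bulk$values[emb$genes, ]
  coords <- withr::with_seed(7, uwot::umap_transform(
    t(x - emb$gene_means), emb$model, n_threads = 1, n_sgd_threads = 0))
  d_same <- sqrt(rowSums((coords - emb$embedding)^2))
  spread <- mean(dist(emb$embedding))
  expect_lt(median(d_same), 0.25 * spread)
  expect_error(fit_bulk_embedding(h$bulk, h$hvgs[1:0]),
               class = "pcpg_validation_error")
})

test_that("new-batch coefficients recover constructed offsets", {
  h <- fx_harmonized()
  model <- h$model
  fitted <- names(model$fitted)[model$fitted & !model$aliased]
  ## sample constructed as mu + gamma(genotype) + 5 -> beta = 5
  geno <- model$genotypes[2]
  y <- model$mu[fitted] + model$gamma[fitted, geno] + 5
  new <- matrix(y, ncol = 1, dimnames = list(fitted, "n1"))
  beta <- estimate_new_batch_coefficients(new, model, genotypes = geno)
  expect_equal(unname(beta[fitted]), rep(5, length(fitted)), tolerance = 1e-8)

  ## singleton batch equal to mu + gamma exactly -> beta = 0
  new0 <- matrix(model$mu[fitted] + model$gamma[fitted, geno], ncol = 1,
                 dimnames = list(fitted, "n1"))
  beta0 <- estimate_new_batch_coefficients(new0, model, genotypes = geno)
  expect_lt(max(abs(beta0)), 1e-8)

  ## a freshly drawn batch with no offset estimates ~ 0 on average
  nb <- simulate_new_bulk_samples(fx_bulk(), subtypes = rep("C1A", 10),
                                  missing_frac = 0, seed = 21)
  vals <- quantile_normalize_to_target(log2(nb$values + 0.5), h$target)
  b2 <- estimate_new_batch_coefficients(vals, model)
  expect_lt(abs(mean(b2, na.rm = TRUE)), 3 * sd(b2, na.rm = TRUE) /
              sqrt(sum(!is.na(b2))) + 0.05)
  expect_error(estimate_new_batch_coefficients(
    matrix(1, 1, 1, dimnames = list("nogene", "s")), model),
    class = "pcpg_validation_error")
})

test_that("kNN gene imputation uses cosine neighbours and beats the mean", {
  ref <- matrix(rnorm(60 * 12), 60,
                dimnames = list(paste0("g", 1:60), paste0("r", 1:12)))
  ## duplicate of r3 with a masked gene, k = 1: imputed exactly from r3
  q <- ref[, 3, drop = FALSE]
  q["g5", ] <- NA
  colnames(q) <- "q"
  out <- knn_impute_genes(q, ref, k = 1, min_shared = 10)
  expect_equal(out["g5", "q"], ref["g5", "r3"])

  ## two equidistant neighbours with gene values 2 and 4 -> 3
  refs <- cbind(r1 = c(1, 1, 2), r2 = c(1, 1, 4))
  rownames(refs) <- c("a", "b", "c")
  q2 <- matrix(c(1, 1, NA), 3, dimnames = list(c("a", "b", "c"), "q"))
  expect_equal(knn_impute_genes(q2, refs, k = 2, min_shared = 2)["c", "q"], 3)

  ## shrinks k with a warning
  expect_warning(knn_impute_genes(q2, refs, k = 5, min_shared = 2), "shrunk")

  ## masked-and-imputed beats gene-mean imputation on the compendium
  h <- fx_harmonized()
  x <- h$bulk$values[h$hvgs, ]
  rmse_knn <- rmse_mean <- numeric(3)
  for (i in 1:3) {
    masked <- withr::with_seed(30 + i,
      sample(length(h$hvgs), floor(length(h$hvgs) * 0.15)))
    qx <- x[, 1:10, drop = FALSE]
    qx[masked, ] <- NA
    imp <- knn_impute_genes(qx, x[, -(1:10)], k = 15)
    rmse_knn[i] <- sqrt(mean((imp[masked, ] - x[masked, 1:10])^2))
    gm <- rowMeans(x[, -(1:10)])
    rmse_mean[i] <- sqrt(mean((gm[masked] - x[masked, 1:10])^2))
  }
  expect_true(all(rmse_knn < rmse_mean))
})

test_that("projection pipeline places held-out and pseudo-bulk samples correctly", {
  emb <- fx_embedding()
  lab <- subtype_of(rownames(emb$embedding))

  ## training matrix itself (batch term 0, nothing missing) projects onto
  ## its training coordinates
  h <- fx_harmonized()
  emb_plain <- emb
  emb_plain$target <- NULL; emb_plain$batch_model <- NULL
  pr_train <- project_new_samples(h$bulk$values[emb$genes, 1:20], emb_plain)
  got <- nearest_embedding_centroid(pr_train, emb$embedding, lab)
  expect_gte(mean(got == lab[1:20]), 0.9)

  ## held-out bulk samples land in their subtype's neighbourhood
  nb <- simulate_new_bulk_samples(fx_bulk(),
                                  subtypes = rep(c("C1A", "C1B", "C2A", "C2B"),
                                                 each = 4), seed = 42)
  pr <- project_new_samples(log2(nb$values + 0.5), emb)
  got2 <- nearest_embedding_centroid(pr, emb$embedding, lab)
  expect_gte(mean(got2 == nb$meta$subtype), 0.8)
  diag <- attr(pr, "diagnostics")
  expect_gt(diag$imputed_genes, 0)
})
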