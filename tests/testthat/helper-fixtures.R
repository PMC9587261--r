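## Shared fixtures, generated once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

## small synthetic bulk compendium (3 batches x 30 samples, 4 subtypes)
fx_bulk <- function() fx("bulk", function() {
  simulate_bulk_compendium(bulk_sim_config(seed = 1))
})

## harmonized compendium + model + target + variable genes
fx_harmonized <- function() fx("harmonized", function() {
  b <- fx_bulk()
  h <- harmonize_compendium(b$bulk)
  h$hvgs <- select_variable_genes_bulk(h$bulk)
  h
})

## fitted bulk embedding bundle
fx_embedding <- function() fx("embedding", function() {
  h <- fx_harmonized()
  fit_bulk_embedding(h$bulk, h$hvgs, batch_model = h$model, target = h$target,
                     seed = 7)
})

subtype_of <- function(sample_ids) {
  truth <- fx_bulk()$truth$samples
  truth$subtype[match(sample_ids, truth$sample_id)]
}

## small single-nuclei sample (3000 cells, 6 types, 2 CNV clones)
fx_sn <- function() fx("sn", function() {
  simulate_snrnaseq(sn_sim_config(seed = 5))
})

## QC'd + normalized + clustered view of fx_sn
fx_sn_processed <- function() fx("sn_processed", function() {
  sn <- fx_sn()
  qc <- mad_filter_cells(sn$cm)
  cm <- subset_cells(sn$cm, qc$keep)
  pr <- pearson_residuals(cm)
  hvgs <- select_hvgs(pr, threshold = 1.3)
  pcs <- pca_embed(pr, genes = hvgs, n_pcs = 20)
  clusters <- cluster_cells(pcs, seed = 0)
  truth <- sn$truth$cells
  idx <- match(clusters$cell, truth$barcode)
  list(sn = sn, qc = qc, cm = cm, pr = pr, hvgs = hvgs, pcs = pcs,
       clusters = clusters,
       truth_type = truth$cell_type[idx],
       truth_composite = paste(truth$cell_type[idx],
                               ifelse(is.na(truth$clone[idx]), "",
                                      truth$clone[idx])))
})

## single-nuclei cohort linked to the bulk subtypes (for projection and
## interactions); reduced cell counts keep the suite fast
fx_cohort <- function() fx("cohort", function() {
  simulate_sn_cohort(fx_bulk(), samples_per_subtype = 2, cells_scale = 0.5,
                     seed = 3)
})

## tiny deterministic count matrix for I/O tests
toy_count_matrix <- function() {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(1, 2, 2, 1),
                            x = c(5, 1, 2, 7), dims = c(3, 2))
  count_matrix(m, gene_ids = c("g1", "g2", "g3"), barcodes = c("c1", "c2"),
               sample_id = "toy",
               cell_meta = tibble::tibble(barcode = c("c1", "c2"),
                                          doublet_score = c(0.1, 0.2),
                                          mito_fraction = c(0.05, 0.1)))
}

## two separated Gaussian blobs in PC-like space
two_blobs <- function(n = 60, d = 5, sep = 50, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d), n))
    ## centres at +/- sep/sqrt(d) along the diagonal: separation survives
    ## per-dimension standardization and both cosine and euclidean metrics
    x[seq_len(n), ] <- x[seq_len(n), ] + sep / sqrt(d)
    x[n + seq_len(n), ] <- x[n + seq_len(n), ] - sep / sqrt(d)
    rownames(x) <- sprintf("cell%03d", seq_len(2 * n))
    list(x = x, truth = rep(c(1, 2), each = n))
  })
}

## CNV profiles of the small single-nuclei sample
cnv_fixture <- function() fx("cnv", function() {
  sn <- fx_sn()
  tc <- sn$truth$cells
  refs <- tc$barcode[tc$cell_type %in% c("endothelial", "fibroblast", "myeloid") &
                       !tc$is_doublet]
  prof <- infer_cnv_profiles(sn$cm, refs, sn$truth$annotation)
  neo <- tc$barcode[tc$cell_type == "NEO" & !tc$is_doublet & !tc$is_low_depth]
  list(sn = sn, refs = refs, prof = prof, neo = neo)
})


## constructed expression matrix with exact edge-case counts
edge_case_fixture <- function() {
  ## sender type S: 30 cells; receiver type R: 30 cells, two samples
  genes <- c("LIG_OK", "REC_OK", "LIG_10", "REC_LOW", "LIG_1SMP", "SAME")
  n <- 120
  expr <- matrix(0, length(genes), n,
                 dimnames = list(genes, paste0("c", seq_len(n))))
  types <- rep(rep(c("S", "R"), each = 30), 2)
  samples <- rep(c("smp1", "smp2"), each = 60)
  sel <- function(t, s) which(types == t & samples == s)
  for (s in c("smp1", "smp2")) {
    expr["LIG_OK", sel("S", s)[1:20]] <- 2       # 20 cells > 10, rate 0.67
    expr["REC_OK", sel("R", s)[1:20]] <- 3
    expr["LIG_10", sel("S", s)[1:10]] <- 5       # exactly 10 cells: boundary
    expr["REC_LOW", sel("R", s)[1:2]] <- 50      # rate 2/30 < 0.1
    expr["SAME", sel("S", s)[1:20]] <- 1
    expr["SAME", sel("R", s)[1:20]] <- 1
  }
  expr["LIG_1SMP", sel("S", "smp1")[1:20]] <- 4  # present in one sample only
  pairs <- tibble::tibble(
    ligand = c("LIG_OK", "LIG_10", "LIG_OK", "LIG_1SMP", "SAME"),
    receptor = c("REC_OK", "REC_OK", "REC_LOW", "REC_OK", "SAME"))
  list(expr = expr, types = types, samples = samples, pairs = pairs)
}

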