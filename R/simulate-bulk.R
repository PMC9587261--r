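#' Configuration for the synthetic bulk compendium
#'
#' The stated world of the synthetic multi-batch, multi-platform compendium:
#' four expression subtypes named after the PCPG literature (C1A/C1B
#' pseudohypoxic, C2A/C2B kinase/Wnt-altered), two to four driver genotypes
#' mapped to each subtype, three batches of thirty samples (two
#' microarray-like, one RNA-seq-like), per-batch gene missingness, per-gene
#' additive batch shifts, and a monotone platform warp on the RNA-seq batch.
#'
#' @param n_genes Number of genes (default 2000).
#' @param subtypes Subtype names (default C1A, C1B, C2A, C2B).
#' @param genotype_map Named character vector genotype -> subtype.
#' @param batches Tibble/list of batches: `name`, `platform` (`microarray` /
#'   `rnaseq`), `n_samples`, `shift_scale` (SD of per-gene additive batch
#'   shifts), `missing_frac` (fraction of genes absent from the batch).
#' @param de_genes_per_subtype DE genes per subtype (default 50, disjoint).
#' @param de_log2fc Absolute subtype effect in log2 units (default 2).
#' @param noise_sd Residual noise SD (default 0.1).
#' @param fraction_unknown_genotype Fraction of samples with unannotated
#'   genotype (default 0.1).
#' @param stroma_range Range of the per-sample stromal admixture fraction
#'   mixed into every bulk tumor profile (default c(0.1, 0.4)) — bulk tumors
#'   are never pure neoplastic tissue.
#' @param seed RNG seed (default 1).
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_genes = 2000,
                            subtypes = c("C1A", "C1B", "C2A", "C2B"),
                            genotype_map = c(SDHB = "C1A", SDHD = "C1A",
                                             VHL = "C1B", EPAS1 = "C1B",
                                             RET = "C2A", NF1 = "C2A",
                                             HRAS = "C2A", MAML3 = "C2B"),
                            batches = NULL,
                            de_genes_per_subtype = 50, de_log2fc = 2,
                            noise_sd = 0.1, fraction_unknown_genotype = 0.1,
                            stroma_range = c(0.1, 0.4), seed = 1) {
  if (is.null(batches)) {
    batches <- tibble(
      name = c("arrayA", "arrayB", "rnaseqA"),
      platform = c("microarray", "microarray", "rnaseq"),
      n_samples = c(30L, 30L, 30L),
      shift_scale = c(0.5, 0.5, 0.5),
      missing_frac = c(0.05, 0.10, 0.05))
  }
  batches <- as_tibble(batches)
  if (de_genes_per_subtype * length(subtypes) > n_genes)
    stop_config("de_genes_per_subtype x n_subtypes exceeds n_genes")
  if (fraction_unknown_genotype < 0 || fraction_unknown_genotype > 1)
    stop_config("fraction_unknown_genotype outside [0,1]")
  if (any(batches$missing_frac < 0 | batches$missing_frac > 1))
    stop_config("missing_frac outside [0,1]")
  if (any(batches$n_samples <= 0) || n_genes <= 0)
    stop_config("counts must be positive")
  if (!all(genotype_map %in% subtypes))
    stop_config("genotype_map targets unknown subtypes")
  structure(list(n_genes = n_genes, subtypes = subtypes,
                 genotype_map = genotype_map, batches = batches,
                 de_genes_per_subtype = de_genes_per_subtype,
                 de_log2fc = de_log2fc, noise_sd = noise_sd,
                 fraction_unknown_genotype = fraction_unknown_genotype,
                 stroma_range = stroma_range, seed = seed),
            class = "bulk_sim_config")
}

## latent (pre-warp, pre-missingness) expression for a set of samples
bulk_latent_values <- function(truthgenes, base_mu, subtype_vec, stroma_frac,
                               stroma_profile, noise_sd) {
  n_genes <- length(base_mu)
  z <- matrix(base_mu, n_genes, length(subtype_vec))
  for (i in seq_along(subtype_vec)) {
    de <- truthgenes[truthgenes$subtype == subtype_vec[i], ]
    tumor <- z[, i]
    tumor[de$gene_idx] <- tumor[de$gene_idx] + de$sign * de$log2fc
    z[, i] <- (1 - stroma_frac[i]) * tumor + stroma_frac[i] * stroma_profile
  }
  z + matrix(rnorm(length(z), sd = noise_sd), nrow(z))
}

#' Simulate the multi-batch, multi-platform bulk compendium
#'
#' Generates microarray-like batches as continuous log2 intensities and
#' RNA-seq-like batches on a warped (monotone nonlinear, different quantile
#' scale) value scale, with per-gene additive batch shifts, per-batch gene
#' missingness, disjoint subtype DE signatures, a shared stromal profile
#' admixed into every tumor sample, and a stated fraction of samples with
#' unknown genotype. Fully deterministic given the config seed.
#'
#' @param cfg A [bulk_sim_config()].
#' @return List with `bulk` (a [bulk_matrix]) and `truth` (list: `samples`,
#'   `de_genes`, `batch_shifts` genes-by-batches matrix, `base_mu`,
#'   `stroma_profile`, `latent` genes-by-samples matrix before warp,
#'   missingness and batch shifts).
#' @export
simulate_bulk_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  withr::with_seed(cfg$seed, {
    n_genes <- cfg$n_genes
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    base_mu <- rnorm(n_genes, mean = 7, sd = 2)
    subtypes <- cfg$subtypes

    de_idx <- sample.int(n_genes, cfg$de_genes_per_subtype * length(subtypes))
    de_genes <- tibble(
      gene_idx = de_idx,
      gene = gene_ids[de_idx],
      subtype = rep(subtypes, each = cfg$de_genes_per_subtype),
      sign = sample(c(-1, 1), length(de_idx), replace = TRUE),
      log2fc = cfg$de_log2fc)

    ## shared stromal profile: its own signature, away from all tumor subtypes
    stroma_profile <- base_mu + rnorm(n_genes, sd = 1)

    batches <- cfg$batches
    n_total <- sum(batches$n_samples)
    sample_meta <- list(); truth_samples <- list()
    values <- matrix(NA_real_, n_genes, n_total,
                     dimnames = list(gene_ids, NULL))
    latent <- values
    shifts <- matrix(0, n_genes, nrow(batches),
                     dimnames = list(gene_ids, batches$name))
    missing_genes <- list()
    col0 <- 0L
    for (b in seq_len(nrow(batches))) {
      nb <- batches$n_samples[b]
      cols <- col0 + seq_len(nb)
      ## balanced subtype allocation, shuffled
      subtype_vec <- sample(rep_len(subtypes, nb))
      genotype <- vapply(subtype_vec, function(s) {
        cand <- names(cfg$genotype_map)[cfg$genotype_map == s]
        if (length(cand)) sample(cand, 1L) else NA_character_
      }, "")
      stroma_frac <- runif(nb, cfg$stroma_range[1L], cfg$stroma_range[2L])
      z <- bulk_latent_values(de_genes, base_mu, subtype_vec, stroma_frac,
                              stroma_profile, cfg$noise_sd)
      shifts[, b] <- rnorm(n_genes, sd = batches$shift_scale[b])
      z <- z + shifts[, b]
      obs <- if (batches$platform[b] == "rnaseq") 2^(z / 2) else z
      miss <- sample.int(n_genes, floor(batches$missing_frac[b] * n_genes))
      obs[miss, ] <- NA_real_
      missing_genes[[batches$name[b]]] <- gene_ids[miss]
      values[, cols] <- obs
      latent[, cols] <- z
      ids <- sprintf("%s_s%02d", batches$name[b], seq_len(nb))
      unknown <- runif(nb) < cfg$fraction_unknown_genotype
      sample_meta[[b]] <- tibble(
        sample_id = ids, batch = batches$name[b],
        platform = batches$platform[b],
        genotype = ifelse(unknown, NA_character_, genotype),
        subtype = NA_character_)
      truth_samples[[b]] <- tibble(
        sample_id = ids, batch = batches$name[b],
        platform = batches$platform[b], subtype = subtype_vec,
        genotype = genotype, genotype_known = !unknown,
        stroma_fraction = stroma_frac)
      col0 <- col0 + nb
    }
    meta <- bind_rows(sample_meta)
    colnames(values) <- meta$sample_id
    colnames(latent) <- meta$sample_id
    bulk <- bulk_matrix(values, meta)
    list(bulk = bulk,
         truth = list(samples = bind_rows(truth_samples),
                      de_genes = de_genes,
                      batch_shifts = shifts,
                      base_mu = setNames(base_mu, gene_ids),
                      stroma_profile = setNames(stroma_profile, gene_ids),
                      missing_genes = missing_genes,
                      latent = latent))
  })
}

#' Simulate pseudo-bulk-like new samples on the latent bulk model
#'
#' Draws held-out samples from the same latent subtype model (RNA-seq-like
#' warp, no batch shift unless given) for projection tests: each sample is a
#' tumor profile of the requested subtype admixed with the shared stromal
#' profile at `stroma_fraction`.
#'
#' @param sim Output of [simulate_bulk_compendium()].
#' @param subtypes Character vector: the truth subtype of each new sample.
#' @param stroma_fraction Stromal admixture per sample (recycled; default 0).
#' @param batch_shift Scalar or per-gene shift added to every new sample
#'   (default 0).
#' @param noise_sd Residual noise (default: the config value is not stored,
#'   so 0.1).
#' @param missing_frac Fraction of genes set missing (default 0.1).
#' @param seed RNG seed.
#' @return List with `values` (genes-by-samples matrix, warped scale),
#'   `meta` tibble (`sample_id`, `subtype`, `genotype = NA`).
#' @export
simulate_new_bulk_samples <- function(sim, subtypes, stroma_fraction = 0,
                                      batch_shift = 0, noise_sd = 0.1,
                                      missing_frac = 0.1, seed = 99) {
  truth <- sim$truth
  n <- length(subtypes)
  stroma_fraction <- rep_len(stroma_fraction, n)
  withr::with_seed(seed, {
    z <- bulk_latent_values(truth$de_genes, truth$base_mu, subtypes,
                            stroma_fraction, truth$stroma_profile, noise_sd)
    z <- z + batch_shift
    obs <- 2^(z / 2)
    if (missing_frac > 0) {
      miss <- sample.int(nrow(obs), floor(missing_frac * nrow(obs)))
      obs[miss, ] <- NA_real_
    }
    rownames(obs) <- names(truth$base_mu)
    colnames(obs) <- sprintf("new_s%02d", seq_len(n))
    list(values = obs,
         meta = tibble(sample_id = colnames(obs), subtype = subtypes,
                       stroma_fraction = stroma_fraction,
                       genotype = NA_character_))
  })
}
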