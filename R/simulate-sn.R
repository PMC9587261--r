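#' Synthetic gene annotation for the simulator's gene universe
#'
#' Genes are laid out evenly over `n_chrom` chromosomes in id order,
#' 0-based half-open intervals 1 kb apart; the first half of each chromosome
#' is arm `p`, the second `q`. Few, long chromosomes keep planted CNV
#' segments longer than twice the smoothing window at desk scale.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_chrom Number of chromosomes (default 5).
#' @return Annotation tibble as from [read_gene_annotation()].
#' @export
simulate_gene_annotation <- function(gene_ids, n_chrom = 5) {
  n <- length(gene_ids)
  per <- ceiling(n / n_chrom)
  chrom_i <- (seq_len(n) - 1L) %/% per + 1L
  pos_i <- (seq_len(n) - 1L) %% per
  tibble(chrom = sprintf("chr%d", chrom_i),
         start = pos_i * 1000L,
         end = pos_i * 1000L + 500L,
         gene_id = gene_ids,
         strand = "+",
         arm = ifelse(pos_i < per / 2, "p", "q")) |>
    arrange(.data$chrom, .data$start)
}

default_sn_cell_types <- function() {
  tibble(
    name = c("NEO", "sustentacular", "endothelial", "fibroblast",
             "myeloid", "T cells"),
    n_cells = c(1200L, 300L, 450L, 400L, 350L, 300L),
    dispersion = 50,
    mito_mean = c(0.05, 0.05, 0.04, 0.04, 0.06, 0.05),
    depth_factor = c(1, 1, 1, 1, 1, 0.5))
}

#' Configuration for the synthetic single-nuclei sample
#'
#' States the world of one simulated snRNA-seq sample: negative-binomial
#' counts around depth-scaled cell-type centroids (variance
#' `mu + mu^2/dispersion`), lognormal sequencing depth, doublets as mixtures
#' of two cells' rate vectors, ambient contamination toward the dataset mean
#' rate vector, planted QC outliers (high mito fraction, collapsed depth),
#' and clone-specific CNV segments in the neoplastic type.
#'
#' @param n_genes Number of genes (default 2000; ids shared with the bulk
#'   simulator).
#' @param cell_types Tibble: `name`, `n_cells`, `dispersion`, `mito_mean`,
#'   `depth_factor` (default: 6 types, 3000 cells, the small fixture).
#' @param n_markers_per_type Disjoint marker genes per type (default 40).
#' @param marker_fold Rate fold-change of markers (default 8).
#' @param neoplastic_type Which type carries clones / subtype signal
#'   (default "NEO").
#' @param subtype_de Optional tibble (`gene_idx`, `sign`, `log2fc`) folded
#'   into the neoplastic centroid — links a sample to a bulk subtype.
#' @param depth_meanlog,depth_sdlog Lognormal depth (defaults log(15000),
#'   0.3).
#' @param doublet_rate Fraction of barcodes that are doublets (default
#'   0.06).
#' @param ambient_fraction Ambient contamination mixing weight (default
#'   0.05).
#' @param mito_outlier_rate,low_depth_rate Planted QC-outlier fractions
#'   (defaults 0.02 each).
#' @param cnv_clones List of clones: each `list(name, fraction, events)`
#'   with `events` a tibble (`chrom`, `start`, `end`, `fold`). Fractions are
#'   of neoplastic cells and must sum to <= 1. Default: two clones sharing a
#'   chr1 0.5x deletion, the second with an extra chr3 1.5x gain.
#' @param annotation Gene annotation (default
#'   [simulate_gene_annotation()]).
#' @param sample_id Sample identifier (default "sn01").
#' @param seed RNG seed.
#' @param structure_seed Seed for the shared expression structure (base
#'   rates and marker assignment). Samples of a simulated cohort share one
#'   `structure_seed` (so they describe the same transcriptome) while
#'   differing in `seed`; defaults to `seed`.
#' @param reserved_gene_idx Gene indices kept out of the marker pool (a
#'   cohort reserves the union of all subtypes' DE genes); defaults to
#'   `subtype_de$gene_idx`.
#' @return An `sn_sim_config` list.
#' @export
sn_sim_config <- function(n_genes = 2000, cell_types = default_sn_cell_types(),
                          n_markers_per_type = 40, marker_fold = 8,
                          neoplastic_type = "NEO", subtype_de = NULL,
                          depth_meanlog = log(15000), depth_sdlog = 0.3,
                          doublet_rate = 0.06, ambient_fraction = 0.05,
                          mito_outlier_rate = 0.02, low_depth_rate = 0.02,
                          cnv_clones = NULL, annotation = NULL,
                          sample_id = "sn01", seed = 1,
                          structure_seed = seed, reserved_gene_idx = NULL) {
  cell_types <- as_tibble(cell_types)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(annotation)) annotation <- simulate_gene_annotation(gene_ids)
  if (is.null(cnv_clones)) {
    del <- tibble(chrom = "chr1", start = 80000L, end = 330000L, fold = 0.5)
    gain <- tibble(chrom = "chr3", start = 60000L, end = 310000L, fold = 1.5)
    cnv_clones <- list(
      list(name = "clone_A", fraction = 0.6, events = del),
      list(name = "clone_B", fraction = 0.4, events = bind_rows(del, gain)))
  }
  if (doublet_rate < 0 || doublet_rate > 0.5)
    stop_config("doublet_rate outside [0, 0.5]")
  if (ambient_fraction < 0 || ambient_fraction > 0.5)
    stop_config("ambient_fraction outside [0, 0.5]")
  fr <- vapply(cnv_clones, function(cl) cl$fraction, 0)
  if (length(fr) && sum(fr) > 1) stop_config("clone fractions sum above 1")
  for (cl in cnv_clones) {
    ev <- as_tibble(cl$events)
    for (i in seq_len(nrow(ev))) {
      hit <- annotation$chrom == ev$chrom[i] &
        annotation$start >= ev$start[i] & annotation$end <= ev$end[i]
      if (!any(hit))
        stop_config(sprintf("clone event %s:%d-%d covers no annotated gene",
                            ev$chrom[i], ev$start[i], ev$end[i]))
    }
  }
  if (!neoplastic_type %in% cell_types$name)
    stop_config("neoplastic_type not among cell types")
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 cell_types = cell_types,
                 n_markers_per_type = n_markers_per_type,
                 marker_fold = marker_fold,
                 neoplastic_type = neoplastic_type, subtype_de = subtype_de,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 doublet_rate = doublet_rate,
                 ambient_fraction = ambient_fraction,
                 mito_outlier_rate = mito_outlier_rate,
                 low_depth_rate = low_depth_rate,
                 cnv_clones = cnv_clones, annotation = annotation,
                 sample_id = sample_id, seed = seed,
                 structure_seed = structure_seed,
                 reserved_gene_idx = reserved_gene_idx),
            class = "sn_sim_config")
}

## per-type expression rate vectors (columns sum to 1) and marker indices
sn_type_rates <- function(cfg) {
  n <- cfg$n_genes
  types <- cfg$cell_types$name
  ## base rates and marker assignment under the structure seed, so cohort
  ## samples share one transcriptome while count noise differs per sample
  structure_draw <- withr::with_seed(cfg$structure_seed %||% cfg$seed, {
    reserved <- unique(cfg$reserved_gene_idx %||% cfg$subtype_de$gene_idx)
    pool <- setdiff(seq_len(n), reserved)
    list(base = rlnorm(n, meanlog = 0, sdlog = 1),
         markers = split(sample(pool, cfg$n_markers_per_type * length(types)),
                         rep(seq_along(types), each = cfg$n_markers_per_type)))
  })
  base <- structure_draw$base
  markers <- structure_draw$markers
  names(markers) <- types
  rates <- vapply(types, function(t) {
    r <- base
    r[markers[[t]]] <- r[markers[[t]]] * cfg$marker_fold
    if (t == cfg$neoplastic_type && !is.null(cfg$subtype_de)) {
      de <- cfg$subtype_de
      r[de$gene_idx] <- r[de$gene_idx] * 2^(de$sign * de$log2fc)
    }
    r / sum(r)
  }, numeric(n))
  rownames(rates) <- cfg$gene_ids
  list(rates = rates, markers = lapply(markers, function(i) cfg$gene_ids[i]))
}

#' Simulate a single-nuclei RNA-seq sample with ground truth
#'
#' See [sn_sim_config()] for the generative model. Deterministic given the
#' config seed.
#'
#' @param cfg An `sn_sim_config`.
#' @return List with `cm` (a [count_matrix] whose `cell_meta` carries
#'   `doublet_score`, `mito_fraction`, `total_counts`, `lineage_label`) and
#'   `truth` (list: `cells` tibble with per-cell type/doublet/clone/outlier
#'   truth, `segments` planted-CNV tibble, `type_rates`, `markers`,
#'   `annotation`).
#' @export
simulate_snrnaseq <- function(cfg) {
  stopifnot(inherits(cfg, "sn_sim_config"))
  withr::with_seed(cfg$seed, {
    tr <- sn_type_rates(cfg)
    types <- cfg$cell_types
    n_cells <- sum(types$n_cells)
    type_of <- rep(types$name, types$n_cells)
    type_i <- rep(seq_len(nrow(types)), types$n_cells)
    disp <- types$dispersion[type_i]

    ## ambient: population-mean rate vector
    rbar <- as.numeric(tr$rates %*% (types$n_cells / n_cells))
    a <- cfg$ambient_fraction
    rate <- (1 - a) * tr$rates[, type_of, drop = FALSE] + a * rbar

    ## CNV clones within the neoplastic type
    neo <- which(type_of == cfg$neoplastic_type)
    clone_of <- rep(NA_character_, n_cells)
    clone_of[neo] <- "diploid"
    segments <- list()
    if (length(cfg$cnv_clones)) {
      fr <- vapply(cfg$cnv_clones, `[[`, 0, "fraction")
      sizes <- floor(fr * length(neo))
      pool <- sample(neo)
      off <- 0L
      for (ci in seq_along(cfg$cnv_clones)) {
        cl <- cfg$cnv_clones[[ci]]
        cells_cl <- pool[off + seq_len(sizes[ci])]
        off <- off + sizes[ci]
        clone_of[cells_cl] <- cl$name
        ev <- as_tibble(cl$events)
        for (i in seq_len(nrow(ev))) {
          hit <- cfg$annotation$chrom == ev$chrom[i] &
            cfg$annotation$start >= ev$start[i] & cfg$annotation$end <= ev$end[i]
          gidx <- match(cfg$annotation$gene_id[hit], cfg$gene_ids)
          rate[gidx, cells_cl] <- rate[gidx, cells_cl] * ev$fold[i]
          segments[[paste(cl$name, i)]] <- tibble(
            clone = cl$name, chrom = ev$chrom[i], start = ev$start[i],
            end = ev$end[i], fold = ev$fold[i], n_genes = sum(hit),
            genes = list(cfg$annotation$gene_id[hit]))
        }
      }
    }

    ## depth, planted QC outliers
    depth <- rlnorm(n_cells, cfg$depth_meanlog, cfg$depth_sdlog) *
      types$depth_factor[type_i]
    low_depth <- runif(n_cells) < cfg$low_depth_rate
    depth[low_depth] <- depth[low_depth] * 0.05
    mito <- pmin(pmax(rnorm(n_cells, types$mito_mean[type_i], 0.015), 0.001), 0.97)
    mito_out <- runif(n_cells) < cfg$mito_outlier_rate
    mito[mito_out] <- runif(sum(mito_out), 0.35, 0.7)

    ## doublets: mixture of own and a partner cell's rate vector
    is_doublet <- runif(n_cells) < cfg$doublet_rate
    partner <- rep(NA_integer_, n_cells)
    if (any(is_doublet)) {
      partner[is_doublet] <- sample.int(n_cells, sum(is_doublet), replace = TRUE)
      rate[, is_doublet] <- (rate[, is_doublet, drop = FALSE] +
                               rate[, partner[is_doublet], drop = FALSE]) / 2
      depth[is_doublet] <- depth[is_doublet] * 1.5
    }

    mu <- rate * rep(depth, each = cfg$n_genes)
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = rep(disp, each = cfg$n_genes)),
                     nrow = cfg$n_genes)
    barcodes <- sprintf("%s_c%04d", cfg$sample_id, seq_len(n_cells))
    dimnames(counts) <- list(cfg$gene_ids, barcodes)

    dscore <- plogis(rnorm(n_cells, mean = ifelse(is_doublet, 2.5, -2.5), sd = 0.8))
    meta <- tibble(barcode = barcodes,
                   doublet_score = dscore,
                   mito_fraction = mito,
                   total_counts = as.integer(colSums(counts)),
                   lineage_label = type_of)
    cm <- count_matrix(counts, sample_id = cfg$sample_id, cell_meta = meta)
    truth_cells <- tibble(
      barcode = barcodes, cell_type = type_of,
      partner_type = ifelse(is_doublet, type_of[partner], NA_character_),
      is_doublet = is_doublet, clone = clone_of,
      is_mito_outlier = mito_out, is_low_depth = low_depth,
      depth = depth)
    list(cm = cm,
         truth = list(cells = truth_cells,
                      segments = if (length(segments)) bind_rows(segments) else tibble(),
                      type_rates = tr$rates, markers = tr$markers,
                      annotation = cfg$annotation))
  })
}

#' Reference centroids and marker gene sets matched to the simulator
#'
#' With `n_cells = 0` (default) the centroids are the noiseless
#' log-normalized transform of the simulator's configured type rates;
#' with `n_cells > 0` a reference cohort is simulated per type and collapsed
#' with [build_centroids()].
#'
#' @param sim Output of [simulate_snrnaseq()] (uses `truth$type_rates`).
#' @param n_cells Reference cells per type (default 0 = noiseless).
#' @param n_marker_genes Marker genes per type for the matched gene sets
#'   (default 40); must not exceed the gene universe.
#' @param scale_factor Log-normalization scale (default 10,000).
#' @param dispersion NB dispersion for the noisy branch (default 50).
#' @param depth Reference depth for the noisy branch (default 15,000).
#' @param seed RNG seed.
#' @return List with `centroids` (genes-by-types matrix) and `gene_sets`
#'   (named list of marker ids, truth-labelled by type).
#' @export
simulate_reference_centroids <- function(sim, n_cells = 0, n_marker_genes = 40,
                                         scale_factor = 10000, dispersion = 50,
                                         depth = 15000, seed = 1) {
  rates <- sim$truth$type_rates
  if (n_marker_genes > nrow(rates))
    stop_config("n_marker_genes exceeds the gene universe")
  centroids <- if (n_cells == 0) {
    log1p(scale_factor * rates)
  } else {
    withr::with_seed(seed, {
      counts <- do.call(cbind, lapply(colnames(rates), function(t) {
        mu <- rates[, t] * depth
        matrix(rnbinom(nrow(rates) * n_cells, mu = mu, size = dispersion),
               nrow = nrow(rates))
      }))
      rownames(counts) <- rownames(rates)
      colnames(counts) <- sprintf("ref_c%04d", seq_len(ncol(counts)))
      labels <- rep(colnames(rates), each = n_cells)
      cm <- count_matrix(counts, sample_id = "reference")
      build_centroids(lognormalize(cm, scale_factor), labels)
    })
  }
  ## marker sets: top genes by rate ratio vs the mean of the other types
  gene_sets <- lapply(colnames(rates), function(t) {
    other <- rowMeans(rates[, setdiff(colnames(rates), t), drop = FALSE])
    ratio <- rates[, t] / pmax(other, .Machine$double.eps)
    names(sort(ratio, decreasing = TRUE))[seq_len(n_marker_genes)]
  })
  names(gene_sets) <- colnames(rates)
  list(centroids = centroids, gene_sets = gene_sets)
}

#' Ligand-receptor pair table with planted sender-to-receiver signals
#'
#' Planted pairs take their ligand from the sender type's marker genes and
#' their receptor from the receiver type's markers, so the planted edge
#' carries elevated expression in the designated direction; decoy pairs are
#' drawn from non-marker background genes.
#'
#' @param sim Output of [simulate_snrnaseq()].
#' @param sender,receiver Cell-type names (defaults "sustentacular" ->
#'   "NEO", the SCLC-to-tumor axis).
#' @param n_planted,n_decoys Pair counts (defaults 8, 40).
#' @param seed RNG seed.
#' @return Tibble: `ligand`, `receptor`, `planted`, `sender`, `receiver`.
#' @export
simulate_lr_pairs <- function(sim, sender = "sustentacular", receiver = "NEO",
                              n_planted = 8, n_decoys = 40, seed = 1) {
  markers <- sim$truth$markers
  if (!sender %in% names(markers) || !receiver %in% names(markers))
    stop_config("sender/receiver not among simulated cell types")
  withr::with_seed(seed, {
    lig <- sample(markers[[sender]], n_planted)
    rec <- sample(markers[[receiver]], n_planted)
    background <- setdiff(rownames(sim$truth$type_rates), unlist(markers))
    dec <- matrix(sample(background, 2 * n_decoys), ncol = 2)
    bind_rows(
      tibble(ligand = lig, receptor = rec, planted = TRUE,
             sender = sender, receiver = receiver),
      tibble(ligand = dec[, 1L], receptor = dec[, 2L], planted = FALSE,
             sender = NA_character_, receiver = NA_character_)) |>
      filter(.data$ligand != .data$receptor)
  })
}

#' Simulate per-sample cell-type composition counts for abundance testing
#'
#' Two groups of samples draw their cell-type composition from a Dirichlet
#' distribution (sampled as normalized Gammas) around group-level
#' proportions; the second group's `enriched_type` proportion is multiplied
#' by `fold` before renormalization. The `concentration` parameter sets the
#' realistic between-sample compositional noise of tumor tissue.
#'
#' @param n_per_group Samples per group (default 8).
#' @param base_props Named baseline proportions (default: the small
#'   fixture's six types, endothelial at 5%).
#' @param enriched_type Type enriched in group B (default "endothelial").
#' @param fold Enrichment factor (default 3).
#' @param total_cells Nuclei per sample (default 600).
#' @param concentration Dirichlet concentration (default 100, chosen a
#'   priori so the logit-scale noise (~0.45 SD for a 5% type, a ~40%
#'   compositional CV) leaves the planted log(3) effect detectable at n=8
#'   per group while keeping null types' compositional displacement well
#'   inside the noise).
#' @param seed RNG seed.
#' @return List: `counts` (samples-by-types matrix), `groups`, and
#'   `enriched_type`.
#' @export
simulate_abundance_counts <- function(n_per_group = 8,
                                      base_props = c(NEO = 0.52,
                                                     sustentacular = 0.08,
                                                     endothelial = 0.05,
                                                     fibroblast = 0.12,
                                                     myeloid = 0.15,
                                                     `T cells` = 0.08),
                                      enriched_type = "endothelial",
                                      fold = 3, total_cells = 600,
                                      concentration = 100, seed = 1) {
  if (!enriched_type %in% names(base_props))
    stop_config("enriched_type not among base_props")
  withr::with_seed(seed, {
    pA <- base_props / sum(base_props)
    pB <- pA
    pB[enriched_type] <- pB[enriched_type] * fold
    pB <- pB / sum(pB)
    draw <- function(p, n) {
      t(vapply(seq_len(n), function(i) {
        g <- stats::rgamma(length(p), shape = p * concentration)
        as.numeric(stats::rmultinom(1, total_cells, g / sum(g)))
      }, numeric(length(p))))
    }
    counts <- rbind(draw(pA, n_per_group), draw(pB, n_per_group))
    dimnames(counts) <- list(sprintf("s%02d", seq_len(2 * n_per_group)),
                             names(base_props))
    list(counts = counts,
         groups = rep(c("A", "B"), each = n_per_group),
         enriched_type = enriched_type)
  })
}
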