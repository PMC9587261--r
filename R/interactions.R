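#' Compute ligand-receptor edge weights per sample and cell-type pair
#'
#' For every (sample, sender type, receiver type, ligand-receptor pair):
#' the ligand's mean CPM over sender cells, the receptor's mean CPM over
#' receiver cells, expressing-cell counts (CPM > 0), detection rates, and
#' the edge weight = product of the two means (the "total expression"
#' weight family).
#'
#' @param expr Genes-by-cells CPM matrix (or sparse Matrix).
#' @param cell_types Per-cell type labels.
#' @param pairs Ligand-receptor pair tibble ([read_lr_pairs()]).
#' @param samples Per-cell sample ids (single sample assumed if `NULL`).
#' @return An `edge_table` tibble: `sample`, `sender`, `receiver`, `ligand`,
#'   `receptor`, `ligand_mean`, `receptor_mean`, `ligand_cells`,
#'   `receptor_cells`, `ligand_rate`, `receptor_rate`, `weight`.
#' @export
compute_edge_weights <- function(expr, cell_types, pairs, samples = NULL) {
  cell_types <- as.character(cell_types)
  if (any(is.na(cell_types))) stop_validation("every cell must be typed")
  if (length(cell_types) != ncol(expr))
    stop_validation("one cell type per column required")
  samples <- samples %||% rep("sample", ncol(expr))
  pairs <- as_tibble(pairs)
  genes <- rownames(expr)
  usable <- pairs$ligand %in% genes & pairs$receptor %in% genes
  if (any(!usable))
    inform(sprintf("%d pair(s) with absent gene(s) skipped", sum(!usable)))
  pairs <- pairs[usable, , drop = FALSE]
  pair_genes <- unique(c(pairs$ligand, pairs$receptor))

  out <- list()
  for (smp in unique(samples)) {
    in_smp <- samples == smp
    types <- sort(unique(cell_types[in_smp]))
    ## per-type mean expression, expressing-cell count and detection rate
    stats_by_type <- lapply(types, function(t) {
      cols <- in_smp & cell_types == t
      sub <- expr[pair_genes, cols, drop = FALSE]
      list(mean = Matrix::rowMeans(sub),
           cells = Matrix::rowSums(sub > 0),
           rate = Matrix::rowMeans(sub > 0),
           n = sum(cols))
    })
    names(stats_by_type) <- types
    grid <- tidyr::expand_grid(sender = types, receiver = types,
                               pair = seq_len(nrow(pairs)))
    lig <- pairs$ligand[grid$pair]; rec <- pairs$receptor[grid$pair]
    lmean <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$sender[i]]]$mean[[lig[i]]], 0)
    rmean <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$receiver[i]]]$mean[[rec[i]]], 0)
    lcells <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$sender[i]]]$cells[[lig[i]]], 0)
    rcells <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$receiver[i]]]$cells[[rec[i]]], 0)
    lrate <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$sender[i]]]$rate[[lig[i]]], 0)
    rrate <- vapply(seq_len(nrow(grid)), function(i)
      stats_by_type[[grid$receiver[i]]]$rate[[rec[i]]], 0)
    out[[smp]] <- tibble(
      sample = smp, sender = grid$sender, receiver = grid$receiver,
      ligand = lig, receptor = rec,
      ligand_mean = lmean, receptor_mean = rmean,
      ligand_cells = lcells, receptor_cells = rcells,
      ligand_rate = lrate, receptor_rate = rrate,
      weight = lmean * rmean)
  }
  out <- bind_rows(out)
  class(out) <- c("edge_table", class(out))
  out
}

#' Filter a ligand-receptor edge table
#'
#' Keeps edges where ligand and receptor are each expressed in strictly more
#' than `min_expressing_cells` cells and both detection rates are at least
#' `min_detection_rate`; drops autocrine edges (sender = receiver) and
#' same-gene pairs; finally drops (sender, receiver, ligand, receptor)
#' combinations seen in fewer than `min_samples` samples.
#'
#' @param et An `edge_table`.
#' @param min_expressing_cells Strict lower bound on expressing cells
#'   (default 10, i.e. > 10 cells required).
#' @param min_detection_rate Minimum detection rate (default 0.1).
#' @param min_samples Minimum samples carrying the edge (default 2).
#' @param drop_autocrine,drop_same_gene Defaults TRUE.
#' @return Filtered `edge_table`.
#' @export
filter_edges <- function(et, min_expressing_cells = 10, min_detection_rate = 0.1,
                         min_samples = 2, drop_autocrine = TRUE,
                         drop_same_gene = TRUE) {
  out <- filter(et,
                .data$ligand_cells > min_expressing_cells,
                .data$receptor_cells > min_expressing_cells,
                .data$ligand_rate >= min_detection_rate,
                .data$receptor_rate >= min_detection_rate)
  if (drop_autocrine) out <- filter(out, .data$sender != .data$receiver)
  if (drop_same_gene) out <- filter(out, .data$ligand != .data$receptor)
  out <- group_by(out, .data$sender, .data$receiver, .data$ligand, .data$receptor) |>
    filter(dplyr::n_distinct(.data$sample) >= min_samples) |>
    ungroup()
  class(out) <- c("edge_table", class(tibble()))
  out
}

#' Aggregate filtered edges per cell-type pair
#'
#' Per ordered (sender, receiver) pair: mean weight across samples, the
#' number of distinct edges, and the percentage of all edges (summing to 100
#' over pairs). The result is exportable as a chord-diagram table.
#'
#' @param et A filtered `edge_table`.
#' @return Tibble: `sender`, `receiver`, `mean_weight`, `n_edges`,
#'   `pct_edges`.
#' @export
aggregate_edge_summary <- function(et) {
  if (nrow(et) == 0L)
    return(tibble(sender = character(), receiver = character(),
                  mean_weight = numeric(), n_edges = integer(),
                  pct_edges = numeric()))
  summarise(group_by(et, .data$sender, .data$receiver),
            mean_weight = mean(.data$weight),
            n_edges = dplyr::n(), .groups = "drop") |>
    mutate(pct_edges = 100 * .data$n_edges / sum(.data$n_edges))
}
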