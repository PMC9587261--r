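## broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a batch model into one row per gene and coefficient
#' @param x A `batch_model`.
#' @param ... Unused.
#' @return Tibble: `gene`, `term` (`intercept`, `batch:<b>`,
#'   `genotype:<g>`), `estimate`.
#' @method tidy batch_model
#' @export
tidy.batch_model <- function(x, ...) {
  bind_rows(
    tibble(gene = names(x$mu), term = "intercept", estimate = unname(x$mu)),
    tidyr::pivot_longer(
      as_tibble(x$beta, rownames = "gene"),
      -"gene", names_to = "term", values_to = "estimate") |>
      mutate(term = paste0("batch:", .data$term)),
    tidyr::pivot_longer(
      as_tibble(x$gamma, rownames = "gene"),
      -"gene", names_to = "term", values_to = "estimate") |>
      mutate(term = paste0("genotype:", .data$term))
  ) |> filter(!is.na(.data$estimate))
}

#' One-row summary of a batch model
#' @param x A `batch_model`.
#' @param ... Unused.
#' @method glance batch_model
#' @export
glance.batch_model <- function(x, ...) {
  tibble(n_genes = length(x$mu), n_fitted = sum(x$fitted),
         n_aliased = sum(x$aliased), n_batches = length(x$batches),
         n_zero_weight = sum(x$weights == 0),
         reference_genotype = x$reference_genotype)
}

#' Tidy a consensus-clustering result into the PAC curve
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return Tibble `k`, `pac`.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(k = as.integer(names(x$pac)), pac = unname(x$pac))
}

#' One-row summary of a consensus-clustering result
#' @param x A `consensus_result`.
#' @param ... Passed to [select_k_pac()].
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  k <- select_k_pac(x, ...)
  tibble(selected_k = as.integer(k), no_plateau = attr(k, "no_plateau"),
         reps = x$params$reps, maxK = x$params$maxK,
         distance = x$params$distance)
}

#' One-row summary of a differential-expression result
#' @param x A `de_result`.
#' @param lfc,fdr Significance thresholds (defaults 0.5, 0.05).
#' @param ... Unused.
#' @method glance de_result
#' @export
glance.de_result <- function(x, lfc = 0.5, fdr = 0.05, ...) {
  tibble(n_genes = dplyr::n_distinct(x$gene),
         n_contrasts = dplyr::n_distinct(x$contrast),
         n_significant = nrow(threshold_de(x, lfc = lfc, fdr = fdr)),
         d0 = attr(x, "d0")[1L])
}

#' PAC curve plot
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$pac)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "PAC",
                  title = "Proportion of ambiguously clustered pairs") +
    ggplot2::theme_minimal()
}

#' Bulk embedding scatter plot
#' @param object An `embedding_bundle`.
#' @param labels Optional per-sample labels to colour by.
#' @param ... Unused.
#' @method autoplot embedding_bundle
#' @export
autoplot.embedding_bundle <- function(object, labels = NULL, ...) {
  df <- as_tibble(object$embedding, rownames = "sample_id")
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$umap_1, y = .data$umap_2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2")
  if (is.null(labels)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
}

#' Mean CNV profile plot along the genome
#' @param object A `cnv_profile`.
#' @param cells Optional subset of cells to average (default: non-reference).
#' @param ... Unused.
#' @method autoplot cnv_profile
#' @export
autoplot.cnv_profile <- function(object, cells = NULL, ...) {
  cells <- cells %||% setdiff(rownames(object$profile), object$reference_cells)
  df <- tibble(position = seq_len(ncol(object$profile)),
               chrom = object$genes$chrom,
               value = colMeans(object$profile[cells, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$chrom)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "genomic position (gene order)",
                  y = "mean modified expression") +
    ggplot2::theme_minimal()
}

#' Cell-type-pair signaling summary plot
#' @param summary Output of [aggregate_edge_summary()].
#' @return A ggplot heat tile of edge percentages by sender/receiver.
#' @export
plot_edge_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$receiver, y = .data$sender,
                                        fill = .data$pct_edges)) +
    ggplot2::geom_tile() +
    ggplot2::labs(fill = "% of edges") +
    ggplot2::theme_minimal()
}
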