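#' Expression-inferred copy-number profiles
#'
#' The windowed-mean core of expression-based CNV inference: putative
#' neoplastic cells are contrasted against diploid reference cells.
#' Pipeline: restrict to genes with mean count >= `expression_floor` across
#' all cells; transform to `log2(1 + CPM/10)`; subtract the per-gene
#' reference mean; cap values at `±cap_sd` reference SDs; order genes
#' genomically; centred moving average of width `window` within each
#' chromosome (odd window, symmetric, shrunk at chromosome edges); re-centre
#' each cell by its median value. HMM denoising layers of the published tool
#' are deliberately out of scope.
#'
#' @param cm A [count_matrix] containing reference and query cells.
#' @param reference_cells Barcodes of diploid reference cells (>= 30).
#' @param annot Gene annotation tibble ([read_gene_annotation()]).
#' @param window Odd smoothing window in genes (default 101).
#' @param cap_sd Cap in reference-SD units (default 3).
#' @param expression_floor Mean-count floor for gene inclusion (default 0.1).
#' @return A `cnv_profile`: list with `profile` (cells-by-genes, genomic
#'   order), `genes` (annotation of used genes), `reference_cells`, `window`.
#' @export
infer_cnv_profiles <- function(cm, reference_cells, annot, window = 101,
                               cap_sd = 3, expression_floor = 0.1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (window %% 2L == 0L) stop_parameter("window must be odd")
  if (length(reference_cells) < 30L)
    stop_validation("need at least 30 reference cells")
  if (!all(reference_cells %in% colnames(cm$counts)))
    stop_validation("unknown reference barcodes")
  counts <- cm$counts
  mean_count <- Matrix::rowMeans(counts)
  expressed <- rownames(counts)[mean_count >= expression_floor]
  ann <- annot[annot$gene_id %in% expressed, , drop = FALSE]
  n_dropped <- length(expressed) - nrow(ann)
  if (n_dropped > 0)
    inform(sprintf("%d expressed gene(s) without annotation dropped", n_dropped))
  if (nrow(ann) == 0L) stop_validation("no expressed genes carry annotation")
  ann <- arrange(ann, .data$chrom, .data$start)
  genes <- ann$gene_id

  totals <- Matrix::colSums(counts)
  x <- t(as.matrix(counts[genes, , drop = FALSE]))    # cells x genes
  x <- log2(1 + (x / totals) * 1e5)                   # log2(1 + CPM/10)
  is_ref <- rownames(x) %in% reference_cells
  ref_mean <- colMeans(x[is_ref, , drop = FALSE])
  ref_sd <- apply(x[is_ref, , drop = FALSE], 2L, sd)
  x <- sweep(x, 2L, ref_mean)
  cap <- cap_sd * pmax(ref_sd, .Machine$double.eps)
  x <- pmin(pmax(x, rep(-cap, each = nrow(x))), rep(cap, each = nrow(x)))

  ## smooth within chromosomes
  for (ch in unique(ann$chrom)) {
    cols <- which(ann$chrom == ch)
    x[, cols] <- running_mean_cols(x[, cols, drop = FALSE], window)
  }
  x <- x - apply(x, 1L, median)
  structure(list(profile = x, genes = ann,
                 reference_cells = reference_cells, window = window),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d cells x %d genes, window %d, %d reference cells\n",
              nrow(x$profile), ncol(x$profile), x$window,
              length(x$reference_cells)))
  invisible(x)
}

#' Detect tumor subclones from CNV profiles
#'
#' Ward hierarchical clustering (Euclidean distance on windowed profiles) of
#' the non-reference cells, cut at `k` clusters or at `height`.
#'
#' @param profile A `cnv_profile`.
#' @param cells Barcodes to cluster (default: all non-reference cells).
#' @param k Number of clones (exclusive with `height`).
#' @param height Dendrogram cut height (exclusive with `k`).
#' @return A `clone_assignment`: tibble `cell`, `clone` plus attribute
#'   `clone_profiles` (clone-by-gene mean profile matrix).
#' @export
call_subclones <- function(profile, cells = NULL, k = NULL, height = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!is.null(k) && !is.null(height))
    stop_parameter("give either k or height, not both")
  if (is.null(k) && is.null(height)) k <- 2L
  cells <- cells %||% setdiff(rownames(profile$profile), profile$reference_cells)
  if (length(cells) < 20L) stop_validation("need at least 20 non-reference cells")
  m <- profile$profile[cells, , drop = FALSE]
  hc <- hclust(dist(m), method = "ward.D2")
  cl <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = height)
  prof <- t(vapply(sort(unique(cl)), function(g)
    colMeans(m[cl == g, , drop = FALSE]), numeric(ncol(m))))
  rownames(prof) <- paste0("clone_", sort(unique(cl)))
  out <- tibble(cell = cells, clone = as.integer(cl))
  attr(out, "clone_profiles") <- prof
  attr(out, "genes") <- profile$genes
  class(out) <- c("clone_assignment", class(out))
  out
}

#' Summarize clone CNV profiles into chromosome-arm event calls
#'
#' Per clone and chromosome arm, the mean modified expression is thresholded
#' into loss / neutral / gain calls. Expression-inferred loss is reported as
#' copy loss, not LOH: expression cannot distinguish copy-neutral LOH.
#'
#' @param clones A `clone_assignment` from [call_subclones()].
#' @param annot Gene annotation with an `arm` column (defaults to the
#'   annotation carried by `clones`).
#' @param loss_threshold,gain_threshold Call thresholds (defaults -0.05,
#'   0.05).
#' @return Tibble: `clone`, `chrom`, `arm`, `mean_expression`, `call`.
#' @export
summarize_arm_events <- function(clones, annot = NULL, loss_threshold = -0.05,
                                 gain_threshold = 0.05) {
  prof <- attr(clones, "clone_profiles")
  ann <- annot %||% attr(clones, "genes")
  if (is.null(prof)) stop_validation("clone profiles missing")
  ann <- ann[match(colnames(prof), ann$gene_id), ]
  arm_key <- paste(ann$chrom, ifelse(is.na(ann$arm), ".", ann$arm))
  purrr::map_dfr(seq_len(nrow(prof)), function(i) {
    means <- tapply(prof[i, ], arm_key, mean)
    tibble(clone = rownames(prof)[i],
           chrom = sub(" .*$", "", names(means)),
           arm = sub("^.* ", "", names(means)),
           mean_expression = as.numeric(means),
           call = dplyr::case_when(
             means < loss_threshold ~ "loss",
             means > gain_threshold ~ "gain",
             TRUE ~ "neutral"))
  })
}
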