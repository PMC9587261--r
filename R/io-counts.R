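#' Construct a single-nuclei count matrix object
#'
#' The substrate of the single-nuclei side of the pipeline: a sparse
#' genes-by-cells matrix of non-negative integer UMI counts with per-cell
#' metadata (doublet score, mitochondrial fraction, total counts, optional
#' lineage label).
#'
#' @param counts A genes-by-cells matrix coercible to [Matrix::sparseMatrix];
#'   non-negative integers.
#' @param gene_ids,barcodes Unique character identifiers for rows / columns.
#' @param sample_id Single sample identifier string.
#' @param cell_meta Optional tibble with one row per barcode. Recognised
#'   columns: `doublet_score`, `mito_fraction` (in \[0,1\]), `total_counts`,
#'   `lineage_label`. `total_counts` is filled from the matrix if absent.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts),
                         sample_id = "sample", cell_meta = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop_validation("count matrix has negative entries")
  if (any(counts@x != round(counts@x))) stop_format("count matrix has non-integer values")
  if (is.null(gene_ids) || is.null(barcodes))
    stop_validation("gene_ids and barcodes are required")
  gene_ids <- as.character(gene_ids); barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts) || length(barcodes) != ncol(counts))
    stop_validation("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop_validation("duplicate gene_ids")
  if (anyDuplicated(barcodes)) stop_validation("duplicate barcodes")
  dimnames(counts) <- list(gene_ids, barcodes)
  if (is.null(cell_meta)) cell_meta <- tibble(barcode = barcodes)
  cell_meta <- as_tibble(cell_meta)
  if (!"barcode" %in% names(cell_meta)) cell_meta$barcode <- barcodes
  if (nrow(cell_meta) != length(barcodes) ||
      !setequal(cell_meta$barcode, barcodes))
    stop_validation("cell_meta rows do not align 1:1 with barcodes")
  cell_meta <- cell_meta[match(barcodes, cell_meta$barcode), ]
  if (!"total_counts" %in% names(cell_meta))
    cell_meta$total_counts <- as.integer(round(Matrix::colSums(counts)))
  if ("mito_fraction" %in% names(cell_meta)) {
    mf <- cell_meta$mito_fraction
    if (any(!is.na(mf) & (mf < 0 | mf > 1)))
      stop_validation("mito_fraction outside [0,1]")
  }
  structure(list(counts = counts, sample_id = sample_id, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, sample '%s'\n",
              nrow(x$counts), ncol(x$counts), x$sample_id))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a Matrix Market count matrix with features and barcodes sidecars
#'
#' @param mtx_path Path to a Matrix Market triplet file (1-based indices).
#' @param features_path,barcodes_path One identifier per line (TSV; first
#'   column used).
#' @param meta_path Optional per-cell metadata TSV with a `barcode` column.
#' @param sample_id Sample identifier to attach.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path,
                              meta_path = NULL, sample_id = "sample") {
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop_format(
                  sprintf("failed to parse MTX file '%s': %s", mtx_path, conditionMessage(e))))
  read_ids <- function(path) {
    lines <- readLines(path)
    vapply(strsplit(lines, "\t"), function(f) f[[1L]], "")
  }
  feats <- read_ids(features_path)
  bcs <- read_ids(barcodes_path)
  if (length(feats) != nrow(m))
    stop_format(sprintf("features file '%s' has %d lines but MTX declares %d rows",
                        features_path, length(feats), nrow(m)))
  if (length(bcs) != ncol(m))
    stop_format(sprintf("barcodes file '%s' has %d lines but MTX declares %d columns",
                        barcodes_path, length(bcs), ncol(m)))
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
    if (!"barcode" %in% names(meta))
      stop_metadata(sprintf("metadata file '%s' lacks a 'barcode' column", meta_path))
  }
  count_matrix(m, gene_ids = feats, barcodes = bcs, sample_id = sample_id,
               cell_meta = meta)
}

#' Write a count matrix as MTX + features.tsv + barcodes.tsv (+ cell_meta.tsv)
#'
#' @param cm A [count_matrix].
#' @param dir_path Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_count_matrix <- function(cm, dir_path) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(grepl("[\t\n]", c(rownames(cm$counts), colnames(cm$counts)))))
    stop_validation("gene ids / barcodes must not contain tabs or newlines")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir_path)) stop_io(sprintf("cannot create directory '%s'", dir_path))
  paths <- c(mtx = file.path(dir_path, "matrix.mtx"),
             features = file.path(dir_path, "features.tsv"),
             barcodes = file.path(dir_path, "barcodes.tsv"),
             meta = file.path(dir_path, "cell_meta.tsv"))
  Matrix::writeMM(cm$counts, paths[["mtx"]])
  writeLines(rownames(cm$counts) %||% character(), paths[["features"]])
  writeLines(colnames(cm$counts) %||% character(), paths[["barcodes"]])
  readr::write_tsv(cm$cell_meta, paths[["meta"]], progress = FALSE)
  invisible(paths)
}
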