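#' Construct a bulk expression matrix object
#'
#' The compendium substrate: a genes-by-samples matrix of continuous
#' expression values where `NA` marks missing entries, plus per-sample
#' metadata. Missingness is constrained to be per gene-by-batch: a gene is
#' either fully present or fully absent within a batch. Partial missingness
#' is promoted to whole-batch missingness with a warning, because the batch
#' model and blockwise differential expression assume gene-by-batch blocks.
#'
#' @param values Numeric genes-by-samples matrix, `NA` = missing.
#' @param sample_meta Tibble with one row per sample; must contain
#'   `sample_id` and `batch`; recognised columns: `platform` (one of
#'   `"microarray"`, `"rnaseq"`, `"pseudobulk"`), `genotype`, `subtype`,
#'   `metastatic`, `replicate_group`.
#' @param promote_partial_missingness Enforce the per gene-by-batch
#'   missingness invariant by promotion (default `TRUE`).
#' @return An object of class `bulk_matrix`.
#' @export
bulk_matrix <- function(values, sample_meta, promote_partial_missingness = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_meta <- as_tibble(sample_meta)
  if (!all(c("sample_id", "batch") %in% names(sample_meta)))
    stop_metadata("sample_meta must contain 'sample_id' and 'batch' columns")
  if (is.null(rownames(values))) stop_validation("values must have gene rownames")
  if (is.null(colnames(values))) colnames(values) <- sample_meta$sample_id
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop_validation(sprintf("duplicate gene ids: %s",
                            paste(head(dups, 5), collapse = ", ")))
  }
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta))
    stop_metadata(sprintf("samples absent from metadata: %s",
                          paste(head(missing_meta, 5), collapse = ", ")))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (any(is.na(sample_meta$batch))) stop_metadata("every sample needs a batch")
  if (promote_partial_missingness) {
    for (b in unique(sample_meta$batch)) {
      cols <- which(sample_meta$batch == b)
      na_cnt <- rowSums(is.na(values[, cols, drop = FALSE]))
      partial <- na_cnt > 0 & na_cnt < length(cols)
      if (any(partial)) {
        warn(sprintf("%d gene(s) partially missing in batch '%s'; promoted to fully missing",
                     sum(partial), b), class = "pcpg_promotion_warning")
        values[partial, cols] <- NA_real_
      }
    }
  }
  structure(list(values = values, sample_meta = sample_meta), class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("<bulk_matrix> %d genes x %d samples, %d batch(es), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$batch)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.bulk_matrix <- function(x) dim(x$values)

#' Read a bulk expression table plus sample metadata
#'
#' @param path Expression TSV/CSV: first column gene ids, header sample ids.
#' @param meta_path Metadata TSV/CSV with one row per sample (`sample_id`,
#'   `batch`, ...).
#' @return A [bulk_matrix]; empty/NA cells become missing-mask entries and the
#'   per gene-by-batch missingness invariant is enforced by promotion.
#' @export
read_bulk_table <- function(path, meta_path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  meta_reader <- if (grepl("\\.csv$", meta_path)) readr::read_csv else readr::read_tsv
  meta <- meta_reader(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!"batch" %in% names(meta)) stop_metadata("metadata lacks a 'batch' column")
  if (!"sample_id" %in% names(meta)) stop_metadata("metadata lacks a 'sample_id' column")
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  bulk_matrix(vals, meta)
}

#' Write a bulk matrix as expression + metadata TSVs
#' @param bm A [bulk_matrix].
#' @param path,meta_path Output TSV paths.
#' @export
write_bulk_table <- function(bm, path, meta_path) {
  tab <- bind_cols(tibble(gene_id = rownames(bm$values)),
                   as_tibble(bm$values, .name_repair = "minimal"))
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(bm$sample_meta, meta_path, progress = FALSE)
  invisible(c(path, meta_path))
}

#' Read a BED-like gene annotation
#'
#' Columns: chrom, start, end, gene_id and optionally strand and chromosome
#' arm (`p`/`q`). Coordinates are 0-based half-open and preserved as such;
#' the returned table is sorted by (chromosome, start).
#'
#' @param bed_path Path to a tab-separated BED-like file (no header).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `arm`.
#' @export
read_gene_annotation <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[ \t]+")
  n_f <- lengths(fields)
  if (any(n_f < 4L))
    stop_format(sprintf("line %d: expected at least 4 fields", which(n_f < 4L)[1L]))
  ann <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    gene_id = vapply(fields, `[[`, "", 4L),
    strand = vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else ".", ""),
    arm = vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else NA_character_, "")
  )
  bad_coord <- which(is.na(ann$start) | is.na(ann$end) | ann$end <= ann$start | ann$start < 0)
  if (length(bad_coord))
    stop_coordinate(sprintf("line %d: invalid interval (end <= start or non-numeric)",
                            bad_coord[1L]))
  if (anyDuplicated(ann$gene_id))
    stop_validation("duplicate gene_id records in annotation")
  if (!all(ann$strand %in% c("+", "-", ".")))
    stop_format("strand must be one of +, -, .")
  arrange(ann, .data$chrom, .data$start)
}

#' Read a GMT gene-set collection
#' @param path GMT file: name, description, then gene ids, tab-separated.
#' @return Named list of unique gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) stop_format("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_validation("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a two-column ligand-receptor pair table
#' @param path TSV with columns `ligand`, `receptor` (header required).
#' @return Tibble of unique pairs; rows where ligand equals receptor are
#'   flagged in a `same_gene` column (they are removed by [filter_edges()]).
#' @export
read_lr_pairs <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop_format("ligand-receptor table needs 'ligand' and 'receptor' columns")
  distinct(tab, .data$ligand, .data$receptor) |>
    mutate(same_gene = .data$ligand == .data$receptor)
}
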