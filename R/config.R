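## Pipeline configuration: every tunable default, keyed module.operation.parameter.

atlas_defaults <- function() {
  list(
    sn_qc = list(
      mad_filter = list(
        doublet_mad_cutoff = 2, mito_mad_cutoff = 5,
        count_mad_cutoff_lymphoid = -4, count_mad_cutoff_other = -2.5,
        lymphoid_labels = c("B cells", "T cells", "mast cells", "NK cells"),
        doublet_direction = "high", count_two_sided = FALSE
      ),
      lognormalize = list(scale_factor = 10000),
      pearson_residuals = list(theta = 100),
      select_hvgs = list(residual_variance_threshold = 1.3, top_n = NULL),
      pca = list(n_pcs = 20),
      cluster = list(k_neighbors = 20, metric = "cosine", resolution = 0.8, seed = 0),
      umap = list(n_neighbors = 20, metric = "cosine")
    ),
    cell_typing = list(
      classify = list(min_overlap = 50, unassigned_floor = 0.2, hvg_top = 3000),
      module_score = list(n_bins = 24, n_ctrl = 100)
    ),
    cnv = list(
      infer = list(window = 101, expression_floor = 0.1, cap_sd = 3),
      arm_events = list(loss_threshold = -0.05, gain_threshold = 0.05)
    ),
    compendium = list(
      consensus = list(pItem = 0.7, reps = 1000, maxK = 12,
                       distance = "pearson", linkage = "ward.D2"),
      pac = list(tol = 0.01, lower = 0.1, upper = 0.9),
      hvg = list(mad_multiplier = 3),
      umap = list(n_neighbors = 15, min_dist = 0.1, n_epochs = 1000, metric = "cosine"),
      knn_impute = list(k = 15, metric = "cosine"),
      new_batch = list(subtract_intercept = TRUE)
    ),
    diffexp = list(
      pseudobulk = list(min_cells_broad = 10, min_cells_subtype = 50,
                        min_cells_subset = 300),
      tmm = list(prior_count = 0.5),
      fit = list(trend = TRUE, lowess_span = 0.5),
      threshold = list(lfc = 0.5, fdr = 0.05, lfc_marker = 3)
    ),
    interactions = list(
      filter = list(min_expressing_cells = 10, min_detection_rate = 0.1,
                    min_samples = 2, drop_autocrine = TRUE, drop_same_gene = TRUE),
      edges = list(per_sample = TRUE)
    )
  )
}

## numeric range constraints, keyed by flattened path
config_ranges <- function() {
  list(
    "sn_qc.mad_filter.mito_mad_cutoff"          = c(0 + 1e-12, Inf),
    "sn_qc.mad_filter.count_mad_cutoff_lymphoid" = c(-Inf, -1e-12),
    "sn_qc.mad_filter.count_mad_cutoff_other"   = c(-Inf, -1e-12),
    "sn_qc.lognormalize.scale_factor"           = c(1e-12, Inf),
    "sn_qc.pearson_residuals.theta"             = c(1e-12, Inf),
    "compendium.consensus.pItem"                = c(0, 1),
    "compendium.pac.tol"                        = c(0, 1),
    "compendium.pac.lower"                      = c(0, 1),
    "compendium.pac.upper"                      = c(0, 1),
    "diffexp.threshold.fdr"                     = c(0, 1),
    "interactions.filter.min_detection_rate"    = c(0, Inf),
    "interactions.filter.min_expressing_cells"  = c(0, Inf)
  )
}

flatten_config <- function(x, prefix = character()) {
  if (!is.list(x)) {
    out <- list(x); names(out) <- paste(prefix, collapse = "."); return(out)
  }
  out <- list()
  for (nm in names(x)) out <- c(out, flatten_config(x[[nm]], c(prefix, nm)))
  out
}

validate_config <- function(cfg) {
  known <- names(flatten_config(atlas_defaults()))
  flat <- flatten_config(cfg)
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    stop_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  ranges <- config_ranges()
  for (key in intersect(names(flat), names(ranges))) {
    v <- flat[[key]]
    if (!is.numeric(v) || is.na(v) || v < ranges[[key]][1] || v > ranges[[key]][2])
      stop_config(sprintf("config key '%s' = %s outside documented range [%g, %g]",
                          key, format(v), ranges[[key]][1], ranges[[key]][2]))
  }
  invisible(cfg)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys are filled with documented defaults; unknown keys and numeric
#' values outside their documented ranges are rejected. The configuration
#' carries provenance (source path and content hash).
#'
#' @param yaml_path Path to a YAML mapping, or `NULL` for pure defaults.
#' @return A `pipeline_config` (nested named list with attributes `source`
#'   and `hash`).
#' @export
load_config <- function(yaml_path = NULL) {
  override <- list()
  if (!is.null(yaml_path)) {
    override <- yaml::read_yaml(yaml_path)
    if (is.null(override)) override <- list()
    if (!is.list(override)) stop_config("config YAML must be a mapping")
  }
  validate_config(override)
  cfg <- merge_config(atlas_defaults(), override)
  structure(cfg, class = "pipeline_config",
            source = yaml_path %||% "<defaults>", hash = config_hash(cfg))
}

#' Hash a configuration
#'
#' Identical configurations hash identically; any field change changes the
#' hash. Used for provenance in serialized bundles.
#' @param cfg A configuration list.
#' @return Character scalar hash.
#' @export
config_hash <- function(cfg) {
  flat <- flatten_config(unclass(cfg))
  flat <- flat[order(names(flat))]
  rlang::hash(flat)
}
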