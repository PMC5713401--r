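#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published analysis conventions this package
#' implements: genes are "widely expressed" at FPKM > 1 in all stages,
#' "variable" above a two-fold range, excluded when undetected in >= 60% of
#' stages, coexpressed at |r| > 0.95 (with a 0.6 soft prefilter for guide
#' queries), and differentially expressed at |log2FC| > 1 and FDR < 0.05.
#'
#' @param min_fpkm_all_samples widely-expressed cutoff (FPKM, strict `>`).
#' @param fold_change_min minimum max/min expression ratio (strict `>`).
#' @param presence_exclusion_fraction gene excluded when at least this
#'   fraction of stages is at or below `detection_floor`.
#' @param detection_floor FPKM at or below which a gene counts as not
#'   expressed in a stage.
#' @param correlation_threshold hard coexpression cutoff on r (strict `>`).
#' @param prefilter_threshold soft guide-query prescreen on |r|; must not
#'   exceed `correlation_threshold`.
#' @param threshold_mode `"absolute"` keeps edges with |r| above threshold
#'   (negative partners retained, as dotted edges are in the source network
#'   figures); `"positive_only"` requires r itself above threshold.
#' @param log2fc_threshold DEG cutoff on |log2 fold change| (strict `>`).
#' @param fdr_threshold DEG cutoff on BH-adjusted p (strict `<`).
#' @param pseudocount added to both FPKM values in log2 fold changes.
#' @param random_seed integer seed for any stochastic step.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_fpkm_all_samples = 1.0,
                            fold_change_min = 2.0,
                            presence_exclusion_fraction = 0.6,
                            detection_floor = 0.0,
                            correlation_threshold = 0.95,
                            prefilter_threshold = 0.6,
                            threshold_mode = c("absolute", "positive_only"),
                            log2fc_threshold = 1.0,
                            fdr_threshold = 0.05,
                            pseudocount = 1.0,
                            random_seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  cfg <- list(min_fpkm_all_samples = min_fpkm_all_samples,
              fold_change_min = fold_change_min,
              presence_exclusion_fraction = presence_exclusion_fraction,
              detection_floor = detection_floor,
              correlation_threshold = correlation_threshold,
              prefilter_threshold = prefilter_threshold,
              threshold_mode = threshold_mode,
              log2fc_threshold = log2fc_threshold,
              fdr_threshold = fdr_threshold,
              pseudocount = pseudocount,
              random_seed = as.integer(random_seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$min_fpkm_all_samples >= 0,
            cfg$fold_change_min > 1,
            cfg$presence_exclusion_fraction > 0,
            cfg$presence_exclusion_fraction <= 1,
            cfg$detection_floor >= 0,
            cfg$correlation_threshold > 0,
            cfg$correlation_threshold <= 1,
            cfg$log2fc_threshold >= 0,
            cfg$fdr_threshold > 0, cfg$fdr_threshold <= 1,
            cfg$pseudocount >= 0)
  if (cfg$prefilter_threshold > cfg$correlation_threshold)
    stop("prefilter_threshold must not exceed correlation_threshold",
         call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Field names in the file mirror the arguments of [pipeline_config()]
#' exactly; unknown fields are rejected. YAML support requires the `yaml`
#' package (suggested); JSON always works.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
      yaml::read_yaml(path)
    },
    stop("unsupported config format '", ext, "' (use json, yaml or yml)",
         call. = FALSE))
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
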