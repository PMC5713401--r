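#' Write a simulated dataset to a directory
#'
#' Materializes everything a downstream run needs as plain text: the FPKM
#' matrix (`matrix.tsv`), fragment counts with lengths and library sizes
#' (`counts.tsv`, `gene_lengths.tsv`, `library_sizes.tsv`), the TF
#' annotation (`annotation.tsv`), a qPCR plate over the planted guides
#' (`qpcr.csv`, when guides exist), and the truth bookkeeping
#' (`truth.json`).
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir directory (created if missing).
#' @return invisibly, the list from [generate_counts()].
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gc_ <- generate_counts(spec)
  write_expression_matrix(gc_$fpkm, file.path(out_dir, "matrix.tsv"))
  cm <- gc_$counts
  write_expression_matrix(expression_matrix(cm$counts),
                          file.path(out_dir, "counts.tsv"))
  utils::write.table(data.frame(gene_id = names(cm$gene_lengths),
                                length_bp = cm$gene_lengths),
                     file.path(out_dir, "gene_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(stage = names(cm$library_sizes),
                                mapped_fragments = cm$library_sizes),
                     file.path(out_dir, "library_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation_table(truth_annotation(gc_$truth),
                         file.path(out_dir, "annotation.tsv"))
  truth <- gc_$truth
  if (length(truth$guides)) {
    q <- generate_qpcr(truth, truth$guides)
    write_qpcr_table(q, file.path(out_dir, "qpcr.csv"))
  }
  jsonlite::write_json(
    list(module = as.list(truth$module),
         tf_family = as.list(truth$tf_family),
         guides = truth$guides,
         seed = truth$spec$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, null = "null",
    na = "null", pretty = TRUE)
  invisible(gc_)
}

#' Run the full coexpression pipeline on an FPKM matrix
#'
#' The end-to-end analysis: presence filter, widely-expressed filter,
#' fold-range filter, coexpression network at the configured threshold,
#' component decomposition, optional guide queries, DEG count matrix, and
#' Z-score profiles.
#'
#' @param m an [expression_matrix()].
#' @param config a [pipeline_config()].
#' @param guides optional guide gene ids (must survive the filters).
#' @param ann optional [annotation_table()] for the guide overlay.
#' @return list with `retained` (filter funnel: present, widely_expressed,
#'   variable), `network`, `partition`, `guide_results` (or NULL),
#'   `deg_counts`, `zscores` (on the variable set).
#' @export
run_pipeline <- function(m, config = pipeline_config(), guides = NULL,
                         ann = NULL) {
  present <- presence_filter(m, config$presence_exclusion_fraction,
                             config$detection_floor)
  wide <- filter_widely_expressed(m[present, , drop = FALSE],
                                  config$min_fpkm_all_samples)
  variable <- filter_fold_range(m[wide, , drop = FALSE],
                                config$fold_change_min, pseudocount = 0)
  mv <- m[variable, , drop = FALSE]
  net <- build_network(mv, config$correlation_threshold,
                       config$threshold_mode)
  part <- connected_components(net)
  guide_results <- if (!is.null(guides))
    guide_query(mv, guides, ann = ann, config = config) else NULL
  list(retained = list(present = present, widely_expressed = wide,
                       variable = variable),
       network = net, partition = part, guide_results = guide_results,
       deg_counts = deg_count_matrix(mv, config),
       zscores = zscore_profiles(mv))
}

#' Write pipeline outputs to a directory
#'
#' Deterministic text outputs: filter gene lists (one id per line),
#' network as edge TSV + GraphML + SIF, component membership TSV, guide
#' neighbor TSV, and the DEG count table.
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$retained))
    writeLines(res$retained[[nm]], file.path(out_dir, paste0(nm, "_genes.txt")))
  write_network(res$network, file.path(out_dir, "network.edges.tsv"), "edge_tsv")
  write_network(res$network, file.path(out_dir, "network.graphml"), "graphml")
  write_network(res$network, file.path(out_dir, "network.sif"), "sif")
  write_components(res$partition, file.path(out_dir, "components.tsv"))
  if (!is.null(res$guide_results))
    write_guide_neighbors(res$guide_results,
                          file.path(out_dir, "guide_neighbors.tsv"))
  utils::write.table(as.data.frame(res$deg_counts),
                     file.path(out_dir, "deg_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
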