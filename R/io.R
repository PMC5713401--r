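#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of stage labels and gene identifiers in the first
#' column. Column order in the file defines the stage order. Malformed input
#' (duplicate gene ids, negative or non-numeric cells, ragged rows) is a hard
#' error naming the offending id or cell.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file has no stage columns: ", path, call. = FALSE)
  gid <- df[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', stage '%s'",
                 gid[bad[1, 1]], colnames(vals)[bad[1, 2]]), call. = FALSE)
  neg <- which(num < 0, arr.ind = TRUE)
  if (length(neg) && nrow(neg))
    stop(sprintf("negative value at gene '%s', stage '%s'",
                 gid[neg[1, 1]], colnames(vals)[neg[1, 2]]), call. = FALSE)
  dimnames(num) <- list(gid, colnames(vals))
  expression_matrix(num)
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression_matrix()]; values are written with full
#' precision (up to 15 significant digits) so write/read round-trips are
#' lossless to well below 1e-9 relative tolerance.
#'
#' @param m an expression matrix.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param id_column header name of the gene id column.
#' @export
write_expression_matrix <- function(m, path, dialect = c("tsv", "csv"),
                                    id_column = "gene_id") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  validate_expression_matrix(m)
  df <- data.frame(rownames(m), format(m, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Three-column TSV (`gene`, `namespace`, `label`); a gene may carry several
#' labels per namespace and genes may be absent entirely (unannotated). Only
#' the namespaces `tf_family` and `pathway_category` are accepted.
#'
#' @param path TSV file path.
#' @return a data.frame of class `"annotation_table"` with columns
#'   `gene`, `namespace`, `label`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  required <- c("gene", "namespace", "label")
  if (!all(required %in% names(df)))
    stop("annotation table needs columns gene, namespace, label", call. = FALSE)
  annotation_table(df[required])
}

#' @rdname read_annotation_table
#' @param df data.frame with columns gene, namespace, label.
#' @export
annotation_table <- function(df) {
  known <- c("tf_family", "pathway_category")
  bad_ns <- setdiff(unique(df$namespace), known)
  if (length(bad_ns))
    stop("unknown annotation namespace(s): ", paste(bad_ns, collapse = ", "),
         "; expected one of ", paste(known, collapse = ", "), call. = FALSE)
  if (any(!nzchar(df$label)))
    stop("annotation table contains empty labels", call. = FALSE)
  if (any(!nzchar(df$gene)))
    stop("annotation table contains empty gene ids", call. = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Look up annotation labels for genes
#'
#' @param ann an annotation table.
#' @param genes gene ids.
#' @param namespace `"tf_family"` or `"pathway_category"`.
#' @return named list mapping each requested gene to a character vector of
#'   labels (`character(0)` when unannotated).
#' @export
annotation_labels <- function(ann, genes, namespace = "tf_family") {
  sub <- ann[ann$namespace == namespace, , drop = FALSE]
  out <- split(sub$label, factor(sub$gene, levels = genes))
  lapply(out, as.character)
}

#' Write an annotation table to TSV
#' @param ann an annotation table.
#' @param path output path.
#' @export
write_annotation_table <- function(ann, path) {
  ord <- order(ann$gene, ann$namespace, ann$label)
  utils::write.table(ann[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Five-column CSV (`gene`, `stage`, `replicate`, `ct`, `is_reference`); the
#' reference (internal control, e.g. actin) must be measured at every
#' (stage, replicate) where any target gene is measured — a missing reference
#' well is a hard error naming the gap.
#'
#' @param path CSV file path.
#' @param calibrator_stage stage used as the 2^-ddCt calibrator; defaults to
#'   the first stage encountered in the file (conventionally the earliest).
#' @return data.frame of class `"qpcr_table"` with attribute
#'   `calibrator_stage`.
#' @export
read_qpcr_table <- function(path, calibrator_stage = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qpcr_table(df, calibrator_stage = calibrator_stage)
}

#' @rdname read_qpcr_table
#' @param df data.frame with columns gene, stage, replicate, ct, is_reference.
#' @export
qpcr_table <- function(df, calibrator_stage = NULL) {
  required <- c("gene", "stage", "replicate", "ct", "is_reference")
  if (!all(required %in% names(df)))
    stop("qPCR table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  df <- df[required]
  df$replicate <- as.integer(df$replicate)
  df$ct <- as.numeric(df$ct)
  df$is_reference <- as.logical(df$is_reference)
  if (any(!is.finite(df$ct))) stop("non-finite Ct value(s)", call. = FALSE)
  if (any(df$replicate < 1)) stop("replicate indices must be >= 1", call. = FALSE)
  targets <- df[!df$is_reference, , drop = FALSE]
  refs <- df[df$is_reference, , drop = FALSE]
  if (!nrow(refs)) stop("qPCR table has no reference-gene rows", call. = FALSE)
  need <- unique(targets[c("stage", "replicate")])
  have <- unique(refs[c("stage", "replicate")])
  key <- function(d) paste(d$stage, d$replicate, sep = "\r")
  gap <- need[!(key(need) %in% key(have)), , drop = FALSE]
  if (nrow(gap))
    stop(sprintf("missing reference measurement at stage '%s', replicate %d",
                 gap$stage[1], gap$replicate[1]), call. = FALSE)
  if (is.null(calibrator_stage)) calibrator_stage <- df$stage[1]
  if (!calibrator_stage %in% df$stage)
    stop("calibrator stage '", calibrator_stage, "' not present in table",
         call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("qpcr_table", "data.frame"),
            calibrator_stage = calibrator_stage)
}

#' Write a qPCR table to CSV
#' @param q a qpcr_table.
#' @param path output path.
#' @export
write_qpcr_table <- function(q, path) {
  ord <- order(q$gene, q$stage, q$replicate)
  out <- as.data.frame(q)[ord, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
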