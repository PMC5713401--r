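#' Construct and validate an expression matrix
#'
#' The central container of the pipeline is a plain numeric matrix of FPKM
#' values with genes in rows and developmental stages in columns. `rownames`
#' carry the gene identifiers, `colnames` the ordered stage labels (column
#' order *is* the stage order). This helper validates the invariants every
#' downstream filter and correlation relies on and attaches the
#' `"expression_matrix"` class tag.
#'
#' @param values numeric matrix, genes in rows, stages in columns; must have
#'   unique non-empty rownames and colnames, at least 3 columns, and only
#'   finite non-negative entries.
#' @return the validated matrix with class `c("expression_matrix", "matrix", "array")`.
#' @examples
#' m <- expression_matrix(matrix(1:12, 4, 3,
#'   dimnames = list(paste0("g", 1:4), c("2DAF", "6DAF", "10DAF"))))
#' stage_labels(m)
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_expression_matrix(values)
  class(values) <- c("expression_matrix", class(matrix()))
  values
}

#' @rdname expression_matrix
#' @param m object to validate.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  gid <- rownames(m)
  stg <- colnames(m)
  if (is.null(gid) || any(!nzchar(gid)))
    stop("expression matrix needs non-empty gene ids as rownames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (is.null(stg) || any(!nzchar(stg)))
    stop("expression matrix needs non-empty stage labels as colnames", call. = FALSE)
  if (anyDuplicated(stg))
    stop("duplicate stage label(s): ",
         paste(unique(stg[duplicated(stg)]), collapse = ", "), call. = FALSE)
  if (ncol(m) < 3)
    stop("at least 3 stages are required (correlation on fewer is degenerate)",
         call. = FALSE)
  if (any(!is.finite(m)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(m < 0))
    stop("expression matrix contains negative values", call. = FALSE)
  invisible(m)
}

#' @rdname expression_matrix
#' @export
stage_labels <- function(m) colnames(m)

#' @rdname expression_matrix
#' @export
gene_ids <- function(m) rownames(m)

#' Construct a count matrix with gene lengths and library sizes
#'
#' Holds the raw inputs of FPKM normalization: a gene-by-stage matrix of
#' fragment counts, per-gene exon lengths in bp, and per-stage totals of
#' mapped fragments. Library sizes need not equal column sums (multi-mapping
#' and unannotated fragments are allowed) but must be positive.
#'
#' @param counts integer-valued gene-by-stage matrix with dimnames.
#' @param gene_lengths named numeric vector, length in bp per gene (> 0).
#' @param library_sizes named numeric vector, mapped fragments per stage (> 0).
#' @return object of class `"count_matrix"`: a list with elements `counts`,
#'   `gene_lengths`, `library_sizes`.
#' @export
count_matrix <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  gid <- rownames(counts)
  stg <- colnames(counts)
  if (is.null(gid) || is.null(stg))
    stop("counts must have gene ids as rownames and stage labels as colnames",
         call. = FALSE)
  if (anyDuplicated(gid)) stop("duplicate gene ids in counts", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  missing_len <- setdiff(gid, names(gene_lengths))
  if (length(missing_len))
    stop("missing gene length for: ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  missing_lib <- setdiff(stg, names(library_sizes))
  if (length(missing_lib))
    stop("missing library size for stage: ", paste(missing_lib, collapse = ", "),
         call. = FALSE)
  if (any(gene_lengths[gid] <= 0) || any(!is.finite(gene_lengths[gid])))
    stop("gene lengths must be positive and finite", call. = FALSE)
  if (any(library_sizes[stg] <= 0) || any(!is.finite(library_sizes[stg])))
    stop("library sizes must be positive and finite", call. = FALSE)
  structure(list(counts = counts,
                 gene_lengths = gene_lengths[gid],
                 library_sizes = library_sizes[stg]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "stages\n")
  invisible(x)
}
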