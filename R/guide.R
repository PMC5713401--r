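#' Sign of a coexpression edge
#'
#' Positive correlations are drawn solid, negative ones dotted in the
#' conventional network figures; the sign is carried on every edge.
#'
#' @param r correlation value(s), non-zero.
#' @return character vector, `"positive"` where r > 0 else `"negative"`.
#' @export
classify_edge_sign <- function(r) {
  if (any(r == 0))
    stop("edge sign undefined at r = 0", call. = FALSE)
  ifelse(r > 0, "positive", "negative")
}

#' Guide-gene coexpression query
#'
#' The guilt-by-association screen: for each designated guide gene, find
#' every other gene whose correlation with the guide survives a two-stage
#' screen — a soft prefilter (`|r| > prefilter_threshold`, default 0.6, a
#' pure optimization that never changes results because it sits below the
#' report threshold) followed by the hard report cutoff
#' (`|r| > correlation_threshold`, default 0.95; or r alone in
#' `positive_only` mode). Neighbors are returned with signed r and their
#' TF-family annotation, sorted by |r| descending.
#'
#' @param m an expression matrix (the full filtered transcriptome, not a
#'   pre-built network — guides are queried transcriptome-wide).
#' @param guides character vector of guide gene ids; each must be present
#'   in `m` and non-constant.
#' @param ann optional [annotation_table()] supplying `tf_family` labels.
#' @param config a [pipeline_config()].
#' @param restrict_to_annotated keep only neighbors carrying at least one
#'   `tf_family` label (the TF-discovery use case).
#' @return list of class `"guide_query_result"` per guide: `guide_id`,
#'   `neighbors` (data.frame gene_id, r, sign, tf_family), `threshold_used`,
#'   `prefilter_used`.
#' @export
guide_query <- function(m, guides, ann = NULL, config = pipeline_config(),
                        restrict_to_annotated = FALSE) {
  validate_expression_matrix(m)
  absent <- setdiff(guides, rownames(m))
  if (length(absent))
    stop("guide gene(s) absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  cx <- m - rowMeans(m)
  norms <- sqrt(rowSums(cx^2))
  if (any(norms[guides] == 0))
    stop("constant guide gene(s): ",
         paste(guides[norms[guides] == 0], collapse = ", "), call. = FALSE)
  usable <- norms > 0
  cxn <- cx[usable, , drop = FALSE] / norms[usable]
  lapply(guides, function(g) {
    r <- drop(cxn %*% cxn[g, ])
    r[r > 1] <- 1
    r[r < -1] <- -1
    r <- r[names(r) != g]
    # soft prescreen, then the hard report threshold
    r <- r[abs(r) > config$prefilter_threshold]
    keep <- if (config$threshold_mode == "absolute")
      abs(r) > config$correlation_threshold
    else r > config$correlation_threshold
    r <- r[keep]
    fam <- if (!is.null(ann)) {
      labs <- annotation_labels(ann, names(r), "tf_family")
      vapply(labs, function(l) if (length(l)) paste(sort(l), collapse = ";")
             else NA_character_, "")
    } else rep(NA_character_, length(r))
    nb <- data.frame(gene_id = names(r), r = unname(r),
                     sign = if (length(r)) classify_edge_sign(unname(r)) else character(0),
                     tf_family = unname(fam), stringsAsFactors = FALSE)
    if (restrict_to_annotated) nb <- nb[!is.na(nb$tf_family), , drop = FALSE]
    nb <- nb[order(-abs(nb$r), nb$gene_id), , drop = FALSE]
    rownames(nb) <- NULL
    structure(list(guide_id = g, neighbors = nb,
                   threshold_used = config$correlation_threshold,
                   prefilter_used = config$prefilter_threshold),
              class = "guide_query_result")
  })
}

#' @export
print.guide_query_result <- function(x, ...) {
  cat(sprintf("guide %s: %d neighbors at |r| > %g\n", x$guide_id,
              nrow(x$neighbors), x$threshold_used))
  invisible(x)
}

#' TF-family distribution over a gene set
#'
#' Counts `tf_family` labels over the given genes. A gene carrying several
#' family labels contributes once per family (family counts are
#' per-family); such genes are flagged. Unannotated genes are tallied
#' separately.
#'
#' @param genes character vector of gene ids.
#' @param ann an [annotation_table()].
#' @return list of class `"family_distribution"`: `counts` (named integer,
#'   sorted by decreasing count then name), `total_tf_count` (genes with at
#'   least one family), `n_unannotated`, `multi_family_genes`.
#' @export
family_distribution <- function(genes, ann) {
  labs <- annotation_labels(ann, genes, "tf_family")
  n_lab <- lengths(labs)
  fam <- unlist(labs, use.names = FALSE)
  counts <- if (length(fam)) table(fam) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (length(counts))
    counts <- counts[order(-counts, names(counts), method = "radix")]
  structure(list(counts = counts,
                 total_tf_count = sum(n_lab > 0),
                 n_unannotated = sum(n_lab == 0),
                 multi_family_genes = names(labs)[n_lab > 1]),
            class = "family_distribution")
}

#' @export
print.family_distribution <- function(x, ...) {
  cat("TF families over", x$total_tf_count, "annotated genes (",
      x$n_unannotated, "unannotated ):\n")
  print(x$counts)
  invisible(x)
}

#' Merge guide-query results into a star-union network
#'
#' Guides become hubs; every guide-neighbor pair becomes an edge carrying
#' the query's signed r. A neighbor shared by several guides appears once
#' as a node, with one edge per guide.
#'
#' @param results list of [guide_query()] results over the same matrix.
#' @return a `coexpression_network` (threshold from the first result).
#' @export
merge_guide_networks <- function(results) {
  stopifnot(length(results) >= 1)
  edges <- do.call(rbind, lapply(results, function(res) {
    nb <- res$neighbors
    if (!nrow(nb))
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        r = numeric(0), sign = character(0)))
    data.frame(gene_a = pmin(res$guide_id, nb$gene_id),
               gene_b = pmax(res$guide_id, nb$gene_id),
               r = nb$r, sign = nb$sign, stringsAsFactors = FALSE)
  }))
  edges <- unique(edges)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(vapply(results, `[[`, "", "guide_id"),
                         edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges,
                 build_threshold = results[[1]]$threshold_used,
                 threshold_mode = "absolute"),
            class = "coexpression_network")
}

#' Write per-guide neighbor tables as TSV
#'
#' @param results list of [guide_query()] results.
#' @param path output TSV with columns guide, gene, r, sign, family.
#' @export
write_guide_neighbors <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(res) {
    nb <- res$neighbors
    data.frame(guide = rep(res$guide_id, nrow(nb)), gene = nb$gene_id,
               r = format_r(nb$r), sign = nb$sign, family = nb$tf_family)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
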