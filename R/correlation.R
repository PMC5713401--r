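#' Pearson correlation of two stage profiles
#'
#' Plain product-moment correlation, computed from centered profiles and
#' clamped to \[-1, 1\] against floating-point rounding. A constant profile
#' has no defined correlation: that is a hard error here, never a silent 0
#' (callers that must tolerate constants flag them first, see
#' [correlation_matrix()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  cx <- x - mean(x)
  cy <- y - mean(y)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0)
    stop("undefined correlation: constant profile", call. = FALSE)
  max(-1, min(1, sum(cx * cy) / den))
}

#' All-pairs Pearson correlation matrix
#'
#' Exact all-pairs correlation over the stage profiles via centered and
#' row-normalized matrix products (`tcrossprod`), feasible at desk scale
#' (tens of thousands of genes over a handful of stages). Genes constant
#' across stages have no defined correlation; they are excluded from the
#' result and reported in the `constant_genes` attribute.
#'
#' @param m an expression matrix (typically after [presence_filter()]).
#' @return symmetric numeric matrix of r values with unit diagonal, dimnames
#'   the non-constant gene ids; attribute `constant_genes` lists exclusions.
#' @export
correlation_matrix <- function(m) {
  validate_expression_matrix(m)
  cx <- m - rowMeans(m)
  norms <- sqrt(rowSums(cx^2))
  constant <- norms == 0
  cx <- cx[!constant, , drop = FALSE] / norms[!constant]
  r <- tcrossprod(cx)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  attr(r, "constant_genes") <- rownames(m)[constant]
  r
}

#' Build a thresholded coexpression network
#'
#' Keeps gene pairs whose correlation strictly exceeds the threshold:
#' `|r| > threshold` in `"absolute"` mode (default — anticorrelated partners
#' are genuine edges, drawn dotted in the conventional network figures) or
#' `r > threshold` in `"positive_only"` mode. Edges store the signed r that
#' created them. Pairs are ordered lexicographically (gene_a < gene_b) and
#' sorted, so outputs are byte-stable.
#'
#' @param m an expression matrix, or a precomputed [correlation_matrix()].
#' @param threshold correlation cutoff in (0, 1\], strict `>`.
#' @param mode `"absolute"` or `"positive_only"`.
#' @param keep_isolated keep nodes with no surviving edge? Default drops
#'   them (the network is the coexpressed gene set).
#' @return object of class `"coexpression_network"`: list with `nodes`
#'   (character), `edges` (data.frame gene_a, gene_b, r, sign),
#'   `build_threshold`, `threshold_mode`.
#' @export
build_network <- function(m, threshold = 0.95,
                          mode = c("absolute", "positive_only"),
                          keep_isolated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  is_corr <- is.matrix(m) && nrow(m) == ncol(m) &&
    identical(rownames(m), colnames(m)) &&
    all(abs(diag(m) - 1) < 1e-12) && all(abs(m) <= 1)
  r <- if (is_corr) m else correlation_matrix(m)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  ut <- upper.tri(r)
  keep <- if (mode == "absolute") abs(r) > threshold else r > threshold
  idx <- which(ut & keep, arr.ind = TRUE)
  ids <- rownames(r)
  ga <- ids[idx[, 1]]
  gb <- ids[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga, gene_b = gb, r = r[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges$sign <- classify_edge_sign(edges$r)
  nodes <- if (keep_isolated) sort(ids) else sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges,
                 build_threshold = threshold, threshold_mode = mode),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges (mode %s, r > %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold_mode,
              x$build_threshold))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("gene_a", "gene_b", "r", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Connected-component decomposition of a coexpression network
#'
#' Maximal connected components ("subnetworks"), sorted by decreasing size
#' with ties broken lexicographically by smallest member id; isolated nodes
#' appear as singletons. Membership within each component is sorted.
#'
#' @param net a `coexpression_network`.
#' @return object of class `"subnetwork_partition"`: list with `components`
#'   (list of sorted character vectors) and `degrees` (named integer).
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!length(net$nodes))
    return(structure(list(components = list(), degrees = integer(0)),
                     class = "subnetwork_partition"))
  g <- as_igraph(net)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, "", 1L))
  comps <- unname(comps[ord])
  structure(list(components = comps, degrees = node_degrees(net)),
            class = "subnetwork_partition")
}

#' @export
print.subnetwork_partition <- function(x, ...) {
  cat("subnetwork_partition:", length(x$components), "components; sizes:",
      paste(utils::head(lengths(x$components), 10), collapse = ", "),
      if (length(x$components) > 10) "..." else "", "\n")
  invisible(x)
}

#' Node degrees of a coexpression network
#'
#' @param net a `coexpression_network`.
#' @return named integer vector over all nodes (isolated nodes get 0);
#'   satisfies the handshake identity `sum(degrees) == 2 * nrow(edges)`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  stats::setNames(as.integer(deg), net$nodes)
}

#' Extract the k largest subnetworks with summaries
#'
#' Returns the top-k components plus the residual gene set (members of
#' smaller components — the genes "relatively less correlated with
#' others"). Each summary reports size, mean |r| over the component's
#' internal edges, and the hub (highest-degree member, ties lexicographic).
#'
#' @param partition a [connected_components()] result.
#' @param net the network the partition came from (for edge r values).
#' @param k number of main subnetworks to keep.
#' @return list with `main` (list of k lists: nodes, size, mean_abs_r, hub)
#'   and `residual` (sorted character vector).
#' @export
main_subnetworks <- function(partition, net, k = 2L) {
  stopifnot(k >= 1)
  comps <- partition$components
  if (k > length(comps)) {
    warning("k = ", k, " exceeds number of components (", length(comps),
            "); returning all")
    k <- length(comps)
  }
  summarize <- function(nodes) {
    e <- net$edges[net$edges$gene_a %in% nodes & net$edges$gene_b %in% nodes, ]
    deg <- partition$degrees[nodes]
    hub <- sort(names(deg)[deg == max(deg)])[1]
    list(nodes = nodes, size = length(nodes),
         mean_abs_r = if (nrow(e)) mean(abs(e$r)) else NA_real_, hub = hub)
  }
  main <- lapply(comps[seq_len(k)], summarize)
  residual <- sort(unlist(comps[-seq_len(k)], use.names = FALSE))
  if (is.null(residual)) residual <- character(0)
  list(main = main, residual = residual)
}
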