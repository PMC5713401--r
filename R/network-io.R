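#' Export a coexpression network
#'
#' Supported interchange formats:
#' * `sif` — Cytoscape simple interaction format, interaction type `"co"`;
#' * `edge_tsv` — four columns `source`, `target`, `r`, `sign`;
#' * `graphml` — via igraph, with `r` and `sign` as edge attributes.
#'
#' Nodes and edges are emitted in lexicographic order so the same network
#' always produces byte-identical files.
#'
#' @param net a `coexpression_network`.
#' @param path output file.
#' @param format one of `"sif"`, `"edge_tsv"`, `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(format) != 1 || !format %in% c("edge_tsv", "sif", "graphml"))
    stop("unknown network format '", paste(format, collapse = ","),
         "'; supported: sif, edge_tsv, graphml", call. = FALSE)
  e <- net$edges[order(net$edges$gene_a, net$edges$gene_b), , drop = FALSE]
  if (format == "edge_tsv") {
    out <- data.frame(source = e$gene_a, target = e$gene_b,
                      r = format_r(e$r), sign = e$sign)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e)) paste(e$gene_a, "co", e$gene_b) else character(0)
    isolated <- setdiff(net$nodes, unique(c(e$gene_a, e$gene_b)))
    writeLines(c(lines, sort(isolated)), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

format_r <- function(r) formatC(r, digits = 15, format = "g")

#' Read a coexpression network back from disk
#'
#' Inverse of [write_network()] for the `edge_tsv` and `graphml` formats
#' (SIF drops the correlation values and is export-only). The recorded
#' build threshold/mode are not stored in the files; they are re-attached
#' from the arguments.
#'
#' @param path file written by [write_network()].
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param threshold,mode provenance to attach to the returned object.
#' @return a `coexpression_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml"),
                         threshold = NA_real_, mode = "absolute") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    edges <- data.frame(gene_a = df$source, gene_b = df$target,
                        r = as.numeric(df$r), sign = df$sign,
                        stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(gene_a = pmin(el$from, el$to),
                        gene_b = pmax(el$from, el$to),
                        r = el$r, stringsAsFactors = FALSE)
    edges$sign <- classify_edge_sign(edges$r)
    nodes <- sort(igraph::V(g)$name)
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, build_threshold = threshold,
                 threshold_mode = mode), class = "coexpression_network")
}

#' Write component membership as a two-column TSV
#'
#' @param partition a [connected_components()] result.
#' @param path output file; columns `gene`, `component_rank` (1 = largest).
#' @export
write_components <- function(partition, path) {
  comps <- partition$components
  df <- data.frame(
    gene = unlist(comps, use.names = FALSE),
    component_rank = rep(seq_along(comps), lengths(comps)))
  if (!nrow(df)) df <- data.frame(gene = character(0), component_rank = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
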