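# Independent oracles the implementation is checked against. These are kept
# deliberately naive (loops, enumeration, textbook formulas) and share no
# code with the package internals.

# definitional Pearson r, term by term
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# BH step-up enumerated by rank: adj for the i-th smallest p is
# min over j >= i of n * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in i:n) vals <- c(vals, n * p[ord[j]] / j)
    adj_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# breadth-first-search connected components over an edge list
oracle_components <- function(nodes, edge_a, edge_b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(edge_a)) {
    adj[[edge_a[k]]] <- c(adj[[edge_a[k]]], edge_b[k])
    adj[[edge_b[k]]] <- c(adj[[edge_b[k]]], edge_a[k])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; members <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(-lengths(comps), vapply(comps, `[`, "", 1L))]
}

# brute-force thresholded edge list from an expression matrix
oracle_edges <- function(m, threshold, mode = "absolute") {
  ids <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      r <- oracle_pearson(m[i, ], m[j, ])
      keep <- if (mode == "absolute") abs(r) > threshold else r > threshold
      if (is.finite(r) && keep) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        out[[length(out) + 1L]] <- data.frame(gene_a = a, gene_b = b, r = r)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

# small helper: expression matrix fixture from a plain matrix
make_em <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                    stages = daf_stage_labels(ncol(values))) {
  dimnames(values) <- list(genes, stages)
  expression_matrix(values)
}

# random Erdos-Renyi style graph as a coexpression_network (r values +-1)
random_network <- function(n_nodes, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      r = sample(c(0.99, -0.99), sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  structure(list(nodes = nodes, edges = edges, build_threshold = 0.95,
                 threshold_mode = "absolute"),
            class = "coexpression_network")
}

default_guide_spec <- function(seed) {
  synthetic_spec(guides = data.frame(module_name = c("mid", "early", "late"),
                                     count = 1L),
                 seed = seed)
}
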