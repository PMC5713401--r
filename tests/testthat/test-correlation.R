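test_that("pearson_r: identities, affine invariance, formula oracle", {
  set.seed(21)
  x <- rexp(7)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2.5 * x + 3), 1)
  expect_error(pearson_r(x, rep(1, 7)), "constant")
  for (k in 1:50) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("correlation_matrix is symmetric, unit-diagonal, matches brute force", {
  set.seed(31)
  m <- make_em(matrix(rexp(350, 1 / 5), 50, 7))
  r <- correlation_matrix(m)
  expect_equal(r, t(r), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(r)), rep(1, 50))
  expect_true(all(abs(r) <= 1))
  for (k in 1:200) {
    i <- sample(50, 1); j <- sample(50, 1)
    if (i == j) next
    expect_equal(r[i, j], oracle_pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }

  # identical rows give off-diagonal exactly 1; constants are excluded
  dup <- make_em(rbind(c(1, 2, 3, 4, 5, 6, 7),
                       c(1, 2, 3, 4, 5, 6, 7),
                       rep(2, 7)))
  r2 <- correlation_matrix(dup)
  expect_equal(r2["g1", "g2"], 1)
  expect_identical(attr(r2, "constant_genes"), "g3")
  expect_identical(rownames(r2), c("g1", "g2"))
})

test_that("build_network thresholds strictly and is monotone in threshold", {
  # A == B (r = 1), C independent: single A-B edge at 0.95
  m <- make_em(rbind(c(1, 2, 3, 4, 5, 6, 7),
                     c(2, 4, 6, 8, 10, 12, 14),
                     c(5, 1, 4, 2, 6, 1, 3)),
               genes = c("A", "B", "C"))
  net <- build_network(m, 0.95)
  expect_identical(net$edges$gene_a, "A")
  expect_identical(net$edges$gene_b, "B")
  expect_equal(net$edges$r, 1)

  # threshold 1.0 on noisy data: empty network (strict >)
  set.seed(41)
  noisy <- make_em(matrix(rexp(140), 20, 7))
  expect_identical(nrow(build_network(noisy, 1.0)$edges), 0L)

  # monotonicity: edges at t2 are a subset of edges at t1 <= t2
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  e60 <- key(build_network(noisy, 0.6))
  e80 <- key(build_network(noisy, 0.8))
  e95 <- key(build_network(noisy, 0.95))
  expect_true(all(e80 %in% e60))
  expect_true(all(e95 %in% e80))

  # positive_only drops negative-r edges
  anti <- make_em(rbind(c(1, 2, 3, 4, 5, 6, 7), c(7, 6, 5, 4, 3, 2, 1)),
                  genes = c("up", "down"))
  expect_identical(nrow(build_network(anti, 0.95, "positive_only")$edges), 0L)
  expect_identical(build_network(anti, 0.95, "absolute")$edges$sign, "negative")
})

test_that("connected_components matches the BFS oracle on random graphs", {
  set.seed(51)
  for (k in 1:60) {
    net <- random_network(sample(2:50, 1), runif(1, 0.02, 0.2))
    got <- connected_components(net)$components
    want <- oracle_components(net$nodes, net$edges$gene_a, net$edges$gene_b)
    expect_identical(got, want)
  }
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             r = numeric(0),
                                             sign = character(0)),
                          build_threshold = 0.95, threshold_mode = "absolute"),
                     class = "coexpression_network")
  expect_identical(connected_components(empty)$components, list())
})

test_that("node_degrees satisfies the handshake identity; hub/star cases", {
  tri <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                       r = rep(0.99, 3), sign = "positive"),
    build_threshold = 0.95, threshold_mode = "absolute"),
    class = "coexpression_network")
  expect_identical(unname(node_degrees(tri)), c(2L, 2L, 2L))

  set.seed(61)
  rnd <- random_network(30, 0.1)
  expect_identical(sum(node_degrees(rnd)), 2L * nrow(rnd$edges))
})

test_that("main_subnetworks returns top-k plus residual consistently", {
  set.seed(71)
  # two planted cliques (sizes 6 and 4) plus two isolated-pair components
  clique_net <- function(ids) {
    pr <- t(combn(ids, 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2], r = 0.99, sign = "positive")
  }
  edges <- rbind(clique_net(sprintf("a%d", 1:6)), clique_net(sprintf("b%d", 1:4)),
                 data.frame(gene_a = "x1", gene_b = "x2", r = -0.97,
                            sign = "negative"))
  net <- structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                        edges = edges, build_threshold = 0.95,
                        threshold_mode = "absolute"),
                   class = "coexpression_network")
  part <- connected_components(net)
  top <- main_subnetworks(part, net, k = 2)
  expect_identical(vapply(top$main, `[[`, 0L, "size"), c(6L, 4L))
  expect_identical(top$residual, c("x1", "x2"))
  expect_identical(top$main[[1]]$hub, "a1")  # clique: tie broken lexicographically
  sizes <- vapply(top$main, function(s) length(s$nodes), 0L)
  expect_identical(sizes, lengths(part$components)[1:2])
  expect_warning(main_subnetworks(part, net, k = 10), "exceeds")
})

test_that("network export round-trips: edge_tsv, graphml, sif; deterministic bytes", {
  set.seed(81)
  m <- make_em(matrix(rexp(70), 10, 7))
  net <- build_network(m, 0.6)
  expect_gt(nrow(net$edges), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tsv, "edge_tsv")
  back <- read_network(tsv, "edge_tsv")
  expect_identical(back$edges$gene_a, net$edges$gene_a)
  expect_equal(back$edges$r, net$edges$r, tolerance = 1e-9)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back2 <- read_network(gml, "graphml")
  expect_identical(nrow(back2$edges), nrow(net$edges))
  expect_equal(back2$edges$r[order(back2$edges$gene_a, back2$edges$gene_b)],
               net$edges$r, tolerance = 1e-9)

  # empty network: header-only edge file
  e <- build_network(m, 1.0)
  write_network(e, tsv, "edge_tsv")
  expect_identical(readLines(tsv), "source\ttarget\tr\tsign")

  # byte-identical across two writes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(net, f1, "sif"); write_network(net, f2, "sif")
  expect_identical(readLines(f1), readLines(f2))
  expect_error(write_network(net, tsv, "gexf"), "supported")
})
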