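test_that("classify_edge_sign is consistent and guards r = 0", {
  expect_identical(classify_edge_sign(0.981), "positive")
  expect_identical(classify_edge_sign(-0.965), "negative")
  set.seed(1)
  r <- runif(50, -1, 1)
  r <- r[r != 0]
  expect_identical(classify_edge_sign(r),
                   ifelse(-(-r) > 0, "positive", "negative"))
  expect_error(classify_edge_sign(0), "undefined")
})

test_that("guide_query recovers planted partners with signs, errors on bad guides", {
  spec <- default_guide_spec(4)
  gm <- generate_matrix(spec)
  g <- gm$truth$guides[1]
  res <- guide_query(gm$matrix, g, config = pipeline_config())[[1]]
  partners <- setdiff(names(gm$truth$module)[
    gm$truth$module == gm$truth$module[[g]]], g)
  expect_true(all(partners %in% res$neighbors$gene_id))
  expect_true(all(res$neighbors$sign[res$neighbors$gene_id %in% partners]
                  == "positive"))
  # sorted by |r| descending, guide not among neighbors
  expect_false(g %in% res$neighbors$gene_id)
  expect_true(!is.unsorted(rev(abs(res$neighbors$r))))

  expect_error(guide_query(gm$matrix, "nope"), "nope")
  mc <- make_em(rbind(rep(1, 7), c(1, 2, 3, 4, 5, 6, 7)),
                genes = c("const", "ok"))
  expect_error(guide_query(mc, "const"), "constant")
})

test_that("anticorrelated planted partner is recovered with negative sign", {
  x <- c(1, 3, 9, 20, 12, 5, 2)
  m <- make_em(rbind(x, max(x) + min(x) - x, c(4, 4, 5, 4, 4, 5, 4)),
               genes = c("guide", "anti", "flatish"))
  res <- guide_query(m, "guide")[[1]]
  expect_identical(res$neighbors$gene_id, "anti")
  expect_identical(res$neighbors$sign, "negative")
})

test_that("prefilter equal to threshold changes nothing (pure optimization)", {
  spec <- default_guide_spec(5)
  gm <- generate_matrix(spec)
  ann <- truth_annotation(gm$truth)
  a <- guide_query(gm$matrix, gm$truth$guides, ann,
                   pipeline_config(prefilter_threshold = 0.6))
  b <- guide_query(gm$matrix, gm$truth$guides, ann,
                   pipeline_config(prefilter_threshold = 0.95))
  for (i in seq_along(a))
    expect_equal(a[[i]]$neighbors, b[[i]]$neighbors)
})

test_that("restricting to TF annotation commutes with post-hoc filtering", {
  spec <- default_guide_spec(6)
  gm <- generate_matrix(spec)
  ann <- truth_annotation(gm$truth)
  restricted <- guide_query(gm$matrix, gm$truth$guides[1], ann,
                            restrict_to_annotated = TRUE)[[1]]
  full <- guide_query(gm$matrix, gm$truth$guides[1], ann)[[1]]
  post <- full$neighbors[!is.na(full$neighbors$tf_family), , drop = FALSE]
  rownames(post) <- NULL
  expect_equal(restricted$neighbors, post)
})

test_that("neighbor recall is non-decreasing in within-module correlation", {
  recalls <- vapply(c(0.4, 0.15, 0.05), function(noise) {
    mean(vapply(1:5, function(s) {
      spec <- synthetic_spec(
        modules = data.frame(name = "mid", archetype = "mid_peak",
                             n_genes = 31L, base_fpkm = 500,
                             noise_sd = noise),
        n_background = 100L,
        guides = data.frame(module_name = "mid", count = 1L), seed = s)
      gm <- generate_matrix(spec)
      score_guide_recovery(
        guide_query(gm$matrix, gm$truth$guides)[[1]], gm$truth)$recall
    }, 0))
  }, 0)
  expect_true(!is.unsorted(recalls))
  expect_equal(recalls[3], 1)  # near-noise-free limit
})

test_that("merge_guide_networks builds the star union with shared neighbors", {
  nb <- function(guide, genes, r) {
    structure(list(guide_id = guide,
                   neighbors = data.frame(gene_id = genes, r = r,
                                          sign = ifelse(r > 0, "positive",
                                                        "negative"),
                                          tf_family = NA_character_),
                   threshold_used = 0.95, prefilter_used = 0.6),
              class = "guide_query_result")
  }
  res <- list(nb("FAD2", c("t1", "t2"), c(0.97, -0.96)),
              nb("FAD3", c("t3", "t4", "t5"), c(0.99, 0.98, 0.97)))
  net <- merge_guide_networks(res)
  expect_identical(nrow(net$edges), 5L)
  expect_identical(length(net$nodes), 7L)

  shared <- list(nb("FAD2", c("t1", "s"), c(0.97, 0.96)),
                 nb("FAD3", c("s"), c(0.99)))
  net2 <- merge_guide_networks(shared)
  expect_identical(unname(node_degrees(net2)["s"]), 2L)

  # exported and re-read edges keep their r values
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f, "edge_tsv")
  back <- read_network(f, "edge_tsv")
  expect_equal(sort(back$edges$r), sort(net$edges$r), tolerance = 1e-9)
})

test_that("family_distribution handles empty sets and multi-family flags", {
  ann <- annotation_table(data.frame(
    gene = c("a", "a", "b", "c"), namespace = "tf_family",
    label = c("MYB", "bHLH", "MYB", "NAC")))
  fd <- family_distribution(c("a", "b", "c", "d"), ann)
  # ties in count are broken by C-locale (radix) name order
  expect_identical(fd$counts, c(MYB = 2L, NAC = 1L, bHLH = 1L))
  expect_identical(fd$multi_family_genes, "a")
  expect_identical(fd$n_unannotated, 1L)
  empty <- family_distribution(character(0), ann)
  expect_identical(length(empty$counts), 0L)
})
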