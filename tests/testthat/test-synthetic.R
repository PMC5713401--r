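test_that("generators are deterministic given the spec seed", {
  spec <- default_guide_spec(17)
  a <- generate_matrix(spec)
  b <- generate_matrix(spec)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$tf_family, b$truth$tf_family)
  ca <- generate_counts(spec); cb <- generate_counts(spec)
  expect_identical(ca$counts$counts, cb$counts$counts)
  qa <- generate_qpcr(a$truth, a$truth$guides)
  qb <- generate_qpcr(b$truth, b$truth$guides)
  expect_identical(qa$ct, qb$ct)
  # and does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_matrix(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("noise-free modules are perfectly correlated; 0.05 noise keeps r >= 0.98", {
  spec0 <- synthetic_spec(
    modules = data.frame(name = "m", archetype = "mid_peak", n_genes = 10L,
                         base_fpkm = 100, noise_sd = 0),
    n_background = 0L, seed = 2)
  r0 <- correlation_matrix(generate_matrix(spec0)$matrix)
  expect_equal(r0[upper.tri(r0)], rep(1, choose(10, 2)), tolerance = 1e-12)

  mean_r <- vapply(1:5, function(s) {
    gm <- generate_matrix(synthetic_spec(n_background = 0L, seed = s))
    r <- correlation_matrix(gm$matrix)
    mods <- gm$truth$module
    mean(vapply(unique(mods), function(md) {
      ids <- names(mods)[mods == md]
      sub <- r[ids, ids]
      mean(sub[upper.tri(sub)])
    }, 0))
  }, 0)
  expect_true(all(mean_r >= 0.98))
})

test_that("archetype profiles have the stated shapes", {
  p <- archetype_profile("mid_peak", 7)
  # maximal at 14 and 18 DAF (equal up to floating point)
  expect_equal(p[4], p[5], tolerance = 1e-9)
  expect_true(min(p[c(4, 5)]) > max(p[-c(4, 5)]))
  expect_true(!is.unsorted(-archetype_profile("early_declining", 7)))
  expect_true(!is.unsorted(archetype_profile("late_rising", 7)))
  expect_identical(archetype_profile("flat_background", 5), rep(1, 5))
  expect_error(archetype_profile("bogus"), "unknown archetype")
  expect_identical(daf_stage_labels(7)[c(1, 7)], c("2DAF", "26DAF"))
})

test_that("generate_counts inverts through compute_fpkm within rounding error", {
  spec <- synthetic_spec(n_background = 50L, seed = 5)
  gc_ <- generate_counts(spec)
  f <- compute_fpkm(gc_$counts)
  bound <- 1e9 / (2 * outer(gc_$counts$gene_lengths,
                            gc_$counts$library_sizes))
  expect_true(all(abs(f - gc_$fpkm) <= bound + 1e-9))
  # zero FPKM stays zero counts
  spec0 <- synthetic_spec(
    modules = data.frame(name = "z", archetype = "flat_background",
                         n_genes = 2L, base_fpkm = 1e-12, noise_sd = 0),
    n_background = 0L, seed = 1)
  expect_true(all(generate_counts(spec0)$counts$counts == 0))
})

test_that("adjusted_rand_index: identity, hand-computed 6-gene case, null", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # contingency [[2,1],[0,3]]: sum C2 = 4, rows 3/3 -> 6, cols 2/4 -> 7,
  # expected 6*7/15 = 2.8, max 6.5 -> (4 - 2.8)/(6.5 - 2.8) = 1.2/3.7
  a <- c("A", "A", "A", "B", "B", "B")
  b <- c("x", "x", "y", "y", "y", "y")
  expect_equal(adjusted_rand_index(a, b), 1.2 / 3.7, tolerance = 1e-12)
  set.seed(8)
  null_ari <- replicate(50, adjusted_rand_index(sample(1:5, 200, TRUE),
                                                sample(1:5, 200, TRUE)))
  expect_lt(abs(mean(null_ari)), 0.02)
})

test_that("recovery scoring: exact truth gives perfect scores", {
  spec <- default_guide_spec(9)
  gm <- generate_matrix(spec)
  mods <- gm$truth$module
  planted <- lapply(c("early", "late", "mid"),
                    function(md) sort(names(mods)[mods == md]))
  part <- structure(list(components = planted[order(-lengths(planted))],
                         degrees = integer(0)),
                    class = "subnetwork_partition")
  expect_equal(score_partition_recovery(part, gm$truth)$ari, 1)
  g <- gm$truth$guides[1]
  res <- structure(list(guide_id = g,
                        neighbors = data.frame(
                          gene_id = setdiff(names(mods)[mods == mods[[g]]], g),
                          r = 0.99, sign = "positive",
                          tf_family = NA_character_),
                        threshold_used = 0.95, prefilter_used = 0.6),
                   class = "guide_query_result")
  sc <- score_guide_recovery(res, gm$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})

test_that("mean module recovery does not improve when noise grows", {
  mean_ari <- vapply(c(0.05, 0.6), function(noise) {
    mean(vapply(1:6, function(s) {
      spec <- synthetic_spec(
        modules = data.frame(name = c("mid", "early", "late"),
                             archetype = c("mid_peak", "early_declining",
                                           "late_rising"),
                             n_genes = 30L, base_fpkm = c(500, 200, 200),
                             noise_sd = noise),
        n_background = 100L, seed = s)
      gm <- generate_matrix(spec)
      res <- run_pipeline(gm$matrix)
      score_partition_recovery(res$partition, gm$truth)$ari
    }, 0))
  }, 0)
  expect_lte(mean_ari[2], mean_ari[1])
})

test_that("truth annotation and TF labelling fraction behave", {
  spec <- synthetic_spec(n_background = 1000L, tf_fraction = 0.3, seed = 11)
  gm <- generate_matrix(spec)
  frac <- mean(!is.na(gm$truth$tf_family))
  expect_lt(abs(frac - 0.3), 0.05)
  ann <- truth_annotation(gm$truth)
  expect_true(all(ann$namespace == "tf_family"))
  expect_identical(nrow(ann), sum(!is.na(gm$truth$tf_family)))
})
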