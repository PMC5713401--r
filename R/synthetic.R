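#' Specification of a synthetic staged-seed transcriptome
#'
#' Describes the world the generator emulates: a single-plant developmental
#' time course (default seven stages, 2-26 days after flowering in steps of
#' 4), a small number of planted coexpression modules following fixed
#' temporal archetypes, a background of independent genes with smooth
#' random trends, TF-family labels sprinkled at a fixed fraction, and
#' designated guide genes inside modules.
#'
#' Archetypes (fixed smooth curves over the normalized stage position
#' x in \[0, 1\]):
#' * `mid_peak` — Gaussian bump maximal at the 14-18 DAF stages;
#' * `early_declining` — exponential decay from the first stage;
#' * `late_rising` — mirror image, maximal at the last stage;
#' * `flat_background` — constant.
#'
#' @param modules data.frame with columns `name`, `archetype` (one of the
#'   four above), `n_genes`, `base_fpkm`, `noise_sd` (log-scale SD of the
#'   per-stage multiplicative noise).
#' @param n_background number of independent background genes.
#' @param n_stages number of stages; labels are `"2DAF"`, `"6DAF"`, ...
#' @param tf_fraction fraction of genes (module and background alike)
#'   receiving a random TF-family label.
#' @param guides data.frame with columns `module_name`, `count`: how many
#'   member genes of each module are designated guides.
#' @param qpcr_noise_sd Gaussian Ct noise (cycles) for [generate_qpcr()].
#' @param background_log_range log10 range of background baseline FPKM,
#'   drawn log-uniformly.
#' @param background_noise_sd log-scale SD of per-stage multiplicative
#'   noise on background genes; default 0.25 (a 20-30% coefficient of
#'   variation, typical of single-library FPKM for genes outside tight
#'   co-regulation).
#' @param seed integer seed; all generators are pure functions of the spec.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(modules = data.frame(
                             name = c("mid", "early", "late"),
                             archetype = c("mid_peak", "early_declining", "late_rising"),
                             n_genes = c(50L, 50L, 50L),
                             base_fpkm = c(500, 200, 200),
                             noise_sd = 0.05),
                           n_background = 500L,
                           n_stages = 7L,
                           tf_fraction = 0.3,
                           guides = data.frame(module_name = character(0),
                                               count = integer(0)),
                           qpcr_noise_sd = 0.1,
                           background_log_range = c(0, 2),
                           background_noise_sd = 0.3,
                           seed = 1L) {
  known <- c("mid_peak", "early_declining", "late_rising", "flat_background")
  stopifnot(is.data.frame(modules),
            all(c("name", "archetype", "n_genes", "base_fpkm", "noise_sd")
                %in% names(modules)),
            all(modules$archetype %in% known),
            !anyDuplicated(modules$name),
            all(modules$n_genes >= 0), all(modules$base_fpkm > 0),
            all(modules$noise_sd >= 0),
            n_background >= 0, n_stages >= 3,
            tf_fraction >= 0, tf_fraction <= 1,
            all(guides$module_name %in% modules$name),
            qpcr_noise_sd >= 0, background_noise_sd >= 0)
  structure(list(modules = modules, n_background = as.integer(n_background),
                 n_stages = as.integer(n_stages), tf_fraction = tf_fraction,
                 guides = guides, qpcr_noise_sd = qpcr_noise_sd,
                 background_log_range = background_log_range,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param n number of stages.
#' @export
daf_stage_labels <- function(n) paste0(seq(2L, by = 4L, length.out = n), "DAF")

#' Archetype profile curves
#'
#' @param archetype archetype name.
#' @param n_stages number of stages.
#' @return positive numeric vector of length `n_stages` (relative units,
#'   max 1 for the peaked/monotone shapes).
#' @export
archetype_profile <- function(archetype, n_stages = 7L) {
  x <- seq(0, 1, length.out = n_stages)
  switch(archetype,
    mid_peak = exp(-(x - 7 / 12)^2 / (2 * 0.25^2)),
    early_declining = exp(-3 * x),
    late_rising = exp(-3 * (1 - x)),
    flat_background = rep(1, n_stages),
    stop("unknown archetype: ", archetype, call. = FALSE))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

tf_family_pool <- c("MYB", "bHLH", "AP2-EREBP", "NAC", "MADS", "WRKY",
                    "C2H2", "B3", "GRF", "HSF")

#' Generate a synthetic FPKM matrix with planted truth
#'
#' Module gene profiles are the module's archetype curve scaled by
#' `base_fpkm` under stage-wise multiplicative log-normal noise
#' (`exp(N(0, noise_sd))` per cell — multiplicative, so values stay
#' positive and look FPKM-like). Background genes get independent smooth
#' random profiles — log-scale Gaussian expression waves with random peak
#' time, width and amplitude, not white noise — so that chance
#' correlations at n = 7 stages are realistically non-trivial (boundary
#' peaks yield monotone trends, the shapes most likely to cross a hard
#' correlation cutoff). TF-family labels are assigned uniformly at random
#' at `tf_fraction` across all genes; guides are the first genes of their
#' modules.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (class `"synthetic_truth"`): `module` (named character, `"background"`
#'   for background genes), `tf_family` (named character, NA when
#'   unlabeled), `guides` (character), `noiseless` (matrix of noise-free
#'   profiles), `spec`.
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stages <- daf_stage_labels(spec$n_stages)
  x <- seq(0, 1, length.out = spec$n_stages)
  with_seed(spec$seed, {
    rows <- list(); noiseless <- list(); module_of <- character(0)
    for (i in seq_len(nrow(spec$modules))) {
      mod <- spec$modules[i, ]
      if (mod$n_genes == 0L) next
      prof <- archetype_profile(mod$archetype, spec$n_stages) * mod$base_fpkm
      ids <- sprintf("%s_g%03d", mod$name, seq_len(mod$n_genes))
      noise <- matrix(stats::rnorm(mod$n_genes * spec$n_stages, 0, mod$noise_sd),
                      mod$n_genes, spec$n_stages)
      vals <- matrix(prof, mod$n_genes, spec$n_stages, byrow = TRUE) * exp(noise)
      dimnames(vals) <- list(ids, stages)
      rows[[length(rows) + 1L]] <- vals
      noiseless[[length(noiseless) + 1L]] <-
        matrix(prof, mod$n_genes, spec$n_stages, byrow = TRUE,
               dimnames = list(ids, stages))
      module_of <- c(module_of, stats::setNames(rep(mod$name, mod$n_genes), ids))
    }
    if (spec$n_background > 0L) {
      ids <- sprintf("bg_g%04d", seq_len(spec$n_background))
      base <- 10^stats::runif(spec$n_background, spec$background_log_range[1],
                              spec$background_log_range[2])
      # smooth expression waves with random peak time, width and amplitude:
      # development moves in waves, so peaks fall anywhere in (or just
      # outside) the sampled window; boundary peaks give monotone trends
      amp <- stats::rnorm(spec$n_background, 0, 0.6)
      ctr <- stats::runif(spec$n_background, -0.2, 1.2)
      wid <- stats::runif(spec$n_background, 0.15, 0.4)
      trend <- amp * exp(-(outer(-ctr, x, "+"))^2 / (2 * wid^2))
      nl <- base * exp(trend)
      noise <- matrix(stats::rnorm(spec$n_background * spec$n_stages, 0,
                                   spec$background_noise_sd),
                      spec$n_background, spec$n_stages)
      vals <- nl * exp(noise)
      dimnames(vals) <- dimnames(nl) <- list(ids, stages)
      rows[[length(rows) + 1L]] <- vals
      noiseless[[length(noiseless) + 1L]] <- nl
      module_of <- c(module_of, stats::setNames(rep("background", length(ids)), ids))
    }
    mat <- do.call(rbind, rows)
    nl <- do.call(rbind, noiseless)
    genes <- rownames(mat)
    tf <- stats::setNames(rep(NA_character_, length(genes)), genes)
    labeled <- stats::runif(length(genes)) < spec$tf_fraction
    tf[labeled] <- sample(tf_family_pool, sum(labeled), replace = TRUE)
    guides <- character(0)
    if (nrow(spec$guides)) {
      for (i in seq_len(nrow(spec$guides))) {
        members <- names(module_of)[module_of == spec$guides$module_name[i]]
        guides <- c(guides, utils::head(members, spec$guides$count[i]))
      }
    }
    truth <- structure(list(module = module_of, tf_family = tf,
                            guides = guides, noiseless = nl, spec = spec),
                       class = "synthetic_truth")
    list(matrix = expression_matrix(mat), truth = truth)
  })
}

#' Generate synthetic fragment counts inverting the FPKM formula
#'
#' Draws gene lengths (uniform 300-3000 bp) and per-stage library sizes
#' (uniform 10-30 million mapped fragments), then sets
#' `counts = round(fpkm * length * library / 1e9)` so that
#' [compute_fpkm()] recovers the generated FPKM matrix up to integer
#' rounding (absolute FPKM error at most `1e9 / (2 * length * library)`
#' per cell... i.e. half a count).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (a [count_matrix()]), `fpkm` (the target
#'   [expression_matrix()]) and `truth`.
#' @export
generate_counts <- function(spec) {
  gm <- generate_matrix(spec)
  m <- gm$matrix
  with_seed(spec$seed + 1L, {
    len <- stats::setNames(round(stats::runif(nrow(m), 300, 3000)), rownames(m))
    lib <- stats::setNames(round(stats::runif(ncol(m), 1e7, 3e7)), colnames(m))
    counts <- round(m * outer(len, lib) / 1e9)
    cm <- count_matrix(counts, len, lib)
    list(counts = cm, fpkm = m, truth = gm$truth)
  })
}

#' Generate a synthetic qPCR plate from planted truth
#'
#' Encodes each selected gene's noiseless relative profile in Ct space:
#' the reference gene (an actin-like internal control) sits at a constant
#' Ct, and each target's Ct is `ref_ct - log2(level) + N(0, qpcr_noise_sd)`
#' so that the 2^-ddCt readout recovers the planted stage ratios exactly
#' at zero noise.
#'
#' @param truth a `synthetic_truth` from [generate_matrix()].
#' @param genes target gene ids (must exist in the truth).
#' @param stages stage labels to assay (default: stages 1, 3, 5, 7 of the
#'   design, mirroring a 4-of-7 validation layout).
#' @param n_replicates biological replicates per (gene, stage); default 4.
#' @param ref_ct baseline Ct of the reference gene.
#' @param reference_id id of the reference gene row.
#' @return a [qpcr_table()] calibrated to the earliest assayed stage.
#' @export
generate_qpcr <- function(truth, genes, stages = NULL, n_replicates = 4L,
                          ref_ct = 20, reference_id = "actin") {
  stopifnot(inherits(truth, "synthetic_truth"))
  all_stages <- colnames(truth$noiseless)
  if (is.null(stages))
    stages <- all_stages[unique(pmin(length(all_stages), c(1L, 3L, 5L, 7L)))]
  stopifnot(all(genes %in% rownames(truth$noiseless)),
            all(stages %in% all_stages), n_replicates >= 1)
  sdq <- truth$spec$qpcr_noise_sd
  with_seed(truth$spec$seed + 2L, {
    grid <- expand.grid(replicate = seq_len(n_replicates), stage = stages,
                        gene = genes, stringsAsFactors = FALSE)
    level <- truth$noiseless[cbind(grid$gene, grid$stage)]
    grid$ct <- ref_ct - log2(level) + stats::rnorm(nrow(grid), 0, sdq)
    grid$is_reference <- FALSE
    refs <- expand.grid(replicate = seq_len(n_replicates), stage = stages,
                        gene = reference_id, stringsAsFactors = FALSE)
    refs$ct <- ref_ct + stats::rnorm(nrow(refs), 0, sdq)
    refs$is_reference <- TRUE
    df <- rbind(grid, refs)[c("gene", "stage", "replicate", "ct", "is_reference")]
    qpcr_table(df, calibrator_stage = stages[1])
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 for random.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Score pipeline recovery against planted truth
#'
#' `score_partition_recovery()` compares a component partition with the
#' planted module membership by ARI over the non-background genes
#' (background genes have no planted structure to recover; genes absent
#' from every component count as their own singletons).
#' `score_guide_recovery()` scores a guide query's neighbor set against
#' the guide's module co-members with precision and recall.
#'
#' @param partition a [connected_components()] result.
#' @param truth a `synthetic_truth`.
#' @return for partitions: list(ari); for guides: list(precision, recall,
#'   n_true, n_found).
#' @export
score_partition_recovery <- function(partition, truth) {
  planted <- names(truth$module)[truth$module != "background"]
  pred <- rep(NA_character_, length(planted))
  names(pred) <- planted
  for (i in seq_along(partition$components)) {
    hit <- intersect(partition$components[[i]], planted)
    pred[hit] <- paste0("comp", i)
  }
  # unassigned genes are singletons
  lone <- is.na(pred)
  pred[lone] <- paste0("single_", which(lone))
  list(ari = adjusted_rand_index(truth$module[planted], pred))
}

#' @rdname score_partition_recovery
#' @param result a single [guide_query()] result.
#' @export
score_guide_recovery <- function(result, truth) {
  g <- result$guide_id
  mod <- truth$module[[g]]
  true_set <- setdiff(names(truth$module)[truth$module == mod], g)
  found <- result$neighbors$gene_id
  tp <- length(intersect(found, true_set))
  list(precision = if (length(found)) tp / length(found) else NA_real_,
       recall = if (length(true_set)) tp / length(true_set) else NA_real_,
       n_true = length(true_set), n_found = length(found))
}

#' Annotation table of a synthetic truth
#'
#' @param truth a `synthetic_truth`.
#' @return an [annotation_table()] with the planted `tf_family` labels.
#' @export
truth_annotation <- function(truth) {
  lab <- truth$tf_family[!is.na(truth$tf_family)]
  annotation_table(data.frame(gene = names(lab), namespace = "tf_family",
                              label = unname(lab), stringsAsFactors = FALSE))
}
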