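#' FPKM normalization from fragment counts
#'
#' Fragments Per Kilobase of exon per Million mapped fragments:
#' \deqn{FPKM_{gs} = \frac{c_{gs} \cdot 10^9}{L_g \cdot N_s}}
#' where \eqn{c_{gs}} is the fragment count of gene g in stage s, \eqn{L_g}
#' the exon length in bp, and \eqn{N_s} the total mapped fragments of the
#' stage's library.
#'
#' @param cm a [count_matrix()].
#' @return an [expression_matrix()] of FPKM values, same dimnames as the
#'   counts.
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  len <- cm$gene_lengths[rownames(cm$counts)]
  lib <- cm$library_sizes[colnames(cm$counts)]
  fpkm <- cm$counts * 1e9 / outer(len, lib)
  expression_matrix(fpkm)
}

#' Expression filters on FPKM matrices
#'
#' Three row filters reproduce the standard staged-transcriptome funnel:
#'
#' * `filter_widely_expressed()` keeps genes with FPKM strictly above
#'   `min_fpkm` in *every* stage;
#' * `filter_fold_range()` keeps genes whose (max + pseudocount) /
#'   (min + pseudocount) ratio across stages strictly exceeds `fold_min`
#'   (pseudocount defaults to 0, appropriate downstream of the FPKM > 1
#'   filter);
#' * `presence_filter()` drops genes not detected (value at or below
#'   `detection_floor`) in at least `exclusion_fraction` of the stages.
#'
#' All three are idempotent and return gene id sets, so they compose in any
#' order via `intersect()`.
#'
#' @param m an expression matrix.
#' @param min_fpkm widely-expressed cutoff (strict `>`).
#' @param fold_min minimum fold ratio (strict `>`, must be > 1).
#' @param pseudocount added to max and min before the ratio.
#' @param exclusion_fraction fraction of undetected stages at or above which
#'   a gene is excluded; in (0, 1].
#' @param detection_floor detection limit; a stage with value <= floor
#'   counts as not expressed.
#' @return character vector of retained gene ids (in matrix row order).
#' @export
filter_widely_expressed <- function(m, min_fpkm = 1.0) {
  stopifnot(min_fpkm >= 0)
  keep <- apply(m, 1L, function(row) all(row > min_fpkm))
  rownames(m)[keep]
}

#' @rdname filter_widely_expressed
#' @export
filter_fold_range <- function(m, fold_min = 2.0, pseudocount = 0) {
  stopifnot(fold_min > 1, pseudocount >= 0)
  hi <- apply(m, 1L, max)
  lo <- apply(m, 1L, min)
  keep <- (hi + pseudocount) / (lo + pseudocount) > fold_min
  rownames(m)[keep]
}

#' @rdname filter_widely_expressed
#' @export
presence_filter <- function(m, exclusion_fraction = 0.6, detection_floor = 0) {
  stopifnot(exclusion_fraction > 0, exclusion_fraction <= 1)
  frac_absent <- rowMeans(m <= detection_floor)
  rownames(m)[frac_absent < exclusion_fraction]
}

#' Per-gene Z-score stage profiles
#'
#' Standardizes each gene's profile across stages to mean 0 and sample
#' (n - 1) standard deviation 1, the transform used for expression heatmaps.
#' Genes constant across stages have no defined Z-score; they are given
#' all-zero rows and flagged in the `constant_genes` attribute rather than
#' dropped.
#'
#' @param m an expression matrix (>= 2 stages).
#' @return numeric matrix of Z-scores, same dimnames as `m`, with attribute
#'   `constant_genes` (character vector).
#' @export
zscore_profiles <- function(m) {
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  sdv[constant] <- 1
  z <- (m - mu) / sdv
  z[constant, ] <- 0
  z <- unclass(z)
  attr(z, "constant_genes") <- rownames(m)[constant]
  z
}
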