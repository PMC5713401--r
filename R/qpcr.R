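#' Delta-Ct and 2^-ddCt primitives
#'
#' `delta_ct()` is the target-minus-reference Ct difference within a well
#' group; `ddct_fold_change()` exponentiates the difference of two delta-Ct
#' values base 2 (amplification efficiency fixed at 2, as the method's name
#' implies), giving the fold change of the sample relative to the
#' calibrator (calibrator = 1).
#'
#' @param target_ct,reference_ct finite Ct values (vectorized).
#' @param sample_dct,calibrator_dct finite delta-Ct values (vectorized).
#' @return numeric vector.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  stopifnot(all(is.finite(target_ct)), all(is.finite(reference_ct)))
  target_ct - reference_ct
}

#' @rdname delta_ct
#' @export
ddct_fold_change <- function(sample_dct, calibrator_dct) {
  stopifnot(all(is.finite(sample_dct)), all(is.finite(calibrator_dct)))
  2^(-(sample_dct - calibrator_dct))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each target gene and stage: per-replicate delta-Ct against the
#' reference gene in the same (stage, replicate); delta-delta-Ct against
#' the gene's calibrator-stage delta-Ct; fold change 2^-ddCt. Replicate
#' handling (`mode`):
#' * `"per_replicate"` (default, common practice): each replicate's
#'   delta-Ct is differenced against the calibrator stage's *mean* delta-Ct,
#'   then fold changes are averaged — the calibrator's mean fold change is 1
#'   only up to replicate noise;
#' * `"mean_of_means"`: delta-Ct values are first averaged per stage, so
#'   the calibrator fold change is exactly 1.
#'
#' The whole pipeline is invariant to any additive Ct shift applied to both
#' target and reference within a (stage, replicate) — plate effects cancel.
#'
#' @param q a [qpcr_table()] (carries its calibrator stage).
#' @param mode replicate handling, see above.
#' @return data.frame of class `"relative_expression"`: one row per
#'   (gene, stage) with `fold_change` (mean over replicates), `sd`, `n`,
#'   and per-replicate values in list-column `replicate_values`.
#' @export
relative_expression_table <- function(q, mode = c("per_replicate", "mean_of_means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(q, "qpcr_table"))
  calib <- attr(q, "calibrator_stage")
  refs <- q[q$is_reference, , drop = FALSE]
  targets <- q[!q$is_reference, , drop = FALSE]
  refkey <- paste(refs$stage, refs$replicate, sep = "\r")
  ref_ct <- tapply(refs$ct, refkey, mean)  # average if several reference wells
  out <- list()
  for (g in unique(targets$gene)) {
    tg <- targets[targets$gene == g, , drop = FALSE]
    dct <- delta_ct(tg$ct, as.numeric(ref_ct[paste(tg$stage, tg$replicate, sep = "\r")]))
    if (!calib %in% tg$stage)
      stop("calibrator stage '", calib, "' missing for gene '", g, "'",
           call. = FALSE)
    calib_dct <- mean(dct[tg$stage == calib])
    for (s in unique(tg$stage)) {
      ds <- dct[tg$stage == s]
      if (mode == "per_replicate") {
        fc <- ddct_fold_change(ds, calib_dct)
        fc_mean <- mean(fc)
      } else {
        fc <- ddct_fold_change(mean(ds), calib_dct)
        fc_mean <- fc
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, stage_label = s, fold_change = fc_mean,
        sd = if (length(fc) > 1) stats::sd(fc) else NA_real_,
        n = length(ds), stringsAsFactors = FALSE)
      out[[length(out)]]$replicate_values <- I(list(fc))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("relative_expression", "data.frame")
  attr(res, "calibrator_stage") <- calib
  res
}

#' qPCR vs RNA-seq concordance
#'
#' Pearson correlation between a gene's RNA-seq stage profile (FPKM) and
#' its qPCR fold-change profile over the same stages. By default both
#' profiles are log2-transformed (with a pseudocount on FPKM) before
#' correlating, which stabilizes the scale; `log = FALSE` correlates raw
#' values. Reported per gene and pooled — the pooled value is computed both
#' as the correlation over all (gene, stage) points and as the mean of
#' per-gene correlations, since either aggregation is defensible.
#'
#' @param m an expression matrix holding the RNA-seq profiles.
#' @param relexpr a [relative_expression_table()] result.
#' @param log correlate on log2 scale (default TRUE).
#' @param pseudocount added to FPKM before log2.
#' @return list: `per_gene` (data.frame gene_id, r), `pooled_r` (all points
#'   pooled), `mean_gene_r` (mean of per-gene r), `stages` used.
#' @export
concordance <- function(m, relexpr, log = TRUE, pseudocount = 1) {
  genes <- intersect(unique(relexpr$gene_id), rownames(m))
  stages <- intersect(colnames(m), unique(relexpr$stage_label))
  missing_st <- setdiff(unique(relexpr$stage_label), colnames(m))
  if (length(missing_st))
    stop("qPCR stages absent from expression matrix: ",
         paste(missing_st, collapse = ", "), call. = FALSE)
  if (length(stages) < 3)
    stop("need >= 3 shared stages for concordance", call. = FALSE)
  xform_rna <- function(v) if (log) log2(v + pseudocount) else v
  xform_q <- function(v) if (log) log2(v) else v
  all_rna <- c(); all_q <- c()
  per <- lapply(genes, function(g) {
    sub <- relexpr[relexpr$gene_id == g, , drop = FALSE]
    qv <- stats::setNames(sub$fold_change, sub$stage_label)[stages]
    rv <- m[g, stages]
    all_rna <<- c(all_rna, xform_rna(rv)); all_q <<- c(all_q, xform_q(qv))
    data.frame(gene_id = g, r = pearson_r(xform_rna(rv), xform_q(qv)))
  })
  per <- do.call(rbind, per)
  list(per_gene = per,
       pooled_r = pearson_r(all_rna, all_q),
       mean_gene_r = mean(per$r),
       stages = stages)
}
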