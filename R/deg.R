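#' Log2 fold change with pseudocount
#'
#' `log2((b + pseudocount) / (a + pseudocount))`, the change of stage B
#' relative to stage A. Antisymmetric under swapping the arguments.
#'
#' @param a,b non-negative FPKM values (vectorized).
#' @param pseudocount positive stabilizer; default 1 (FPKM units).
#' @return numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1) {
  stopifnot(pseudocount > 0, all(a >= 0), all(b >= 0))
  log2((b + pseudocount) / (a + pseudocount))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR control: with p-values ranked ascending, the adjusted value
#' at rank i is `min_{j >= i} (n / j) * p_(j)`, capped at 1; output order
#' matches input order. Implemented directly (cumulative minimum over the
#' reversed ranked vector) so it can be cross-checked against the
#' enumerated step-up definition.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
  adj
}

#' Classify differential-expression calls
#'
#' A gene pair comparison is called `up` when log2FC strictly exceeds the
#' threshold and (if an FDR is supplied) the FDR is strictly below the FDR
#' cutoff; symmetric for `down`; otherwise `ns`. The dispersion test that
#' produces the p-values is upstream of this package (edgeR-style tools);
#' here p-values are optional externally supplied inputs.
#'
#' @param records data.frame with columns `gene_id`, `stage_a`, `stage_b`,
#'   `log2fc` and optionally `pvalue` and/or `fdr` (NA allowed).
#' @param config a [pipeline_config()].
#' @return the data.frame with a `call` factor column (`up`/`down`/`ns`).
#' @export
classify_deg <- function(records, config = pipeline_config()) {
  stopifnot(is.data.frame(records), "log2fc" %in% names(records))
  fdr <- if ("fdr" %in% names(records)) records$fdr else rep(NA_real_, nrow(records))
  sig <- is.na(fdr) | fdr < config$fdr_threshold
  call <- rep("ns", nrow(records))
  call[sig & records$log2fc > config$log2fc_threshold] <- "up"
  call[sig & records$log2fc < -config$log2fc_threshold] <- "down"
  records$call <- factor(call, levels = c("up", "down", "ns"))
  records
}

#' Pairwise DEG count matrix across stages
#'
#' For every ordered stage pair (a, b) counts genes called up and down in b
#' relative to a, producing the familiar triangular up/down summary of
#' staged designs. When no FDR information breaks the symmetry,
#' `n_up(a, b) == n_down(b, a)` exactly.
#'
#' @param m an expression matrix.
#' @param config a [pipeline_config()]; `log2fc_threshold`, `fdr_threshold`
#'   and `pseudocount` are used.
#' @param pvalues optional function `(stage_a, stage_b) -> numeric` giving a
#'   per-gene p-value vector for the pair (aligned with `rownames(m)`); when
#'   supplied, values are BH-adjusted per pair before calling.
#' @return object of class `"deg_count_matrix"`: a data.frame with columns
#'   `stage_a`, `stage_b`, `n_up`, `n_down` for all ordered pairs, plus the
#'   stage order in attribute `stages`.
#' @export
deg_count_matrix <- function(m, config = pipeline_config(), pvalues = NULL) {
  stages <- colnames(m)
  stopifnot(length(stages) >= 2)
  grid <- expand.grid(a = seq_along(stages), b = seq_along(stages))
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$a[i]; b <- grid$b[i]
    lfc <- log2_fold_change(m[, a], m[, b], config$pseudocount)
    rec <- data.frame(gene_id = rownames(m), stage_a = stages[a],
                      stage_b = stages[b], log2fc = lfc)
    if (!is.null(pvalues))
      rec$fdr <- bh_adjust(pvalues(stages[a], stages[b]))
    rec <- classify_deg(rec, config)
    data.frame(stage_a = stages[a], stage_b = stages[b],
               n_up = sum(rec$call == "up"), n_down = sum(rec$call == "down"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("deg_count_matrix", "data.frame"), stages = stages)
}

#' @export
print.deg_count_matrix <- function(x, ...) {
  stages <- attr(x, "stages")
  cat("DEG counts (row = earlier stage a, col = later stage b, cell = up/down in b vs a)\n")
  fmt <- matrix("", length(stages), length(stages),
                dimnames = list(stages, stages))
  for (i in seq_len(nrow(x)))
    fmt[x$stage_a[i], x$stage_b[i]] <- sprintf("%d↑ %d↓",
                                               x$n_up[i], x$n_down[i])
  print(as.data.frame(fmt), ...)
  invisible(x)
}
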