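---
title: "Methods: staged-seed coexpression, guide-gene queries, and their synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged-seed coexpression, guide-gene queries, and their synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcoexp)
```

## The model and its assumptions

The pipeline operates on a gene-by-stage matrix of FPKM values from a
*single* biological series — one library per developmental stage, no
replicates. That design constrains everything downstream:

* There is no within-stage variance estimate, so "differential expression"
  between two stages is a fold-change statement, optionally combined with
  p-values supplied by an external count-based test. This package
  deliberately does not re-implement such a test; it consumes p-values when
  given and applies only thresholding plus Benjamini–Hochberg adjustment.
* Correlation across stages is computed over n = 7 points. A Pearson r of
  0.95 at n = 7 is far from conventional significance — under an
  independence null roughly one pair in a thousand of *smooth* profiles
  crosses it (the test suite measures this; see "the null rate" below). The
  hard cutoff is therefore a *selection rule*, not a test, and the package
  treats it as such: strict inequalities exactly where the convention says
  "greater than", both signs kept in `absolute` mode because strongly
  anticorrelated partners are biologically meaningful (they appear as
  dotted edges in the conventional network figures).
* FPKM, not log FPKM, is the correlation substrate, matching field
  practice for this analysis. A consequence worth knowing: on the raw
  scale, correlation between co-monotone convex profiles is dominated by
  the highest-expression stages, so monotone profiles correlate much more
  easily than intuition from log-scale data suggests. The synthetic world
  below is designed with this in mind.

## The pipeline

1. **Normalization** — `compute_fpkm()`: `c · 10⁹ / (L · N)` per cell.
2. **Filter funnel** — presence filter (gene dropped when undetected in
   ≥ 60 % of stages; detection floor 0 by default, configurable because
   "detected" is never defined in field descriptions), widely-expressed
   filter (FPKM > 1 in *every* stage, strict), fold-range filter
   (max/min > 2, strict; no pseudocount by default since the upstream
   filter guarantees values > 1). All filters are idempotent and
   set-valued, so they compose transparently.
3. **Network** — exact all-pairs Pearson via centered, row-normalized
   matrix products; edges where |r| > 0.95 (or r > 0.95 in
   `positive_only` mode); connected components as subnetworks, sorted by
   size with lexicographic tie-breaks so every output is byte-stable.
4. **Guide queries** — correlation of each guide against the full
   filtered matrix (not just a pre-built network): a soft prescreen at
   |r| > 0.6 followed by the hard 0.95 report threshold. The prescreen is
   read as a pure optimization — it sits strictly below the report
   threshold, so it can never change results (a property the tests
   enforce). Neighbors carry signed r and TF-family labels; family
   distributions count genes once per family, flagging multi-family genes.
5. **qPCR validation** — 2^−ΔΔCt with a reference gene and a calibrator
   stage. ΔΔCt is computed per replicate against the calibrator's *mean*
   ΔCt (common practice; a `mean_of_means` mode is provided because
   replicate handling is rarely specified). The calibrator defaults to the
   earliest stage. Amplification efficiency is fixed at 2. Concordance
   with RNA-seq is Pearson r on log2 scale by default (raw mode
   available), reported per gene, pooled over all (gene, stage) points,
   and as the mean of per-gene r — the pooled aggregation is not
   standardized in the field, so both are emitted.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_fpkm_all_samples` | 1.0 | FPKM | "widely expressed" convention; strict > |
| `fold_change_min` | 2.0 | ratio | "more than two-fold"; strict > |
| `presence_exclusion_fraction` | 0.6 | fraction of stages | 60 % exclusion rule |
| `detection_floor` | 0 | FPKM | "expressed" means > 0 unless stated |
| `correlation_threshold` | 0.95 | r | hard coexpression cutoff; strict > |
| `prefilter_threshold` | 0.6 | r | soft guide prescreen; must be ≤ threshold |
| `threshold_mode` | absolute | — | negative partners are reported in practice |
| `log2fc_threshold` | 1.0 | log2 | DEG rule; strict > |
| `fdr_threshold` | 0.05 | — | BH-adjusted; strict < |
| `pseudocount` | 1.0 | FPKM | bounded distortion once FPKM > 1 |

## What the synthetic world emulates — and what it does not

`synthetic_spec()` describes a 7-stage series (2–26 DAF) with three planted
module archetypes: `mid_peak` (Gaussian bump on normalized stage position,
maximal at the 14/18 DAF stages, ≈15:1 dynamic range), `early_declining`
(exponential decay, 20:1), `late_rising` (its mirror). Module genes are the
archetype times a base FPKM (defaults 500/200/200 — module genes represent
well-expressed pathway genes that must comfortably survive the FPKM > 1
filter) under per-cell multiplicative log-normal noise (sd 0.05 on the log
scale, calibrated so within-module mean r stays ≥ 0.98, the regime the
planted-recovery checks assume). Multiplicative rather than additive noise
keeps values positive and reproduces the heavy-tailed look of FPKM data.

Background genes are *not* white noise: each gets a smooth log-scale
Gaussian expression wave with random amplitude (N(0, 0.6)), random peak
time (uniform on a window slightly wider than the sampled course, so
boundary peaks yield monotone trends), random width (0.15–0.4 of the
course), plus per-stage log-noise of sd 0.3 (a 20–30 % CV, typical of
single-library FPKM outside tight co-regulation). This family was a
deliberate design decision. A first candidate — random low-order
polynomial log-trends — turned out to be structurally incompatible with
recoverable planted structure: such backgrounds are dominated by monotone
shapes, and on the raw FPKM scale *any* co-monotone convex pair at n = 7
correlates above 0.95 (we measured r = 0.949 between exp(−3x) and
exp(−0.5x) profiles), so background genes bridged the early and late
modules in every run. Waves with random peak times are both more realistic
for development (genes peak in waves across the course) and only
occasionally monotone, giving a null |r| > 0.95 edge rate of ~1.7 × 10⁻³ —
small enough for module recovery, large enough to document that the 0.95
cutoff at n = 7 is permissive.

What a green recovery test establishes: the pipeline's filters, exact
correlations, thresholding and component logic jointly recover planted
structure under calibrated noise. What it does not establish: performance
on real transcriptomes, where co-monotone trends are abundant, modules are
not equicorrelated blocks, and expression is not log-normal around smooth
curves. In particular the generator has no isoform structure, no
count-level overdispersion beyond rounding, and no correlated background.

Synthetic qPCR plates encode each gene's noiseless stage profile in Ct
space (`Ct = ref − log2(level) + noise`), so the 2^−ΔΔCt reduction inverts
them exactly at zero noise — the tests exploit this as a closed-loop
oracle.

## Numerical choices

* Correlations are clamped to [−1, 1] after matrix products; constant
  genes are never silently given r = 0 — scalar `pearson_r()` raises an
  error, matrix routines exclude and report them, Z-scoring flags them and
  emits zero rows.
* Sample (n − 1) standard deviation throughout.
* Every sort has a deterministic key (component size then smallest member;
  |r| descending then gene id; C-locale radix order for label ties), so
  repeated runs produce byte-identical files; generators save and restore
  the caller's RNG state.
* BH adjustment is the cumulative-minimum step-up form, checked against an
  enumerated textbook oracle rather than delegated to `p.adjust`, keeping
  implementation and oracle independent.
* `generate_counts()` inverts the FPKM formula with rounding; the
  per-cell FPKM error bound `10⁹ / (2 L N)` is asserted in tests.

## Design choices where the convention was open

* The published "default value 0.6" for guide coexpression is read as a
  soft prefilter below the 0.95 report threshold — the only reading
  consistent with reporting only |r| > 0.95 partners. Both knobs are
  exposed.
* Guide TF counts can be read per guide or as the union over guides;
  `guide_query()` returns per-guide results and `merge_guide_networks()`
  the union, so both are available.
* The residual set of `main_subnetworks()` (genes outside the top-k
  components) is this package's interpretation of "less correlated with
  others" members of a coexpressed gene set.
* DEG p-values are optional external inputs; without them, calls reduce to
  the fold-change rule, which keeps the up/down count matrix exactly
  antisymmetric under stage-pair reversal (asserted in tests).

## Known limitations

* The null-rate self-consistency check uses a binomial envelope around a
  20-seed mean; pair events share genes, so the true seed-to-seed spread
  is ~1.6× the binomial sd and the envelope is mildly anti-conservative.
  It is used as a generator guard, not as an inference procedure.
* At n = 7 stages, r > 0.95 is a permissive selector (≈10⁻³ null edge
  rate even for wave-like backgrounds, far higher for monotone ones).
  Conclusions drawn from such networks on real data inherit that caveat;
  this package makes the rate measurable rather than hiding it.
* No soft-thresholding/WGCNA-style module detection, no enrichment
  statistics, no efficiency-corrected qPCR variants — all out of scope.
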