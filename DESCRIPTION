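Package: seedcoexp
Title: Guide-Gene Coexpression Analysis for Staged Seed Transcriptomes
Version: 0.1.0
Authors@R:
    person("Seed", "Coexpression Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for guide-gene coexpression analysis of staged (time-course)
    bulk RNA-seq expression data, as used in oilseed developmental studies:
    FPKM normalization from fragment counts, expression-level and fold-range
    filtering, Pearson coexpression network construction with hard
    correlation thresholds, subnetwork (connected component) decomposition,
    guide-gene neighbourhood queries overlaid with transcription-factor
    family annotation, pairwise differential-expression count summaries,
    per-gene Z-score stage profiles, and 2^-ddCt qPCR relative
    quantification with RNA-seq concordance checks. Includes a synthetic
    staged-transcriptome generator with planted temporal modules and
    designated guide genes so the whole pipeline can be exercised and scored
    against known truth without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
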