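Package: somatichit
Title: Somatic Variant Prioritization and Two-Hit Integration for
    Tumor-Suppressor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tumor/normal somatic variant prioritization pipeline for
    whole-exome cohorts: multi-caller consensus calling (2-of-3 in tumors,
    1-of-3 in normals), read-support and population-frequency somatic
    filtering with cohort-wide blacklist propagation, a four-step
    functional-consequence cascade (coding/splice region, silent with
    splicing-impact rescue, expression, deleteriousness majority vote with
    indel overrides), recurrence-based candidate gene selection
    cross-referenced against an external cohort, gene-level copy-number
    calling from SEG segmentation, and integration of mutation zygosity with
    copy state into biallelic ("two-hit") inactivation calls. Includes
    per-sample hypergeometric gene-set enrichment, cohort burden and
    mutation-spectrum summaries, exact one-tailed rank-sum comparisons, and
    a truth-labelled synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
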