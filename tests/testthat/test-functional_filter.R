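fcfg <- functional_filter_config(expressed_genes = c("TP53", "SHPRH"))

test_that("region filter keeps only coding and splice-site classes", {
  expect_equal(filter_region(c("INTRONIC", "SPLICING", "UTR", "EXONIC",
                               "EXONIC_SPLICING", "INTERGENIC")),
               c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("silent variants are removed unless spliceogenic (|z| >= 2, inclusive)", {
  expect_false(filter_silent("SILENT", 1.5, fcfg))
  expect_true(filter_silent("SILENT", -2.3, fcfg))
  expect_true(filter_silent("SILENT", 2.0, fcfg))   # inclusive bound
  expect_false(filter_silent("SILENT", NA_real_, fcfg))
  expect_true(filter_silent("MISSENSE", NA_real_, fcfg))
})

test_that("expression filter is exact-match by default and refuses an empty set", {
  expect_true(filter_expression("TP53", fcfg))
  expect_false(filter_expression("tp53", fcfg))
  ci <- functional_filter_config(c("TP53"), case_insensitive_genes = TRUE)
  expect_true(filter_expression("tp53", ci))
  expect_error(filter_expression("TP53",
                                 structure(list(expressed_genes = character()),
                                           class = "functional_filter_config")),
               "empty")
})

test_that("tolerability vote follows the printed rule with overrides", {
  vm <- function(...) matrix(c(...), nrow = 1)
  # 3 of 6 tolerated: tie counts toward removal
  expect_false(predictor_vote("MISSENSE", vm("D","D","D","T","T","T"),
                              NA_real_, fcfg))
  # 2 of 6 tolerated: retained
  expect_true(predictor_vote("MISSENSE", vm("D","D","D","D","T","T"),
                             NA_real_, fcfg))
  # indel override beats an all-tolerated vote
  expect_true(predictor_vote("FRAMESHIFT_INDEL", vm("T","T","T","T","T","T"),
                             NA_real_, fcfg))
  # SPIDEX override
  expect_true(predictor_vote("MISSENSE", vm("T","T","T","T","T","T"),
                             2.4, fcfg))
  # missing verdicts leave the denominator: D,T,....  -> A=2, T=1 -> removed
  expect_false(predictor_vote("MISSENSE", vm("D","T",".",".",".","."),
                              NA_real_, fcfg))
  # under the all-predictors denominator the same vector is retained (T=1 < 3)
  all_cfg <- functional_filter_config(c("TP53"), vote_denominator = "all")
  expect_true(predictor_vote("MISSENSE", vm("D","T",".",".",".","."),
                             NA_real_, all_cfg))
  # no verdicts at all -> retained (insufficient evidence)
  expect_true(predictor_vote("MISSENSE", vm(".",".",".",".",".","."),
                             NA_real_, fcfg))
})

test_that("cascade applies stages in the printed order and traces removals", {
  som <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:3,
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
  preds <- matrix("D", 3, 6, dimnames = list(NULL, c("SIFT", "LRT",
    "MutationTaster", "MutationAssessor", "FATHMM", "MetaSVM")))
  ann <- data.frame(chrom = "chr1", pos = 1:3, ref = "C", alt = "T",
                    gene = c("TP53", "UNEXPR1", "TP53"),
                    region_class = c("EXONIC", "EXONIC", "INTRONIC"),
                    effect_class = c("MISSENSE", "SILENT", "MISSENSE"),
                    preds, spidex_dpsi_z = c(NA, 2.5, NA),
                    pop_freq_max = NA_real_, stringsAsFactors = FALSE)
  res <- run_functional_cascade(som, ann, fcfg)
  # pos 1 survives; pos 2 is silent-rescued but unexpressed (order matters);
  # pos 3 dies at REGION
  expect_equal(res$retained$pos, 1L)
  expect_equal(res$traces$stage[res$traces$pos == 2], "UNEXPRESSED")
  expect_equal(res$traces$stage[res$traces$pos == 3], "REGION")
  # empty input -> empty output, no traces
  empty <- run_functional_cascade(som[0, ], ann, fcfg)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$traces), 0L)
  # missing annotation is an error naming the key
  expect_error(run_functional_cascade(
    data.frame(sample_id = "S1", chrom = "chr9", pos = 9L, ref = "A",
               alt = "T"), ann, fcfg), "chr9:9:A:T")
})

test_that("planted silent variants vanish and expressed frameshifts survive the cascade", {
  co <- nonoise_cohort()
  tv <- co$gen$truth_variants
  ann <- read_annotation_table(file.path(co$dir, "annotations.tsv"))
  aid <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  expressed <- readLines(file.path(co$dir, "expressed_genes.txt"))
  fid <- paste(co$run$functional$sample_id,
               variant_id(co$run$functional$chrom, co$run$functional$pos,
                          co$run$functional$ref, co$run$functional$alt))
  tv$key <- variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)
  z <- ann$spidex_dpsi_z[match(tv$key, aid)]
  silent_plain <- tv$origin == "SOMATIC" & tv$effect_class == "SILENT" &
    (is.na(z) | abs(z) < 2)
  expect_length(intersect(paste(tv$sample_id, tv$key)[silent_plain], fid), 0L)
  fs_expr <- tv$origin == "SOMATIC" & tv$effect_class == "FRAMESHIFT_INDEL" &
    tv$gene %in% expressed & is.na(tv$pop_freq_max)
  expect_true(all(paste(tv$sample_id, tv$key)[fs_expr] %in% fid))
})
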