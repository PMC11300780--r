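test_that("read-support rules fire in order with the printed strictness", {
  cfg <- somatic_filter_config()
  # normal VAF exactly 5% -> removed (rule is inclusive)
  expect_equal(filter_read_support(50, 50, 95, 5, cfg), "NORMAL_VAF")
  # zero alt with 25 ref reads -> removed
  expect_equal(filter_read_support(25, 0, 100, 0, cfg), "ZERO_ALT")
  # tumor VAF 0.039 vs normal 0.020: below twice -> removed
  expect_equal(filter_read_support(961, 39, 98, 2, cfg), "VAF_RATIO")
  # normal VAF above 5% is reported as NORMAL_VAF even when the ratio rule
  # would also fire (first rule in the printed order wins)
  expect_equal(filter_read_support(90, 10, 949, 51, cfg), "NORMAL_VAF")
  # tumor VAF exactly twice the normal VAF -> retained ("less than" strict)
  expect_equal(filter_read_support(960, 40, 980, 20, cfg), "PASS")
  # zero alt, ref 15, zero-depth-free normal: no rule fires
  expect_equal(filter_read_support(15, 0, 100, 0, cfg), "PASS")
  # zero-depth normal defines VAF 0, so the ratio rule cannot fire
  expect_equal(filter_read_support(90, 10, 0, 0, cfg), "PASS")
  expect_error(filter_read_support(-1, 0, 10, 0, cfg), "non-negative")
})

test_that("population-frequency rule is strictly greater than 1%", {
  cfg <- somatic_filter_config()
  expect_true(filter_population_frequency(0.02, cfg))
  expect_false(filter_population_frequency(0.01, cfg))
  expect_false(filter_population_frequency(NA_real_, cfg))
  expect_error(filter_population_frequency(1.2, cfg), "outside")
})

test_that("blacklist propagation removes a failing key from every sample", {
  keys <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "C",
                     alt = "T")
  tumor_sets <- list(
    S3 = toy_tumor_set("S3", keys),
    S7 = toy_tumor_set("S7", keys))
  # chr1:100 fails VAF_RATIO in S3 only; chr1:200 passes everywhere
  counts <- data.frame(
    sample = c("S3", "S3", "S7", "S7"),
    chrom = "chr1", pos = c(100L, 200L, 100L, 200L), ref = "C", alt = "T",
    tumor_ref = c(95, 60, 60, 60), tumor_alt = c(5, 40, 40, 40),
    normal_ref = c(96, 100, 100, 100), normal_alt = c(4, 0, 0, 0))
  f <- file.path(withr::local_tempdir(), "counts.tsv")
  utils::write.table(counts, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "C", alt = "T",
                    pop_freq_max = NA_real_)
  res <- run_somatic_cascade(tumor_sets, character(), read_counts_table(f),
                             ann)
  ret <- variant_id(res$retained$chrom, res$retained$pos, res$retained$ref,
                    res$retained$alt)
  expect_equal(sort(paste(res$retained$sample_id, ret)),
               c("S3 chr1:200:C:T", "S7 chr1:200:C:T"))
  tr <- res$traces
  expect_equal(tr$stage[tr$sample_id == "S3" & tr$pos == 100], "VAF_RATIO")
  expect_equal(tr$stage[tr$sample_id == "S7" & tr$pos == 100], "BLACKLIST")
})

test_that("variants without counts are removed with a dedicated trace", {
  ts <- list(S1 = toy_tumor_set("S1", data.frame(chrom = "chr1", pos = 5L,
                                                 ref = "A", alt = "G")))
  counts <- data.frame(sample_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       tumor_ref = integer(), tumor_alt = integer(),
                       normal_ref = integer(), normal_alt = integer())
  ann <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), pop_freq_max = numeric())
  res <- run_somatic_cascade(ts, character(), counts, ann)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$traces$stage, "MISSING_COUNTS")
})

test_that("cascade conserves counts per stage and is deterministic", {
  co <- small_cohort()
  run <- co$run
  n_consensus <- sum(vapply(run$tumor_consensus, nrow, integer(1)))
  som_stages <- c("NORMAL_PANEL", "MISSING_COUNTS", "NORMAL_VAF", "ZERO_ALT",
                  "VAF_RATIO", "BLACKLIST", "POPFREQ")
  n_som_traces <- sum(run$traces$stage %in% som_stages)
  expect_equal(n_consensus, nrow(run$somatic) + n_som_traces)
  fun_stages <- c("REGION", "SILENT", "UNEXPRESSED", "PREDICTOR_VOTE")
  expect_equal(nrow(run$somatic),
               nrow(run$functional) + sum(run$traces$stage %in% fun_stages))
  # germline truth is fully removed before the somatic set
  tv <- co$gen$truth_variants
  gid <- paste(tv$sample_id,
               variant_id(tv$chrom, tv$pos, tv$ref, tv$alt))[tv$origin == "GERMLINE"]
  sid <- paste(run$somatic$sample_id,
               variant_id(run$somatic$chrom, run$somatic$pos,
                          run$somatic$ref, run$somatic$alt))
  expect_length(intersect(gid, sid), 0L)
})

test_that("tightening the normal-VAF threshold never grows the retained set", {
  co <- small_cohort()
  loose <- run_pipeline(co$dir,
                        somatic_cfg = somatic_filter_config(max_normal_vaf = 0.10))
  tight <- run_pipeline(co$dir,
                        somatic_cfg = somatic_filter_config(max_normal_vaf = 0.02))
  id <- function(r) paste(r$somatic$sample_id,
                          variant_id(r$somatic$chrom, r$somatic$pos,
                                     r$somatic$ref, r$somatic$alt))
  expect_true(all(id(tight) %in% id(loose)))
})
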