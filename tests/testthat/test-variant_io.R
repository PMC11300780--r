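test_that("normalization trims shared prefix/suffix and rejects degenerate keys", {
  k <- normalize_variant("chr1", 100, "AT", "AG")
  expect_equal(k[c("pos", "ref", "alt")], list(pos = 101L, ref = "T", alt = "G"))
  # suffix first, then prefix
  k <- normalize_variant("chr2", 10, "TACG", "TCCG")
  expect_equal(k[c("pos", "ref", "alt")], list(pos = 11L, ref = "A", alt = "C"))
  expect_error(normalize_variant("chr1", 100, "G", "G"), "ref == alt")
  expect_error(normalize_variant("chr1", 100, "", "A"), "non-empty")
  expect_error(normalize_variant("chr1", 0, "A", "C"), "positive")
})

test_that("indel left-alignment matches the exhaustive-shift oracle", {
  # reference context ...TACCC... anchored at position 99
  context <- "TACCC"
  fetch <- function(chrom, s, e) substr(context, s - 98L, e - 98L)
  k <- normalize_variant("chr1", 100, "ACC", "AC", ref_fetch = fetch)
  ora <- oracle_left_align_del(context, 99L, 100L, "AC", "A")
  expect_equal(k$pos, ora$pos)
  expect_equal(k$ref, ora$ref)
  expect_equal(k$alt, ora$alt)
  # a right-shifted representation of the same deletion converges to it
  k2 <- normalize_variant("chr1", 102, "CC", "C", ref_fetch = fetch)
  expect_equal(k2[c("pos", "ref", "alt")], k[c("pos", "ref", "alt")])
})

test_that("normalization is idempotent over generated keys", {
  set.seed(31)
  for (i in 1:50) {
    len_r <- sample(1:4, 1); len_a <- sample(1:4, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), len_r, TRUE), collapse = "")
    alt <- paste(sample(c("A", "C", "G", "T"), len_a, TRUE), collapse = "")
    if (ref == alt) next
    k1 <- normalize_variant("chrX", 500, ref, alt)
    k2 <- normalize_variant(k1$chrom, k1$pos, k1$ref, k1$alt)
    expect_identical(k1, k2)
  }
})

test_that("VCF reading splits multi-allelic sites independent of allele order", {
  dir <- withr::local_tempdir()
  write_vcf <- function(path, rows) {
    writeLines(c("##fileformat=VCFv4.2",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", sep = "\t"), rows), path)
  }
  f1 <- file.path(dir, "a.vcf")
  write_vcf(f1, c("chr1\t100\t.\tAT\tAG,AC\t.\tPASS\t.",
                  "chr6\t50\t.\tC\tT\t.\tPASS\t."))
  r <- read_caller_vcf(f1, "varscan", "S1", "TUMOR")
  expect_equal(nrow(r), 3L)
  expect_setequal(variant_id(r$chrom, r$pos, r$ref, r$alt),
                  c("chr1:101:T:G", "chr1:101:T:C", "chr6:50:C:T"))
  expect_true(all(r$caller == "varscan"))
  # allele listing order does not change the key set
  f2 <- file.path(dir, "b.vcf")
  write_vcf(f2, "chr1\t100\t.\tAT\tAC,AG\t.\tPASS\t.")
  r2 <- read_caller_vcf(f2, "varscan", "S1", "TUMOR")
  expect_setequal(variant_id(r2$chrom, r2$pos, r2$ref, r2$alt),
                  c("chr1:101:T:G", "chr1:101:T:C"))
  # header-only file -> empty
  f3 <- file.path(dir, "c.vcf")
  write_vcf(f3, character())
  expect_equal(nrow(read_caller_vcf(f3, "bcftools", "S1", "NORMAL")), 0L)
})

test_that("counts table enforces schema, duplicates and sign", {
  dir <- withr::local_tempdir()
  hdr <- "sample\tchrom\tpos\tref\talt\ttumor_ref\ttumor_alt\tnormal_ref\tnormal_alt"
  f <- file.path(dir, "c.tsv")
  writeLines(c(hdr, "S1\tchr6\t100\tC\tT\t90\t10\t100\t0",
               "S1\tchr6\t200\tA\tG\t0\t0\t0\t0"), f)
  ct <- read_counts_table(f)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$tumor_alt[1] / (ct$tumor_alt[1] + ct$tumor_ref[1]), 0.10)
  # zero-depth row is accepted
  expect_equal(ct$tumor_ref[2] + ct$tumor_alt[2], 0L)
  writeLines(c(hdr, "S1\tchr6\t100\tC\tT\t90\t10\t100\t0",
               "S1\tchr6\t100\tC\tT\t1\t1\t1\t1"), f)
  expect_error(read_counts_table(f), "duplicate")
  writeLines(c(hdr, "S1\tchr6\t100\tC\tT\t-1\t10\t100\t0"), f)
  expect_error(read_counts_table(f), "negative")
  writeLines("sample\tchrom\tpos\tref\talt\ttumor_ref\ttumor_alt\tnormal_ref", f)
  expect_error(read_counts_table(f), "missing required column")
})

test_that("SEG rejects intra-sample overlaps; BED converts coordinates and collapses genes", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "x.seg")
  writeLines(c("sample\tchrom\tstart\tend\tseg_mean",
               "S1\tchr6\t1\t10\t-1.4", "S1\tchr6\t5\t20\t0"), f)
  expect_error(read_seg(f), "overlapping")
  writeLines(c("sample\tchrom\tstart\tend\tseg_mean",
               "S1\tchr6\t1\t10\t-1.4", "S1\tchr6\t11\t20\t0",
               "S2\tchr6\t5\t15\t0.3"), f)
  expect_equal(nrow(read_seg(f)), 3L)

  b <- file.path(dir, "g.bed")
  writeLines("chr6\t1000\t2000\tSHPRH", b)
  g <- read_gene_bed(b)
  expect_equal(g$start, 1001L)
  expect_equal(g$end, 2000L)
  # multi-interval gene collapses to spanning interval
  writeLines(c("chr6\t1000\t2000\tSHPRH", "chr6\t5000\t6000\tSHPRH"), b)
  g <- read_gene_bed(b)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(1001L, 6000L))
  writeLines(character(), b)
  expect_equal(nrow(read_gene_bed(b)), 0L)
})

test_that("MAF-like table round-trips through write/read", {
  co <- small_cohort()
  df <- co$run$functional
  f <- file.path(withr::local_tempdir(), "out.maf.tsv")
  write_maf_like(df, f)
  back <- read_maf_like(f)
  expect_equal(nrow(back), nrow(df))
  for (cc in c("sample_id", "gene", "chrom", "pos", "ref", "alt",
               "effect_class", "callers"))
    expect_equal(back[[cc]], df[[cc]])
  expect_equal(back$tumor_vaf, df$tumor_vaf, tolerance = 1e-12)
})
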