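test_that("burden table counts stage survivors per sample", {
  som <- data.frame(sample_id = rep(c("S1", "S2"), c(10L, 0L)),
                    chrom = "chr1", pos = 1:10, ref = "C", alt = "T")
  fun <- data.frame(sample_id = rep("S1", 3L), chrom = "chr1", pos = 1:3,
                    ref = "C", alt = "T")
  traces <- data.frame(sample_id = "S1", chrom = "chr1", pos = 4:10,
                       ref = "C", alt = "T",
                       stage = c(rep("REGION", 4L), rep("SILENT", 3L)),
                       detail = "")
  b <- burden_table(som, fun, traces, territory_mb = 38)
  s1 <- b[b$sample_id == "S1", ]
  expect_equal(s1$mutation_count, 10L)
  expect_equal(s1$coding_variants, 6L)
  expect_equal(s1$functional_variants, 3L)
  expect_equal(s1$tmb, 10 / 38)
  expect_error(burden_table(som, fun, traces, territory_mb = 0), "positive")
})

test_that("mutation spectrum uses the pyrimidine-reference convention", {
  sp <- mutation_spectrum(c("G", "C", "A"), c("T", "T", "C"))
  expect_equal(sp$count[sp$class == "C>A"], 1L)  # G>T complements to C>A
  expect_equal(sp$count[sp$class == "C>T"], 1L)
  expect_equal(sp$count[sp$class == "T>G"], 1L)  # A>C complements to T>G
  expect_equal(sum(sp$fraction), 1.0)
  # complementing every SNV leaves the class counts unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(9)
  ref <- sample(names(comp), 60, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(names(comp), r), 1), "")
  expect_equal(mutation_spectrum(ref, alt)$count,
               mutation_spectrum(comp[ref], comp[alt])$count)
  expect_error(mutation_spectrum("CA", "C"), "single-base")
  expect_error(mutation_spectrum("N", "A"), "non-ACGT")
})

test_that("validation applies the 5% capture-read rule with a per-sample median", {
  cand <- data.frame(sample_id = rep(c("S1", "S2", "S3"), each = 2),
                     chrom = "chr1", pos = 1:6, ref = "C", alt = "T")
  cap <- data.frame(sample_id = cand$sample_id, chrom = "chr1", pos = 1:6,
                    ref = "C", alt = "T",
                    capture_ref = c(94, 50, 96, 50, 99, 50),
                    capture_alt = c(6, 50, 4, 50, 1, 50))
  v <- validation_rate(cand, cap)
  # 6/100 validates (>= 5%), 4/100 and 1/100 do not
  expect_equal(v$per_sample$rate, c(1.0, 0.5, 0.5))
  expect_equal(v$median_rate, 0.5)
  # variants not captured stay out of the denominator
  v2 <- validation_rate(cand, cap[-2, ])
  expect_equal(v2$per_sample$assessed, c(1L, 2L, 2L))
  expect_warning(validation_rate(cand, cap[0, ]), "no assessed variants")
})

test_that("exact one-tailed rank-sum matches enumeration and is symmetric", {
  r <- rank_sum_one_tailed(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 20)
  # swapping groups with the mirrored alternative gives the same p
  r2 <- rank_sum_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r2$p_value, r$p_value)
  # identical groups are symmetric: p >= 0.5
  r3 <- rank_sum_one_tailed(c(1, 2, 7), c(1, 2, 7), "less")
  expect_gte(r3$p_value, 0.5)
  expect_warning(r4 <- rank_sum_one_tailed(c(2, 2), c(2, 2, 2), "less"),
                 "identical")
  expect_equal(r4$p_value, 1)
  # exact path agrees with stats::wilcox.test for untied data
  set.seed(21)
  a <- rnorm(6); b <- rnorm(7) + 0.5
  mine <- rank_sum_one_tailed(a, b, "less")
  ref <- stats::wilcox.test(a, b, alternative = "less", exact = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(mine$U, unname(ref$statistic))
  # large-sample path is a close approximation of the exact p
  set.seed(22)
  a <- rnorm(15); b <- rnorm(15) + 0.8
  approx <- rank_sum_one_tailed(a, b, "less")
  ref2 <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                             correct = TRUE)
  expect_equal(approx$p_value, unname(ref2$p.value), tolerance = 1e-10)
})
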