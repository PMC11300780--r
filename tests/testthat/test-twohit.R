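test_that("zygosity classification follows the VAF threshold and compound rule", {
  zc <- zygosity_config()
  expect_equal(classify_zygosity(0.82, zc), "HOM")
  expect_equal(classify_zygosity(0.40, zc), "HET")
  expect_equal(classify_zygosity(numeric(), zc), "NONE")
  # two distinct variants: HOM under the compound rule, HET without it
  expect_equal(classify_zygosity(c(0.3, 0.35), zc), "HOM")
  expect_equal(classify_zygosity(c(0.3, 0.35),
                                 zygosity_config(compound_hom = FALSE)),
               "HET")
  expect_error(zygosity_config(homozygous_vaf_min = 0.4))
})

test_that("two-hit integration matches the full zygosity x copy truth table", {
  expected <- list(
    NONE = c(AMP = "WT", NEUTRAL = "WT", LOSS = "ONE_HIT",
             DEEP_DEL = "TWO_HIT"),
    HET = c(AMP = "ONE_HIT", NEUTRAL = "ONE_HIT", LOSS = "TWO_HIT",
            DEEP_DEL = "TWO_HIT"),
    HOM = c(AMP = "TWO_HIT", NEUTRAL = "TWO_HIT", LOSS = "TWO_HIT",
            DEEP_DEL = "TWO_HIT"))
  for (z in names(expected)) for (cp in names(expected[[z]])) {
    res <- classify_two_hit(z, cp)
    expect_equal(res$status, expected[[z]][[cp]],
                 label = paste(z, cp, res$status))
    # the status/mechanism invariant
    two_mechs <- c("DEEP_DELETION", "HOMOZYGOUS_MUTATION",
                   "HET_MUTATION_PLUS_LOSS")
    expect_equal(res$status == "TWO_HIT",
                 length(intersect(res$mechanisms, two_mechs)) > 0)
    expect_equal(res$status == "WT", length(res$mechanisms) == 0)
  }
  expect_equal(classify_two_hit("NONE", "DEEP_DEL")$mechanisms,
               "DEEP_DELETION")
  expect_equal(classify_two_hit("HET", "LOSS")$mechanisms,
               "HET_MUTATION_PLUS_LOSS")
  expect_equal(classify_two_hit("HET", "NEUTRAL")$mechanisms,
               "MUTATION_ONLY")
})

test_that("cohort alteration frequencies reproduce printed percentage formats", {
  calls <- data.frame(sample_id = sprintf("T%03d", 1:980), gene = "SHPRH",
                      status = c(rep("TWO_HIT", 200), rep("ONE_HIT", 174),
                                 rep("WT", 606)), stringsAsFactors = FALSE)
  f <- cohort_alteration_frequency(calls, statuses = c("TWO_HIT", "ONE_HIT"))
  expect_equal(f$count, 374L)
  expect_equal(f$total, 980L)
  expect_equal(f$percentage, 100 * 374 / 980)
  expect_equal(f$display, "38%")
  zero <- cohort_alteration_frequency(
    data.frame(sample_id = "a", gene = "G", status = "WT"), statuses = "TWO_HIT")
  expect_equal(zero$percentage, 0)
  expect_error(cohort_alteration_frequency(calls[0, ]), "no alteration calls")
})

test_that("engineered two-hit configurations are recovered exactly by the pipeline", {
  co <- nonoise_cohort()
  truth <- co$gen$truth_alterations
  al <- co$run$alterations
  m <- match(paste(truth$sample_id, truth$gene),
             paste(al$sample_id, al$gene))
  expect_false(anyNA(m))
  expect_equal(al$status[m], truth$status)
  # mechanisms line up with the engineering
  d <- co$gen$spec$designated
  mech <- function(g, s) al$mechanisms[al$gene == g &
                                         al$sample_id == sprintf("S%02d", s)]
  expect_equal(mech(d$deep_del$gene, d$deep_del$samples[1]), "DEEP_DELETION")
  expect_equal(mech(d$hom_mut$gene, d$hom_mut$samples[1]),
               "HOMOZYGOUS_MUTATION")
  expect_equal(mech(d$het_loss$gene, d$het_loss$samples[1]),
               "HET_MUTATION_PLUS_LOSS")
  expect_equal(mech(d$mut_only$gene, d$mut_only$samples[1]), "MUTATION_ONLY")
})
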