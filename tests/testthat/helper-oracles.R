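# Independent oracles used by the property and acceptance tests. These stay
# deliberately separate from the package's own code paths.

# Left-alignment oracle for single-base deletions: enumerate every
# anchor+deleted-base representation across the printed local context that
# produces the same edited sequence, and return the 5'-most one.
oracle_left_align_del <- function(context, context_start, pos, ref, alt) {
  stopifnot(nchar(ref) == nchar(alt) + 1L)
  apply_del <- function(p) {
    # delete the base at absolute position p+1 (anchor at p)
    i <- p - context_start + 1L
    paste0(substr(context, 1L, i), substr(context, i + 2L, nchar(context)))
  }
  target <- apply_del(pos)
  hits <- Filter(function(p) apply_del(p) == target,
                 seq(context_start, context_start + nchar(context) - 2L))
  p <- min(unlist(hits))
  i <- p - context_start + 1L
  list(pos = p, ref = substr(context, i, i + 1L),
       alt = substr(context, i, i))
}

# Exact hypergeometric upper tail by direct pmf enumeration (base choose()).
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exact one-tailed rank-sum p-value by enumerating group assignments and
# counting pairwise wins (ties = 1/2) -- a different route from the rank-sum
# formula used by the implementation.
oracle_rank_sum <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2L, function(i) u_of(pooled[i], pooled[-i]))
  if (alternative == "less") mean(us <= u_obs) else mean(us >= u_obs)
}

# Direct evaluation of the printed tolerability-vote rule for one verdict
# vector (used to sweep all 3^6 vectors).
oracle_vote_retain <- function(verdicts, is_indel, z_rescued,
                               denominator = "available") {
  if (is_indel || z_rescued) return(TRUE)
  A <- if (denominator == "all") 6L else sum(verdicts != ".")
  T_ <- sum(verdicts == "T")
  !(A >= 1L && T_ >= ceiling(A / 2))
}

# Cached synthetic cohorts shared across test files (generation is
# deterministic, so building each once per session is safe).
.cohort_cache <- new.env(parent = emptyenv())

nonoise_cohort <- function() {
  if (is.null(.cohort_cache$nonoise)) {
    dir <- file.path(tempdir(), "somatichit-nonoise")
    spec <- cohort_spec(
      n_pairs = 15L,
      caller_sensitivity = c(bcftools = 1, varscan = 1, freebayes = 1),
      false_positives_per_sample = 0L,
      depth_tumor = 100, depth_normal = 100, seed = 7L)
    gen <- generate_cohort(spec, dir)
    run <- run_pipeline(dir)
    .cohort_cache$nonoise <- list(gen = gen, run = run, dir = dir)
  }
  .cohort_cache$nonoise
}

small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    dir <- file.path(tempdir(), "somatichit-small")
    spec <- cohort_spec(n_pairs = 3L, somatic_mean = 40,
                        germline_per_sample = 12L,
                        false_positives_per_sample = 4L, seed = 11L)
    gen <- generate_cohort(spec, dir)
    run <- run_pipeline(dir)
    .cohort_cache$small <- list(gen = gen, run = run, dir = dir)
  }
  .cohort_cache$small
}

# Minimal consensus-style data frame builder for filter tests.
toy_tumor_set <- function(sample_id, keys) {
  data.frame(sample_id = sample_id, tissue = "TUMOR",
             chrom = keys$chrom, pos = keys$pos, ref = keys$ref,
             alt = keys$alt, callers = "bcftools,varscan", n_callers = 2L,
             stringsAsFactors = FALSE)
}
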