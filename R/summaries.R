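#' Per-sample mutation burden table
#'
#' `mutation_count` is the somatic-cascade survivor count, `coding_variants`
#' the survivors after the coding/splice region filter, and
#' `functional_variants` the final functional-cascade survivors. TMB is
#' `mutation_count / territory_mb`. FGA is computed when segmentation is
#' supplied.
#'
#' @param somatic Somatic-variant data frame (post somatic cascade).
#' @param functional Functional-variant data frame (cascade survivors).
#' @param functional_traces Trace data frame from
#'   [run_functional_cascade()].
#' @param seg Optional cohort SEG data frame for FGA.
#' @param territory_mb Callable territory in megabases (default 38, a
#'   typical exome callable size).
#' @param fga_threshold Passed to [fraction_genome_altered()].
#' @return Data frame: `sample_id`, `mutation_count`, `coding_variants`,
#'   `functional_variants`, `tmb`, `fga` (`NA` without `seg`).
#' @export
burden_table <- function(somatic, functional, functional_traces, seg = NULL,
                         territory_mb = 38, fga_threshold = 0.2) {
  if (territory_mb <= 0) stop("territory_mb must be positive")
  samples <- sort(unique(c(somatic$sample_id, functional$sample_id)))
  n_som <- table(factor(somatic$sample_id, levels = samples))
  region_rm <- functional_traces[functional_traces$stage == "REGION", ,
                                 drop = FALSE]
  n_region_rm <- table(factor(region_rm$sample_id, levels = samples))
  n_fun <- table(factor(functional$sample_id, levels = samples))
  out <- data.frame(sample_id = samples,
                    mutation_count = as.integer(n_som),
                    coding_variants = as.integer(n_som) - as.integer(n_region_rm),
                    functional_variants = as.integer(n_fun),
                    stringsAsFactors = FALSE)
  out$tmb <- out$mutation_count / territory_mb
  out$fga <- NA_real_
  if (!is.null(seg)) {
    for (i in seq_len(nrow(out))) {
      ss <- seg[seg$sample_id == out$sample_id[i], , drop = FALSE]
      if (nrow(ss)) out$fga[i] <- fraction_genome_altered(ss, fga_threshold)
    }
  }
  out
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Six-class single-nucleotide mutation spectrum
#'
#' Each SNV is mapped to its pyrimidine-reference class (purine-reference
#' substitutions are reverse-complemented, e.g. G>T counts as C>A).
#'
#' @param ref,alt Single-base allele vectors (indels must be excluded first).
#' @return Data frame with `class`, `count`, `fraction` (fractions sum to 1
#'   over non-empty input).
#' @export
mutation_spectrum <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("mutation_spectrum expects single-base SNV alleles")
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T")))
    stop("non-ACGT allele in spectrum input")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  cls <- paste0(r, ">", a)
  counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  data.frame(class = SPECTRUM_CLASSES, count = as.integer(counts),
             fraction = if (length(ref)) as.numeric(counts) / length(ref)
                        else rep(NA_real_, 6L),
             stringsAsFactors = FALSE)
}

#' Orthogonal-capture validation rate
#'
#' A candidate variant is validated when at least `min_alt_fraction` of its
#' capture reads support the alternate allele. Only variants present in the
#' capture count table (i.e. in captured genes and samples) enter the
#' denominator; samples with nothing assessed are excluded from the median
#' with a warning.
#'
#' @param candidates Data frame of candidate variants (`sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param capture_counts Data frame with `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `capture_ref`, `capture_alt`.
#' @param min_alt_fraction Validation threshold on the capture VAF.
#' @return List with `per_sample` (data frame: `sample_id`, `assessed`,
#'   `validated`, `rate`) and `median_rate`.
#' @export
validation_rate <- function(candidates, capture_counts,
                            min_alt_fraction = 0.05) {
  kid <- paste(capture_counts$sample_id,
               variant_id(capture_counts$chrom, capture_counts$pos,
                          capture_counts$ref, capture_counts$alt))
  m <- match(paste(candidates$sample_id,
                   variant_id(candidates$chrom, candidates$pos,
                              candidates$ref, candidates$alt)), kid)
  assessed <- !is.na(m)
  dp <- capture_counts$capture_ref[m] + capture_counts$capture_alt[m]
  vaf <- ifelse(dp > 0, capture_counts$capture_alt[m] / dp, 0)
  ok <- assessed & vaf >= min_alt_fraction
  samples <- sort(unique(candidates$sample_id))
  per <- data.frame(
    sample_id = samples,
    assessed = as.integer(table(factor(candidates$sample_id[assessed],
                                       levels = samples))),
    validated = as.integer(table(factor(candidates$sample_id[ok],
                                        levels = samples))),
    stringsAsFactors = FALSE)
  per$rate <- ifelse(per$assessed > 0, per$validated / per$assessed, NA_real_)
  if (any(per$assessed == 0L))
    warning("sample(s) with no assessed variants excluded from the median: ",
            paste(per$sample_id[per$assessed == 0L], collapse = ", "))
  list(per_sample = per,
       median_rate = stats::median(per$rate[per$assessed > 0L]))
}

#' One-tailed Mann-Whitney (rank-sum) test
#'
#' Exact p-value by complete enumeration of group assignments over the
#' pooled mid-ranks when `length(a) + length(b) <= max_exact`; otherwise a
#' normal approximation with tie correction and continuity correction. The
#' U statistic counts pairs where an `a` value exceeds a `b` value, ties
#' counting one half.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"less"` tests whether `a` is stochastically smaller
#'   than `b`; `"greater"` the reverse.
#' @param max_exact Largest pooled size for exact enumeration.
#' @return List with `U` (for group `a`) and `p_value`.
#' @export
rank_sum_one_tailed <- function(a, b, alternative = c("less", "greater"),
                                max_exact = 20L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(pooled)  # mid-ranks under ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(U = U, p_value = 1))
  }
  if (n <= max_exact) {
    idx <- utils::combn(n, na)
    rs <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- if (alternative == "less") mean(rs <= U) else mean(rs >= U)
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- if (alternative == "less") (U - mu + 0.5) / sqrt(sig2)
         else (U - mu - 0.5) / sqrt(sig2)
    p <- if (alternative == "less") stats::pnorm(z)
         else stats::pnorm(z, lower.tail = FALSE)
  }
  list(U = U, p_value = p)
}
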