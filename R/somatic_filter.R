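#' Somatic read-support filter configuration
#'
#' Thresholds for the four somatic filters: matched-normal VAF (removed when
#' `>=` 5\%), zero-alt with deep reference coverage (removed when tumor alt
#' reads are 0 and ref reads exceed 20), tumor-to-normal VAF ratio (removed
#' when tumor VAF is strictly less than twice the normal VAF), and maximum
#' healthy-population frequency (removed when strictly above 1\%).
#'
#' @param max_normal_vaf Normal VAF at or above which a variant is removed.
#' @param min_ref_reads_for_zero_alt Reference-read count that must be
#'   exceeded for the zero-alt rule to fire.
#' @param tumor_to_normal_vaf_ratio Required tumor/normal VAF multiple.
#' @param max_population_freq Population frequency above which a variant is
#'   removed.
#' @return A `somatic_filter_config` list.
#' @export
somatic_filter_config <- function(max_normal_vaf = 0.05,
                                  min_ref_reads_for_zero_alt = 20L,
                                  tumor_to_normal_vaf_ratio = 2.0,
                                  max_population_freq = 0.01) {
  stopifnot(max_normal_vaf > 0, min_ref_reads_for_zero_alt > 0,
            tumor_to_normal_vaf_ratio >= 1, max_population_freq > 0)
  structure(list(max_normal_vaf = max_normal_vaf,
                 min_ref_reads_for_zero_alt = as.integer(min_ref_reads_for_zero_alt),
                 tumor_to_normal_vaf_ratio = tumor_to_normal_vaf_ratio,
                 max_population_freq = max_population_freq),
            class = "somatic_filter_config")
}

.trace <- function(sample_id, chrom, pos, ref, alt, stage, detail = "") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, stage = stage, detail = detail,
             stringsAsFactors = FALSE)
}

.empty_trace <- function() {
  .trace(character(), character(), integer(), character(), character(),
         character(), character())
}

#' Remove tumor variants present in the panel of normals
#'
#' @param tumor_set Tumor consensus data frame.
#' @param panel Character vector of panel keys from [build_normal_panel()].
#' @return List with `retained` (data frame) and `traces` (stage
#'   `NORMAL_PANEL`).
#' @export
filter_normal_panel <- function(tumor_set, panel) {
  id <- variant_id(tumor_set$chrom, tumor_set$pos, tumor_set$ref,
                   tumor_set$alt)
  hit <- id %in% panel
  traces <- if (any(hit))
    .trace(tumor_set$sample_id[hit], tumor_set$chrom[hit],
           tumor_set$pos[hit], tumor_set$ref[hit], tumor_set$alt[hit],
           "NORMAL_PANEL", "present in a matched-normal consensus")
  else .empty_trace()
  list(retained = tumor_set[!hit, , drop = FALSE], traces = traces)
}

#' Apply the three read-support rules to tumor/normal read counts
#'
#' Rules are evaluated in their canonical order and the first firing rule is
#' returned: (1) normal VAF at or above `max_normal_vaf`; (2) zero tumor alt
#' reads with more than `min_ref_reads_for_zero_alt` reference reads;
#' (3) tumor VAF strictly less than `tumor_to_normal_vaf_ratio` times the
#' normal VAF. A zero-depth tissue has VAF 0 by definition.
#'
#' @param tumor_ref,tumor_alt,normal_ref,normal_alt Non-negative read-count
#'   vectors.
#' @param cfg A [somatic_filter_config()].
#' @return Character vector of verdicts: `"PASS"`, `"NORMAL_VAF"`,
#'   `"ZERO_ALT"` or `"VAF_RATIO"`.
#' @export
filter_read_support <- function(tumor_ref, tumor_alt, normal_ref, normal_alt,
                                cfg = somatic_filter_config()) {
  counts <- cbind(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (any(is.na(counts)) || any(counts < 0))
    stop("read counts must be non-negative and non-missing")
  ndp <- normal_ref + normal_alt
  tdp <- tumor_ref + tumor_alt
  nvaf <- ifelse(ndp > 0, normal_alt / ndp, 0)
  tvaf <- ifelse(tdp > 0, tumor_alt / tdp, 0)
  verdict <- rep("PASS", length(tvaf))
  r3 <- tvaf < cfg$tumor_to_normal_vaf_ratio * nvaf
  r2 <- tumor_alt == 0 & tumor_ref > cfg$min_ref_reads_for_zero_alt
  r1 <- nvaf >= cfg$max_normal_vaf
  verdict[r3] <- "VAF_RATIO"
  verdict[r2] <- "ZERO_ALT"
  verdict[r1] <- "NORMAL_VAF"
  verdict
}

#' Remove variants whose maximum healthy-population frequency exceeds 1\%
#'
#' @param pop_freq_max Numeric vector in \[0,1\], `NA` when unannotated.
#' @param cfg A [somatic_filter_config()].
#' @return Logical vector: `TRUE` where the variant is removed. A missing
#'   frequency never fires the rule.
#' @export
filter_population_frequency <- function(pop_freq_max,
                                        cfg = somatic_filter_config()) {
  if (any(pop_freq_max < 0 | pop_freq_max > 1, na.rm = TRUE))
    stop("pop_freq_max outside [0, 1]")
  !is.na(pop_freq_max) & pop_freq_max > cfg$max_population_freq
}

#' Run the full somatic filter cascade over a tumor cohort
#'
#' Stages, in order: panel-of-normals subtraction; removal of variants with
#' no read-count entry; the three read-support rules; cohort-wide blacklist
#' propagation (a key failing any read-support rule in one sample is removed
#' from every sample); population-frequency filter. Every removal is traced.
#'
#' @param tumor_sets Named list (by sample) of tumor consensus data frames.
#' @param panel Panel-of-normals keys.
#' @param counts Read-count table from [read_counts_table()].
#' @param annotations Annotation table (for `pop_freq_max`), keyed by variant.
#' @param cfg A [somatic_filter_config()].
#' @return List with `retained` (one data frame over all samples, with counts
#'   and VAF columns) and `traces`.
#' @export
run_somatic_cascade <- function(tumor_sets, panel, counts, annotations,
                                cfg = somatic_filter_config()) {
  traces <- list()
  stage1 <- list()
  for (s in names(tumor_sets)) {
    fp <- filter_normal_panel(tumor_sets[[s]], panel)
    stage1[[s]] <- fp$retained
    traces[[length(traces) + 1L]] <- fp$traces
  }

  # join read counts; two-pass verdicts for blacklist propagation
  cid <- paste(counts$sample_id,
               variant_id(counts$chrom, counts$pos, counts$ref, counts$alt))
  per_sample <- list()
  for (s in names(stage1)) {
    df <- stage1[[s]]
    if (nrow(df) == 0L) { per_sample[[s]] <- df; next }
    key <- variant_id(df$chrom, df$pos, df$ref, df$alt)
    m <- match(paste(df$sample_id, key), cid)
    missing <- is.na(m)
    if (any(missing)) {
      traces[[length(traces) + 1L]] <-
        .trace(df$sample_id[missing], df$chrom[missing], df$pos[missing],
               df$ref[missing], df$alt[missing], "MISSING_COUNTS",
               "no entry in the read-count table")
    }
    df <- df[!missing, , drop = FALSE]
    m <- m[!missing]
    df$tumor_ref <- counts$tumor_ref[m];  df$tumor_alt <- counts$tumor_alt[m]
    df$normal_ref <- counts$normal_ref[m]; df$normal_alt <- counts$normal_alt[m]
    tdp <- df$tumor_ref + df$tumor_alt; ndp <- df$normal_ref + df$normal_alt
    df$tumor_vaf <- ifelse(tdp > 0, df$tumor_alt / tdp, 0)
    df$normal_vaf <- ifelse(ndp > 0, df$normal_alt / ndp, 0)
    df$verdict <- filter_read_support(df$tumor_ref, df$tumor_alt,
                                      df$normal_ref, df$normal_alt, cfg)
    per_sample[[s]] <- df
  }

  blk <- unlist(lapply(per_sample, function(df) {
    if (nrow(df) == 0L) return(character())
    variant_id(df$chrom, df$pos, df$ref, df$alt)[df$verdict != "PASS"]
  }))
  blacklist <- unique(blk)

  retained <- list()
  for (s in names(per_sample)) {
    df <- per_sample[[s]]
    if (nrow(df) == 0L) { retained[[s]] <- df; next }
    key <- variant_id(df$chrom, df$pos, df$ref, df$alt)
    fail_own <- df$verdict != "PASS"
    fail_blk <- !fail_own & key %in% blacklist
    if (any(fail_own))
      traces[[length(traces) + 1L]] <-
        .trace(df$sample_id[fail_own], df$chrom[fail_own], df$pos[fail_own],
               df$ref[fail_own], df$alt[fail_own], df$verdict[fail_own], "")
    if (any(fail_blk))
      traces[[length(traces) + 1L]] <-
        .trace(df$sample_id[fail_blk], df$chrom[fail_blk], df$pos[fail_blk],
               df$ref[fail_blk], df$alt[fail_blk], "BLACKLIST",
               "failed a read-support rule in another sample")
    retained[[s]] <- df[!fail_own & !fail_blk, , drop = FALSE]
  }

  out <- do.call(rbind, retained)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(sample_id = character(), tissue = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      callers = character(), n_callers = integer(),
                      tumor_ref = integer(), tumor_alt = integer(),
                      normal_ref = integer(), normal_alt = integer(),
                      tumor_vaf = numeric(), normal_vaf = numeric(),
                      verdict = character(), stringsAsFactors = FALSE)
  } else {
    aid <- variant_id(annotations$chrom, annotations$pos, annotations$ref,
                      annotations$alt)
    m <- match(variant_id(out$chrom, out$pos, out$ref, out$alt), aid)
    pf <- ifelse(is.na(m), NA_real_, annotations$pop_freq_max[m])
    drop <- filter_population_frequency(pf, cfg)
    if (any(drop))
      traces[[length(traces) + 1L]] <-
        .trace(out$sample_id[drop], out$chrom[drop], out$pos[drop],
               out$ref[drop], out$alt[drop], "POPFREQ",
               sprintf("pop_freq_max=%g", pf[drop]))
    out <- out[!drop, , drop = FALSE]
  }
  out$verdict <- NULL
  rownames(out) <- NULL
  tr <- do.call(rbind, traces)
  if (is.null(tr)) tr <- .empty_trace()
  rownames(tr) <- NULL
  list(retained = out, traces = tr)
}
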