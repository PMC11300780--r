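#' Copy-number calling thresholds
#'
#' Gene-level log2-ratio thresholds: amplification at `amp` and above,
#' single-copy loss at `loss` and below, deep (biallelic) deletion at
#' `deep_del` and below. The deep-deletion bound is an analysis parameter:
#' -1.3 corresponds to under one remaining copy in a diploid background.
#'
#' @param amp,loss,deep_del Log2-ratio thresholds with
#'   `deep_del < loss < 0 < amp`.
#' @return A `copy_thresholds` list.
#' @export
copy_thresholds <- function(amp = 0.8, loss = -0.6, deep_del = -1.3) {
  stopifnot(deep_del < loss, loss < 0, amp > 0)
  structure(list(amp = amp, loss = loss, deep_del = deep_del),
            class = "copy_thresholds")
}

.call_from_mean <- function(seg_mean, thr) {
  ifelse(seg_mean >= thr$amp, "AMP",
         ifelse(seg_mean <= thr$deep_del, "DEEP_DEL",
                ifelse(seg_mean <= thr$loss, "LOSS", "NEUTRAL")))
}

#' Gene-level copy call from segmented copy number
#'
#' The gene's log2 ratio is the base-length-weighted mean of the overlapping
#' segment means (or the minimum overlapping segment mean under
#' `summary = "min"`), thresholded into AMP / NEUTRAL / LOSS / DEEP_DEL.
#' A gene with no overlapping segment is NEUTRAL with a warning.
#'
#' @param segments Segment data frame (one sample) from [read_seg()].
#' @param gene_interval One-row data frame (`gene`, `chrom`, `start`, `end`).
#' @param thresholds A [copy_thresholds()].
#' @param summary `"weighted_mean"` (default) or `"min"`.
#' @return One-row data frame: `sample_id`, `gene`, `seg_mean`, `call`.
#' @export
gene_copy_call <- function(segments, gene_interval,
                           thresholds = copy_thresholds(),
                           summary = c("weighted_mean", "min")) {
  summary <- match.arg(summary)
  sid <- if (nrow(segments)) segments$sample_id[1L] else NA_character_
  seg <- segments[segments$chrom == gene_interval$chrom &
                  segments$start <= gene_interval$end &
                  segments$end >= gene_interval$start, , drop = FALSE]
  if (nrow(seg) == 0L) {
    warning("gene ", gene_interval$gene, " has no overlapping segment; ",
            "calling NEUTRAL")
    return(data.frame(sample_id = sid, gene = gene_interval$gene,
                      seg_mean = 0, call = "NEUTRAL",
                      stringsAsFactors = FALSE))
  }
  w <- pmin(seg$end, gene_interval$end) - pmax(seg$start, gene_interval$start) + 1L
  gm <- if (summary == "weighted_mean") sum(w * seg$seg_mean) / sum(w)
        else min(seg$seg_mean)
  data.frame(sample_id = sid, gene = gene_interval$gene, seg_mean = gm,
             call = .call_from_mean(gm, thresholds), stringsAsFactors = FALSE)
}

#' Gene-level copy calls for a whole cohort
#'
#' @param seg Cohort SEG data frame.
#' @param genes Gene-interval data frame from [read_gene_bed()].
#' @inheritParams gene_copy_call
#' @return Data frame of per-sample per-gene calls.
#' @export
gene_copy_calls <- function(seg, genes, thresholds = copy_thresholds(),
                            summary = c("weighted_mean", "min")) {
  summary <- match.arg(summary)
  out <- list()
  for (s in unique(seg$sample_id)) {
    ss <- seg[seg$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      out[[length(out) + 1L]] <-
        suppressWarnings(gene_copy_call(ss, genes[i, , drop = FALSE],
                                        thresholds, summary))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of genome altered
#'
#' The fraction of segmented bases whose segment |log2 ratio| meets the
#' threshold (cBioPortal-style, default 0.2).
#'
#' @param segments Segment data frame for one sample.
#' @param fga_threshold Absolute log2-ratio cutoff.
#' @return A fraction in \[0, 1\].
#' @export
fraction_genome_altered <- function(segments, fga_threshold = 0.2) {
  if (nrow(segments) == 0L) stop("no segments: FGA undefined")
  len <- as.numeric(segments$end - segments$start + 1L)
  tot <- sum(len)
  if (tot <= 0) stop("zero total segmented length")
  sum(len[abs(segments$seg_mean) >= fga_threshold]) / tot
}
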