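#' Zygosity-inference configuration
#'
#' Homozygous (biallelic) mutation is inferred when any functional variant in
#' the gene reaches `homozygous_vaf_min` tumor VAF, or — under the compound
#' rule — when two or more distinct functional variants hit the gene in the
#' same sample (phasing is unavailable; treating the pair as biallelic is an
#' explicit assumption).
#'
#' @param homozygous_vaf_min Tumor VAF at or above which a single variant is
#'   called homozygous; must lie in (0.5, 1].
#' @param compound_hom Treat >= 2 distinct functional variants in one gene as
#'   homozygous.
#' @return A `zygosity_config` list.
#' @export
zygosity_config <- function(homozygous_vaf_min = 0.7, compound_hom = TRUE) {
  stopifnot(homozygous_vaf_min > 0.5, homozygous_vaf_min <= 1)
  structure(list(homozygous_vaf_min = homozygous_vaf_min,
                 compound_hom = isTRUE(compound_hom)),
            class = "zygosity_config")
}

#' Classify mutation zygosity of one gene in one sample
#'
#' @param tumor_vafs Tumor VAFs of the gene's functional variants in the
#'   sample (length 0 when unmutated).
#' @param zcfg A [zygosity_config()].
#' @return `"NONE"`, `"HET"` or `"HOM"`.
#' @export
classify_zygosity <- function(tumor_vafs, zcfg = zygosity_config()) {
  n <- length(tumor_vafs)
  if (n == 0L) return("NONE")
  if (any(tumor_vafs >= zcfg$homozygous_vaf_min) ||
      (zcfg$compound_hom && n >= 2L)) return("HOM")
  "HET"
}

#' Integrate zygosity and copy state into a two-hit classification
#'
#' Biallelic ("two-hit") inactivation is deep deletion, homozygous mutation,
#' or heterozygous mutation combined with loss of the second allele
#' (copy call LOSS or DEEP_DEL). A heterozygous mutation on neutral/amplified
#' copy, or a loss with no mutation, is a single hit.
#'
#' @param zygosity `"NONE"`, `"HET"` or `"HOM"`.
#' @param copy_call `"AMP"`, `"NEUTRAL"`, `"LOSS"` or `"DEEP_DEL"`.
#' @return List with `status` (`"WT"`, `"ONE_HIT"`, `"TWO_HIT"`) and
#'   `mechanisms` (character vector).
#' @export
classify_two_hit <- function(zygosity, copy_call) {
  zygosity <- match.arg(zygosity, c("NONE", "HET", "HOM"))
  copy_call <- match.arg(copy_call, c("AMP", "NEUTRAL", "LOSS", "DEEP_DEL"))
  mech <- character()
  if (copy_call == "DEEP_DEL") mech <- c(mech, "DEEP_DELETION")
  if (zygosity == "HOM") mech <- c(mech, "HOMOZYGOUS_MUTATION")
  if (zygosity == "HET" && copy_call %in% c("LOSS", "DEEP_DEL"))
    mech <- c(mech, "HET_MUTATION_PLUS_LOSS")
  if (zygosity == "HET" && copy_call %in% c("NEUTRAL", "AMP"))
    mech <- c(mech, "MUTATION_ONLY")
  if (zygosity == "NONE" && copy_call == "LOSS")
    mech <- c(mech, "LOSS_ONLY")
  two <- any(mech %in% c("DEEP_DELETION", "HOMOZYGOUS_MUTATION",
                         "HET_MUTATION_PLUS_LOSS"))
  status <- if (two) "TWO_HIT"
            else if (length(mech)) "ONE_HIT" else "WT"
  list(status = status, mechanisms = mech)
}

#' Per-sample per-gene alteration calls for a cohort
#'
#' @param functional Functional-variant data frame (`sample_id`, `gene`,
#'   `tumor_vaf`).
#' @param copy_calls Gene copy calls from [gene_copy_calls()].
#' @param zcfg A [zygosity_config()].
#' @return Data frame: `sample_id`, `gene`, `zygosity`, `copy_call`,
#'   `status`, `mechanisms` (comma-joined).
#' @export
alteration_calls <- function(functional, copy_calls,
                             zcfg = zygosity_config()) {
  key <- paste(copy_calls$sample_id, copy_calls$gene, sep = "\r")
  mut <- split(functional$tumor_vaf,
               paste(functional$sample_id, functional$gene, sep = "\r"))
  out <- copy_calls[, c("sample_id", "gene")]
  out$zygosity <- vapply(key, function(k) {
    classify_zygosity(if (k %in% names(mut)) mut[[k]] else numeric(), zcfg)
  }, character(1), USE.NAMES = FALSE)
  out$copy_call <- copy_calls$call
  cls <- Map(classify_two_hit, out$zygosity, out$copy_call)
  out$status <- vapply(cls, `[[`, character(1), "status")
  out$mechanisms <- vapply(cls, function(x)
    paste(x$mechanisms, collapse = ","), character(1))
  rownames(out) <- NULL
  out
}

#' Cohort alteration frequency of a gene
#'
#' @param calls Alteration-call data frame (one row per sample for the gene
#'   of interest, or a cohort table to be subset by `gene`).
#' @param gene Gene symbol (ignored when `calls` already holds one gene).
#' @param statuses Statuses counted as altered.
#' @param digits Decimal places for the display percentage.
#' @return List: `count`, `total`, `percentage` (exact), `display`
#'   (rounded string, e.g. `"38%"`).
#' @export
cohort_alteration_frequency <- function(calls, gene = NULL,
                                        statuses = c("TWO_HIT"),
                                        digits = 0L) {
  if (!is.null(gene)) calls <- calls[calls$gene == gene, , drop = FALSE]
  total <- nrow(calls)
  if (total == 0L) stop("no alteration calls to summarize")
  count <- sum(calls$status %in% statuses)
  pct <- 100 * count / total
  list(count = count, total = total, percentage = pct,
       display = paste0(formatC(round(pct, digits), format = "f",
                                digits = digits), "%"))
}
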