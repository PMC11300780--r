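#' Merge per-caller variant records into a per-sample consensus set
#'
#' Tumor variants must be reported by at least `min_callers_tumor` of the
#' callers (default 2-of-3); matched-normal variants by any single caller
#' (default 1-of-3). Caller support is presence-based: genotype and quality
#' fields play no role.
#'
#' @param records Data frame of per-caller records (columns `chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, `tissue`, `caller`), all from one sample and
#'   tissue, keys already normalized.
#' @param tissue `"TUMOR"` or `"NORMAL"`.
#' @param min_callers_tumor,min_callers_normal Absolute caller-count
#'   thresholds.
#' @return Data frame with one row per retained key: `sample_id`, `tissue`,
#'   `chrom`, `pos`, `ref`, `alt`, `callers` (comma-joined, sorted),
#'   `n_callers`.
#' @export
build_consensus <- function(records, tissue,
                            min_callers_tumor = 2L, min_callers_normal = 1L) {
  tissue <- match.arg(tissue, TISSUES)
  empty <- data.frame(sample_id = character(), tissue = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      callers = character(), n_callers = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  if (length(unique(records$sample_id)) > 1L)
    stop("build_consensus expects records from a single sample")
  if (any(records$tissue != tissue))
    stop("records carry a tissue other than ", tissue)
  if (length(unique(records$caller)) > 3L)
    warning("more than 3 distinct callers; thresholds are absolute counts")

  id <- variant_id(records$chrom, records$pos, records$ref, records$alt)
  sp <- split(records$caller, id)
  callers <- vapply(sp, function(x) paste(sort(unique(x)), collapse = ","),
                    character(1))
  n <- vapply(sp, function(x) length(unique(x)), integer(1))
  first <- records[!duplicated(id), , drop = FALSE]
  first <- first[match(names(sp), variant_id(first$chrom, first$pos,
                                             first$ref, first$alt)), ]
  out <- data.frame(sample_id = first$sample_id, tissue = tissue,
                    chrom = first$chrom, pos = first$pos,
                    ref = first$ref, alt = first$alt,
                    callers = callers, n_callers = n,
                    stringsAsFactors = FALSE)
  thr <- if (tissue == "TUMOR") min_callers_tumor else min_callers_normal
  out <- out[out$n_callers >= thr, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the cohort-wide panel of normals
#'
#' The union of variant keys observed in any matched-normal consensus set;
#' tumor variants present in this panel are treated as germline or systematic
#' artifacts and removed cohort-wide.
#'
#' @param normal_sets List of normal-tissue consensus data frames.
#' @return Character vector of variant-key identifiers (see [variant_id()]).
#' @export
build_normal_panel <- function(normal_sets) {
  if (length(normal_sets) == 0L) return(character())
  ids <- unlist(lapply(normal_sets, function(s) {
    if (nrow(s) == 0L) return(character())
    if (any(s$tissue != "NORMAL"))
      stop("build_normal_panel expects NORMAL-tissue consensus sets")
    variant_id(s$chrom, s$pos, s$ref, s$alt)
  }))
  sort(unique(ids))
}
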