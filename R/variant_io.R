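#' @keywords internal
"_PACKAGE"

CALLERS <- c("bcftools", "varscan", "freebayes")
TISSUES <- c("TUMOR", "NORMAL")

#' Canonical string identifier for a variant key
#'
#' Variant identity throughout the pipeline is the normalized
#' (chrom, pos, ref, alt) tuple; this helper renders it as a single string
#' used for joins, set operations and trace records.
#'
#' @param chrom Chromosome name (verbatim string).
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of `chrom:pos:ref:alt` identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.check_alleles <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt alleles must be non-empty")
  bad <- grepl("[^ACGTN]", toupper(c(ref, alt)))
  if (any(bad))
    stop("non-ACGTN characters in alleles: ",
         paste(unique(c(ref, alt)[bad]), collapse = ", "))
}

#' Normalize a variant key
#'
#' Deterministic re-implementation of the usual VCF normalization: the shared
#' suffix is trimmed first, then the shared prefix with the position advanced
#' accordingly; when a reference-base accessor is supplied, indels are
#' additionally left-aligned to their 5'-most equivalent representation. The
#' operation is idempotent.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings (A/C/G/T, non-empty, `ref != alt`).
#' @param ref_fetch Optional `function(chrom, start, end)` returning the
#'   reference bases for a 1-based inclusive range. When absent only
#'   prefix/suffix trimming is performed.
#' @return A list with elements `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "AT", "AG")  # -> chr1:101 T>G
#' @export
normalize_variant <- function(chrom, pos, ref, alt, ref_fetch = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  .check_alleles(ref, alt)
  if (ref == alt)
    stop("degenerate variant: ref == alt (", ref, ") at ", chrom, ":", pos)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer")

  rr <- strsplit(ref, "", fixed = TRUE)[[1]]
  aa <- strsplit(alt, "", fixed = TRUE)[[1]]

  if (is.null(ref_fetch)) {
    # suffix trim, keeping at least one base on each side
    while (length(rr) > 1L && length(aa) > 1L &&
           rr[length(rr)] == aa[length(aa)]) {
      rr <- rr[-length(rr)]; aa <- aa[-length(aa)]
    }
    # prefix trim, advancing pos
    while (length(rr) > 1L && length(aa) > 1L && rr[1L] == aa[1L]) {
      rr <- rr[-1L]; aa <- aa[-1L]; pos <- pos + 1L
    }
    # one more asymmetric prefix trim for pure SNV-in-longer-context cases
    while (length(rr) > 1L && length(aa) > 1L && rr[1L] == aa[1L]) break
  } else {
    # full left-alignment against the reference (vt/bcftools style)
    repeat {
      if (length(rr) > 0L && length(aa) > 0L &&
          rr[length(rr)] == aa[length(aa)]) {
        rr <- rr[-length(rr)]; aa <- aa[-length(aa)]
      } else if (length(rr) == 0L || length(aa) == 0L) {
        if (pos <= 1L)
          stop("cannot left-align at ", chrom, ":", pos,
               ": no reference base to the left")
        base <- toupper(ref_fetch(chrom, pos - 1L, pos - 1L))
        if (!nzchar(base) || nchar(base) != 1L)
          stop("ref_fetch must return a single base")
        rr <- c(base, rr); aa <- c(base, aa); pos <- pos - 1L
      } else break
    }
    while (length(rr) > 1L && length(aa) > 1L && rr[1L] == aa[1L]) {
      rr <- rr[-1L]; aa <- aa[-1L]; pos <- pos + 1L
    }
  }
  if (length(rr) == 0L || length(aa) == 0L)
    stop("alleles emptied during normalization and no reference supplied")
  out <- list(chrom = chrom, pos = pos,
              ref = paste(rr, collapse = ""), alt = paste(aa, collapse = ""))
  if (out$ref == out$alt)
    stop("degenerate variant after normalization at ", chrom, ":", pos)
  out
}

#' Normalize the keys of a variant table in place
#'
#' @param df Data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param ref_fetch See [normalize_variant()].
#' @return `df` with normalized keys.
#' @export
normalize_keys <- function(df, ref_fetch = NULL) {
  if (nrow(df) == 0L) return(df)
  for (i in seq_len(nrow(df))) {
    k <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i],
                           ref_fetch)
    df$pos[i] <- k$pos; df$ref[i] <- k$ref; df$alt[i] <- k$alt
  }
  df
}

#' Read one caller's VCF into variant records
#'
#' Multi-allelic rows are split into one record per alternate allele and each
#' key is prefix/suffix normalized. Genotype and quality fields are ignored:
#' downstream consensus is presence-based.
#'
#' @param path VCF v4.x file (plain text or bgzip).
#' @param caller Caller identifier, one of `"bcftools"`, `"varscan"`,
#'   `"freebayes"` (other labels are accepted with a warning).
#' @param sample_id Sample the file belongs to.
#' @param tissue `"TUMOR"` or `"NORMAL"`.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `tissue`, `caller`, sorted by key.
#' @export
read_caller_vcf <- function(path, caller, sample_id, tissue) {
  tissue <- match.arg(tissue, TISSUES)
  if (!caller %in% CALLERS)
    warning("unrecognized caller label: ", caller)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) fix <- t(fix)  # single-record file
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), tissue = character(),
                      caller = character(), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]) |
               !nzchar(fix[, "REF"]) | !nzchar(fix[, "ALT"]))
  if (length(bad))
    stop("malformed VCF record in ", path, " at data line ", bad[1L])
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n <- lengths(alts)
  df <- data.frame(chrom = rep(fix[, "CHROM"], n), pos = rep(pos, n),
                   ref = rep(fix[, "REF"], n), alt = unlist(alts),
                   stringsAsFactors = FALSE)
  df <- normalize_keys(df)
  df$sample_id <- sample_id
  df$tissue <- tissue
  df$caller <- caller
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}

#' Read a per-variant read-count table
#'
#' The table is the output of a read-recounting step (one row per sample and
#' variant, with tumor and matched-normal ref/alt read counts). Keys are
#' normalized on load so they join against VCF-derived records.
#'
#' @param path Tab-delimited file with header columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `tumor_ref`, `tumor_alt`, `normal_ref`,
#'   `normal_alt`.
#' @return Data frame keyed by (`sample_id`, variant key) with the four
#'   counts; duplicate keys or negative counts are errors.
#' @export
read_counts_table <- function(path) {
  # read as character first: an all-T allele column must not become logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  .require_cols(df, c("sample", "chrom", "pos", "ref", "alt", "tumor_ref",
                      "tumor_alt", "normal_ref", "normal_alt"), "counts table")
  df$pos <- as.integer(df$pos)
  cnt <- c("tumor_ref", "tumor_alt", "normal_ref", "normal_alt")
  for (cc in cnt) {
    x <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(x) | x < 0 | x != floor(x)))
      stop("counts table contains negative or non-integer read counts")
    df[[cc]] <- as.integer(x)
  }
  df <- normalize_keys(df)
  names(df)[names(df) == "sample"] <- "sample_id"
  id <- paste(df$sample_id, variant_id(df$chrom, df$pos, df$ref, df$alt))
  if (anyDuplicated(id))
    stop("duplicate (sample, variant) rows in counts table: ",
         id[duplicated(id)][1L])
  df
}

#' Read a SEG copy-number segmentation file
#'
#' @param path Tab-delimited file with columns `sample`, `chrom`, `start`,
#'   `end`, optional `n_markers`, `seg_mean` (log2 copy ratio); coordinates
#'   1-based inclusive.
#' @return Data frame of segments; overlapping segments within one
#'   (sample, chromosome) are an input error.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("sample", "chrom", "start", "end", "seg_mean"), "SEG")
  names(df)[names(df) == "sample"] <- "sample_id"
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$seg_mean <- as.numeric(df$seg_mean)
  if (any(df$start > df$end)) stop("SEG has start > end")
  sp <- split(seq_len(nrow(df)), paste(df$sample_id, df$chrom))
  for (idx in sp) {
    o <- idx[order(df$start[idx])]
    if (length(o) > 1L && any(df$start[o][-1L] <= df$end[o][-length(o)])) {
      j <- which(df$start[o][-1L] <= df$end[o][-length(o)])[1L]
      stop("overlapping SEG segments for sample ", df$sample_id[o[1L]],
           " on ", df$chrom[o[1L]], ": rows ", o[j], " and ", o[j + 1L])
    }
  }
  df
}

#' Read a gene-interval BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' inclusive convention used internally (`start + 1`). Multiple intervals for
#' one gene symbol are collapsed to their spanning interval.
#'
#' @param path BED file (chrom, start, end, gene, \[score, strand\]).
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED must have at least 4 columns (name required)")
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  df$strand <- if (ncol(df) >= 6L) df[[6L]] else "."
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("BED interval with start > end")
  sp <- split(df, df$gene)
  out <- do.call(rbind, lapply(sp, function(g) {
    if (length(unique(g$chrom)) > 1L)
      stop("gene ", g$gene[1L], " maps to multiple chromosomes")
    data.frame(gene = g$gene[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Write and read the MAF-like retained-variant table
#'
#' One row per retained functional variant: sample, gene, normalized key,
#' effect class, supporting callers, tumor/normal VAFs and filter provenance.
#'
#' @param df Data frame of retained variants (as produced by
#'   [run_functional_cascade()] joined with counts).
#' @param path Output TSV path.
#' @return `path`, invisibly; `read_maf_like()` returns the data frame.
#' @export
write_maf_like <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_maf_like
#' @export
read_maf_like <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  num <- c("pos", "n_callers", "tumor_ref", "tumor_alt", "normal_ref",
           "normal_alt", "tumor_vaf", "normal_vaf", "spidex_dpsi_z",
           "pop_freq_max")
  for (cc in intersect(num, names(df)))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  for (cc in intersect(c("pos", "n_callers", "tumor_ref", "tumor_alt",
                         "normal_ref", "normal_alt"), names(df)))
    df[[cc]] <- as.integer(df[[cc]])
  df
}
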