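PREDICTORS <- c("SIFT", "LRT", "MutationTaster", "MutationAssessor",
                "FATHMM", "MetaSVM")
REGION_CLASSES <- c("EXONIC", "SPLICING", "EXONIC_SPLICING", "UTR",
                    "INTRONIC", "INTERGENIC", "NCRNA", "OTHER")
EFFECT_CLASSES <- c("MISSENSE", "NONSENSE", "SILENT", "FRAMESHIFT_INDEL",
                    "INFRAME_INDEL", "STOPLOSS", "SPLICE", "UNKNOWN")
CODING_REGIONS <- c("EXONIC", "SPLICING", "EXONIC_SPLICING")
INDEL_EFFECTS <- c("FRAMESHIFT_INDEL", "INFRAME_INDEL")

#' Functional filter configuration
#'
#' @param expressed_genes Character vector of gene symbols expressed in the
#'   tumor type under study; variants in any other gene are removed.
#' @param spidex_z_threshold Absolute splicing-impact (DPSI) z-score at or
#'   above which a variant counts as spliceogenic (rescues silent variants
#'   and overrides the predictor vote).
#' @param min_predictors_for_vote Minimum number of non-missing predictor
#'   verdicts required before the tolerability vote may remove a variant.
#' @param vote_denominator `"available"` counts only predictors that returned
#'   a verdict; `"all"` always divides by six.
#' @param case_insensitive_genes Match gene symbols case-insensitively in the
#'   expression filter.
#' @param exempt_truncating Exempt NONSENSE/SPLICE/STOPLOSS classes from the
#'   vote (off by default: only indels and spliceogenic variants are exempt).
#' @return A `functional_filter_config` list.
#' @export
functional_filter_config <- function(expressed_genes,
                                     spidex_z_threshold = 2.0,
                                     min_predictors_for_vote = 1L,
                                     vote_denominator = c("available", "all"),
                                     case_insensitive_genes = FALSE,
                                     exempt_truncating = FALSE) {
  stopifnot(spidex_z_threshold > 0, min_predictors_for_vote >= 1L)
  structure(list(expressed_genes = unique(as.character(expressed_genes)),
                 spidex_z_threshold = spidex_z_threshold,
                 min_predictors_for_vote = as.integer(min_predictors_for_vote),
                 vote_denominator = match.arg(vote_denominator),
                 case_insensitive_genes = isTRUE(case_insensitive_genes),
                 exempt_truncating = isTRUE(exempt_truncating)),
            class = "functional_filter_config")
}

#' Read the per-variant annotation table
#'
#' Tab-delimited, one row per variant key: `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `region_class`, `effect_class`, one column per predictor
#' (`SIFT`, `LRT`, `MutationTaster`, `MutationAssessor`, `FATHMM`,
#' `MetaSVM`; values `D` deleterious / `T` tolerated / `.` missing),
#' `spidex_dpsi_z` and `pop_freq_max` (`NA` when unannotated).
#'
#' @param path TSV path.
#' @return Annotation data frame with normalized keys.
#' @export
read_annotation_table <- function(path) {
  # character colClasses: predictor columns of pure T verdicts and T/TA
  # alleles must never be parsed as logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = c("NA", ""))
  .require_cols(df, c("chrom", "pos", "ref", "alt", "gene", "region_class",
                      "effect_class", PREDICTORS, "spidex_dpsi_z",
                      "pop_freq_max"), "annotation table")
  df$pos <- as.integer(df$pos)
  bad <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad)) stop("unknown region_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$effect_class), EFFECT_CLASSES)
  if (length(bad)) stop("unknown effect_class: ", paste(bad, collapse = ", "))
  for (p in PREDICTORS) {
    df[[p]][is.na(df[[p]])] <- "."
    if (any(!df[[p]] %in% c("D", "T", ".")))
      stop("predictor column ", p, " must contain D, T or .")
  }
  indel <- df$effect_class %in% INDEL_EFFECTS
  if (any(indel & nchar(df$ref) == nchar(df$alt)))
    stop("indel effect class on length-preserving alleles")
  df$spidex_dpsi_z <- as.numeric(df$spidex_dpsi_z)
  df$pop_freq_max <- as.numeric(df$pop_freq_max)
  normalize_keys(df)
}

#' Region filter: keep protein-coding and splice-site variants
#'
#' @param region_class Character vector of region classes.
#' @return Logical vector, `TRUE` where the variant is retained
#'   (`EXONIC`, `SPLICING` or `EXONIC_SPLICING`).
#' @export
filter_region <- function(region_class) {
  region_class %in% CODING_REGIONS
}

#' Silent filter with splicing-impact rescue
#'
#' Removes variants silent at the amino-acid level unless their splicing
#' z-score magnitude reaches the threshold.
#'
#' @param effect_class,spidex_dpsi_z Vectors over variants.
#' @param cfg A [functional_filter_config()].
#' @return Logical retain vector.
#' @export
filter_silent <- function(effect_class, spidex_dpsi_z, cfg) {
  rescued <- !is.na(spidex_dpsi_z) &
    abs(spidex_dpsi_z) >= cfg$spidex_z_threshold
  !(effect_class == "SILENT" & !rescued)
}

#' Expression filter
#'
#' @param gene Gene symbols.
#' @param cfg A [functional_filter_config()]; an empty expressed-gene set is
#'   an error (it would remove every variant).
#' @return Logical retain vector.
#' @export
filter_expression <- function(gene, cfg) {
  if (length(cfg$expressed_genes) == 0L)
    stop("expressed_genes is empty: refusing to remove every variant")
  if (cfg$case_insensitive_genes)
    toupper(gene) %in% toupper(cfg$expressed_genes)
  else gene %in% cfg$expressed_genes
}

#' Deleteriousness majority vote with indel and splicing overrides
#'
#' Indels and spliceogenic variants are always retained. Otherwise, with
#' `A` predictors returning a verdict and `T` of them voting tolerated, the
#' variant is removed when `A >= min_predictors_for_vote` and
#' `T >= ceiling(A/2)` (ties count toward removal). Under
#' `vote_denominator = "all"`, `A` is fixed at six.
#'
#' @param effect_class Effect class vector.
#' @param verdicts Character matrix (rows = variants, columns = the six
#'   predictors) of `D`/`T`/`.`.
#' @param spidex_dpsi_z Splicing z-score vector (`NA` allowed).
#' @param cfg A [functional_filter_config()].
#' @return Logical retain vector.
#' @export
predictor_vote <- function(effect_class, verdicts, spidex_dpsi_z, cfg) {
  verdicts <- as.matrix(verdicts)
  stopifnot(ncol(verdicts) == length(PREDICTORS))
  exempt_classes <- INDEL_EFFECTS
  if (cfg$exempt_truncating)
    exempt_classes <- c(exempt_classes, "NONSENSE", "SPLICE", "STOPLOSS")
  override <- effect_class %in% exempt_classes |
    (!is.na(spidex_dpsi_z) & abs(spidex_dpsi_z) >= cfg$spidex_z_threshold)
  n_tol <- rowSums(verdicts == "T")
  n_avail <- if (cfg$vote_denominator == "all")
    rep(length(PREDICTORS), nrow(verdicts))
  else rowSums(verdicts != ".")
  removed <- n_avail >= cfg$min_predictors_for_vote &
    n_tol >= ceiling(n_avail / 2)
  override | !removed
}

#' Run the functional-consequence cascade
#'
#' Applies, in order: region filter, silent filter with splicing rescue,
#' expression filter, predictor vote. Each removal is traced with its stage
#' (`REGION`, `SILENT`, `UNEXPRESSED`, `PREDICTOR_VOTE`).
#'
#' @param somatic Data frame of somatic variants (post somatic cascade).
#' @param annotations Annotation data frame from [read_annotation_table()].
#' @param cfg A [functional_filter_config()].
#' @return List with `retained` (somatic rows joined with `gene`,
#'   `region_class`, `effect_class`, `spidex_dpsi_z`) and `traces`.
#' @export
run_functional_cascade <- function(somatic, annotations, cfg) {
  if (nrow(somatic) == 0L)
    return(list(retained = cbind(somatic,
                                 data.frame(gene = character(),
                                            region_class = character(),
                                            effect_class = character(),
                                            spidex_dpsi_z = numeric())),
                traces = .empty_trace()))
  aid <- variant_id(annotations$chrom, annotations$pos, annotations$ref,
                    annotations$alt)
  key <- variant_id(somatic$chrom, somatic$pos, somatic$ref, somatic$alt)
  m <- match(key, aid)
  if (anyNA(m))
    stop("somatic variants missing annotation: ",
         paste(utils::head(unique(key[is.na(m)]), 5L), collapse = ", "))
  df <- somatic
  df$gene <- annotations$gene[m]
  df$region_class <- annotations$region_class[m]
  df$effect_class <- annotations$effect_class[m]
  df$spidex_dpsi_z <- annotations$spidex_dpsi_z[m]
  verdicts <- as.matrix(annotations[m, PREDICTORS, drop = FALSE])

  traces <- list()
  stage <- function(keep, name) {
    drop <- !keep
    if (any(drop))
      traces[[length(traces) + 1L]] <<-
        .trace(df$sample_id[drop], df$chrom[drop], df$pos[drop],
               df$ref[drop], df$alt[drop], name, "")
    verdicts <<- verdicts[keep, , drop = FALSE]
    df <<- df[keep, , drop = FALSE]
  }
  stage(filter_region(df$region_class), "REGION")
  stage(filter_silent(df$effect_class, df$spidex_dpsi_z, cfg), "SILENT")
  stage(filter_expression(df$gene, cfg), "UNEXPRESSED")
  stage(predictor_vote(df$effect_class, verdicts, df$spidex_dpsi_z, cfg),
        "PREDICTOR_VOTE")
  tr <- do.call(rbind, traces)
  if (is.null(tr)) tr <- .empty_trace()
  rownames(df) <- NULL; rownames(tr) <- NULL
  list(retained = df, traces = tr)
}
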