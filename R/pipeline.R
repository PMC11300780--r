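#' Run the full prioritization pipeline on a cohort directory
#'
#' Orchestrates ingest, consensus, somatic filtering, functional filtering,
#' candidate selection, copy-number calling, two-hit integration and cohort
#' summaries. The directory must follow the layout written by
#' [generate_cohort()]: `vcf/<sample>_<TUMOR|NORMAL>_<caller>.vcf`,
#' `counts.tsv`, `annotations.tsv`, `expressed_genes.txt`, `cohort.seg`,
#' `genes.bed`, `external_counts.tsv`, and optionally `census_genes.txt`,
#' `gene_sets.gmt`, `capture_counts.tsv`.
#'
#' @param input_dir Cohort directory.
#' @param somatic_cfg A [somatic_filter_config()].
#' @param copy_thr A [copy_thresholds()].
#' @param zcfg A [zygosity_config()].
#' @param min_callers_tumor,min_callers_normal Consensus thresholds.
#' @param cohort_min,external_min Candidate recurrence thresholds.
#' @param spidex_z_threshold,vote_denominator Functional-filter settings
#'   (the expressed-gene list is read from the directory).
#' @param alpha,min_recurrent_samples Enrichment settings.
#' @param territory_mb TMB callable territory (megabases).
#' @return A `somatichit_run` object: stage outputs, traces, candidate
#'   table, alteration calls, summaries and a machine-readable `report`.
#' @export
run_pipeline <- function(input_dir,
                         somatic_cfg = somatic_filter_config(),
                         copy_thr = copy_thresholds(),
                         zcfg = zygosity_config(),
                         min_callers_tumor = 2L, min_callers_normal = 1L,
                         cohort_min = 2L, external_min = 3L,
                         spidex_z_threshold = 2.0,
                         vote_denominator = "available",
                         alpha = 0.05, min_recurrent_samples = 3L,
                         territory_mb = 38) {
  p <- function(...) file.path(input_dir, ...)
  need <- c("counts.tsv", "annotations.tsv", "expressed_genes.txt",
            "cohort.seg", "genes.bed", "external_counts.tsv")
  miss <- need[!file.exists(p(need))]
  if (length(miss))
    stop("missing pipeline input(s) under ", input_dir, ": ",
         paste(miss, collapse = ", "))

  # ---- ingest -------------------------------------------------------------
  vcfs <- list.files(p("vcf"), pattern = "\\.vcf$", full.names = TRUE)
  if (!length(vcfs)) stop("no VCFs under ", p("vcf"))
  meta <- regmatches(basename(vcfs),
                     regexec("^(.+)_(TUMOR|NORMAL)_([a-z]+)\\.vcf$",
                             basename(vcfs)))
  bad <- which(lengths(meta) != 4L)
  if (length(bad))
    stop("VCF name not <sample>_<TISSUE>_<caller>.vcf: ", vcfs[bad[1L]])
  recs <- Map(function(f, m) read_caller_vcf(f, m[4L], m[2L], m[3L]),
              vcfs, meta)
  all_rec <- do.call(rbind, recs)
  counts <- read_counts_table(p("counts.tsv"))
  annotations <- read_annotation_table(p("annotations.tsv"))
  genes <- read_gene_bed(p("genes.bed"))
  seg <- read_seg(p("cohort.seg"))
  expressed <- readLines(p("expressed_genes.txt"))
  external <- utils::read.delim(p("external_counts.tsv"),
                                colClasses = c("character", "integer"))
  census <- if (file.exists(p("census_genes.txt")))
    readLines(p("census_genes.txt")) else character()
  fcfg <- functional_filter_config(expressed,
                                   spidex_z_threshold = spidex_z_threshold,
                                   vote_denominator = vote_denominator)

  # ---- consensus ----------------------------------------------------------
  tumor_sets <- list(); normal_sets <- list()
  for (s in sort(unique(all_rec$sample_id))) {
    tr <- all_rec[all_rec$sample_id == s & all_rec$tissue == "TUMOR", ]
    nr <- all_rec[all_rec$sample_id == s & all_rec$tissue == "NORMAL", ]
    tumor_sets[[s]] <- build_consensus(tr, "TUMOR", min_callers_tumor,
                                       min_callers_normal)
    normal_sets[[s]] <- build_consensus(nr, "NORMAL", min_callers_tumor,
                                        min_callers_normal)
  }
  panel <- build_normal_panel(normal_sets)

  # ---- somatic + functional cascades --------------------------------------
  som <- run_somatic_cascade(tumor_sets, panel, counts, annotations,
                             somatic_cfg)
  fun <- run_functional_cascade(som$retained, annotations, fcfg)

  # ---- candidates, copy number, two-hit -----------------------------------
  recurrence <- select_candidates(fun$retained, external, cohort_min,
                                  external_min, census)
  candidates <- recurrence[recurrence$is_candidate, , drop = FALSE]
  novel <- candidates$gene[!candidates$is_known_driver]
  copy_calls <- gene_copy_calls(seg, genes, copy_thr)
  alterations <- alteration_calls(fun$retained, copy_calls, zcfg)

  enrichment <- NULL
  if (file.exists(p("gene_sets.gmt")) && length(novel)) {
    gmt <- read_gmt(p("gene_sets.gmt"))
    sg <- lapply(split(fun$retained$gene, fun$retained$sample_id),
                 function(g) intersect(unique(g), novel))
    sg <- sg[lengths(sg) > 0L]
    if (length(sg))
      enrichment <- enrich_per_sample(sg, gmt, expressed, alpha,
                                      min_recurrent_samples)
  }

  # ---- summaries ----------------------------------------------------------
  burden <- burden_table(som$retained, fun$retained, fun$traces, seg,
                         territory_mb)
  snv <- som$retained[nchar(som$retained$ref) == 1L &
                        nchar(som$retained$alt) == 1L, , drop = FALSE]
  spectrum <- mutation_spectrum(snv$ref, snv$alt)
  validation <- NULL
  if (file.exists(p("capture_counts.tsv"))) {
    cap <- utils::read.delim(p("capture_counts.tsv"),
                             colClasses = "character")
    for (cc in c("pos", "capture_ref", "capture_alt"))
      cap[[cc]] <- as.integer(cap[[cc]])
    validation <- suppressWarnings(validation_rate(fun$retained, cap))
  }

  traces <- rbind(som$traces, fun$traces)
  n_consensus <- sum(vapply(tumor_sets, nrow, integer(1)))
  stage_counts <- c(tumor_consensus = n_consensus,
                    table(factor(traces$stage,
                                 levels = c("NORMAL_PANEL", "MISSING_COUNTS",
                                            "NORMAL_VAF", "ZERO_ALT",
                                            "VAF_RATIO", "BLACKLIST",
                                            "POPFREQ", "REGION", "SILENT",
                                            "UNEXPRESSED",
                                            "PREDICTOR_VOTE"))),
                    somatic_retained = nrow(som$retained),
                    functional_retained = nrow(fun$retained))
  report <- list(
    samples = names(tumor_sets),
    stage_counts = as.list(stage_counts),
    n_candidate_genes = nrow(candidates),
    candidate_genes = candidates$gene,
    novel_candidate_genes = novel,
    recurrent_terms = if (is.null(enrichment)) character()
                      else enrichment$recurrent_terms,
    median_validation_rate = if (is.null(validation)) NA_real_
                             else validation$median_rate,
    config = list(somatic = unclass(somatic_cfg),
                  copy_thresholds = unclass(copy_thr),
                  zygosity = unclass(zcfg),
                  consensus = list(min_callers_tumor = min_callers_tumor,
                                   min_callers_normal = min_callers_normal),
                  recurrence = list(cohort_min = cohort_min,
                                    external_min = external_min),
                  functional = list(spidex_z_threshold = spidex_z_threshold,
                                    vote_denominator = vote_denominator),
                  territory_mb = territory_mb))

  structure(list(tumor_consensus = tumor_sets, normal_panel = panel,
                 somatic = som$retained, functional = fun$retained,
                 traces = traces, recurrence = recurrence,
                 candidates = candidates, copy_calls = copy_calls,
                 alterations = alterations, enrichment = enrichment,
                 burden = burden, spectrum = spectrum,
                 validation = validation, report = report),
            class = "somatichit_run")
}

#' @export
print.somatichit_run <- function(x, ...) {
  sc <- x$report$stage_counts
  cat("somatic variant prioritization run\n")
  cat("  samples:             ", length(x$report$samples), "\n")
  cat("  tumor consensus:     ", sc$tumor_consensus, "\n")
  cat("  somatic retained:    ", sc$somatic_retained, "\n")
  cat("  functional retained: ", sc$functional_retained, "\n")
  cat("  candidate genes:     ", x$report$n_candidate_genes,
      paste0("(", paste(utils::head(x$report$candidate_genes, 8L),
                        collapse = ", "),
             if (x$report$n_candidate_genes > 8L) ", ..." else "", ")"),
      "\n")
  invisible(x)
}

#' @export
summary.somatichit_run <- function(object, ...) {
  print(object)
  cat("\nremovals by stage:\n")
  sc <- object$report$stage_counts
  for (s in setdiff(names(sc), c("tumor_consensus", "somatic_retained",
                                 "functional_retained")))
    cat(sprintf("  %-15s %d\n", s, sc[[s]]))
  cat("\nper-sample burden:\n")
  print(object$burden, row.names = FALSE)
  invisible(object)
}

#' Write the machine-readable run report
#'
#' @param run A `somatichit_run`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
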