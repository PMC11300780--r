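#' Specification of a synthetic tumor/normal cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: a panel of
#' tumor/matched-normal pairs with planted somatic and germline variants,
#' binomial read counts at configurable depth, per-caller detection error,
#' annotation fields consistent with the planted effect classes, and
#' engineered copy-number events including a 6q-like deleted region hosting
#' designated one-hit and two-hit tumor-suppressor configurations.
#'
#' The synthetic genome has `n_chroms` chromosomes of `chrom_length` bases
#' carrying `n_genes` equally spaced genes (`GENE01`, `GENE02`, ...). Five
#' genes on the last chromosome are reserved for engineering and excluded
#' from random mutation placement: a deep-deletion target, a homozygous-
#' mutation target (planted VAF 0.9), a het-mutation target inside the
#' 6q-like loss region, a mutation-only target and a loss-only target.
#'
#' @param n_pairs Number of tumor/normal pairs.
#' @param somatic_mean,somatic_dispersion Negative-binomial mean and size of
#'   the per-tumor somatic variant count.
#' @param germline_per_sample Germline heterozygous sites per individual,
#'   drawn from a shared polymorphism pool (so sites recur across samples).
#' @param depth_tumor,depth_normal Mean sequencing depths (Poisson).
#' @param somatic_vaf_shape Beta shape parameters of the somatic VAF
#'   distribution (subclonal skew).
#' @param somatic_vaf_min Lower truncation of somatic VAFs (caller detection
#'   floor).
#' @param caller_sensitivity Named per-caller detection probabilities.
#' @param false_positives_per_sample Caller-private false calls per caller
#'   per sample (per tissue).
#' @param effect_mix Named probabilities over coding effect classes.
#' @param coding_fraction Fraction of somatic variants falling in coding or
#'   splice regions.
#' @param silent_spliceogenic_rate Fraction of silent variants given
#'   |splicing z| >= 2.
#' @param missense_deleterious_rate P(planted deleterious | missense).
#' @param predictor_concordance Probability each predictor's verdict matches
#'   the planted deleteriousness.
#' @param popfreq_contaminant_rate Fraction of tumor-only variants that are
#'   common polymorphisms (`pop_freq_max` > 1\%).
#' @param expressed_fraction Fraction of genes expressed (designated genes
#'   always expressed).
#' @param capture_nonconfirm_rate Fraction of true variants that fail
#'   orthogonal capture confirmation.
#' @param cn_profile List of engineered copy events, each a list with
#'   `chrom`, `start`, `end`, `seg_mean`, `samples` (indices); `NULL` uses
#'   the default engineering described above.
#' @param seed Integer seed; identical seeds give byte-identical output
#'   trees.
#' @return A `cohort_spec` list (includes the designated-gene map in
#'   `$designated`).
#' @export
cohort_spec <- function(n_pairs = 15L,
                        somatic_mean = 150, somatic_dispersion = 8,
                        germline_per_sample = 40L,
                        depth_tumor = 100, depth_normal = 80,
                        somatic_vaf_shape = c(2, 5),
                        somatic_vaf_min = 0.10,
                        caller_sensitivity = c(bcftools = 0.95,
                                               varscan = 0.90,
                                               freebayes = 0.85),
                        false_positives_per_sample = 20L,
                        effect_mix = c(MISSENSE = 0.50, SILENT = 0.25,
                                       NONSENSE = 0.08,
                                       FRAMESHIFT_INDEL = 0.07,
                                       INFRAME_INDEL = 0.02, SPLICE = 0.08),
                        coding_fraction = 0.8,
                        silent_spliceogenic_rate = 0.10,
                        missense_deleterious_rate = 0.5,
                        predictor_concordance = 0.9,
                        popfreq_contaminant_rate = 0.02,
                        expressed_fraction = 0.8,
                        capture_nonconfirm_rate = 0.10,
                        cn_profile = NULL,
                        seed = 20260101L) {
  stopifnot(n_pairs >= 1L, all(caller_sensitivity >= 0),
            all(caller_sensitivity <= 1), somatic_vaf_min >= 0,
            abs(sum(effect_mix) - 1) < 1e-8)
  n_chroms <- 6L; genes_per_chrom <- 10L
  n_genes <- n_chroms * genes_per_chrom
  chrom_length <- 2000000L; gene_length <- 10000L
  genes <- data.frame(
    gene = sprintf("GENE%02d", seq_len(n_genes)),
    chrom = paste0("chr", rep(seq_len(n_chroms), each = genes_per_chrom)),
    start = rep(seq_len(genes_per_chrom) * 150000L + 1L, n_chroms),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + gene_length - 1L
  genes$strand <- "+"

  in_range <- function(i) intersect(i, seq_len(n_pairs))
  designated <- list(
    deep_del = list(gene = "GENE58", samples = in_range(2:4)),
    hom_mut = list(gene = "GENE52", samples = in_range(5:6), vaf = 0.9),
    het_loss = list(gene = "GENE59", samples = in_range(c(1L, 7L)), vaf = 0.4),
    mut_only = list(gene = "GENE53", samples = in_range(9L), vaf = 0.4),
    loss_only = list(gene = "GENE60", samples = integer()))
  loss_samples <- in_range(1:8)
  if (is.null(cn_profile)) {
    cn_profile <- list(
      list(chrom = "chr6", start = 1000001L, end = 2000000L,
           seg_mean = -0.8, samples = loss_samples),
      list(chrom = "chr6", start = 1190001L, end = 1220000L,
           seg_mean = -1.8, samples = designated$deep_del$samples),
      list(chrom = "chr1", start = 1L, end = 300000L,
           seg_mean = 0.9, samples = in_range(10:12)))
  }
  structure(list(
    n_pairs = as.integer(n_pairs), somatic_mean = somatic_mean,
    somatic_dispersion = somatic_dispersion,
    germline_per_sample = as.integer(germline_per_sample),
    depth_tumor = depth_tumor, depth_normal = depth_normal,
    somatic_vaf_shape = somatic_vaf_shape,
    somatic_vaf_min = somatic_vaf_min,
    caller_sensitivity = caller_sensitivity,
    false_positives_per_sample = as.integer(false_positives_per_sample),
    effect_mix = effect_mix, coding_fraction = coding_fraction,
    silent_spliceogenic_rate = silent_spliceogenic_rate,
    missense_deleterious_rate = missense_deleterious_rate,
    predictor_concordance = predictor_concordance,
    popfreq_contaminant_rate = popfreq_contaminant_rate,
    expressed_fraction = expressed_fraction,
    capture_nonconfirm_rate = capture_nonconfirm_rate,
    cn_profile = cn_profile, genes = genes,
    designated = designated, loss_samples = loss_samples,
    n_chroms = n_chroms, chrom_length = chrom_length,
    seed = as.integer(seed)), class = "cohort_spec")
}

.sample_ids <- function(n) sprintf("S%02d", seq_len(n))

.sub_seed <- function(seed, i, salt) {
  as.integer((as.numeric(seed) * 48271 + i * 7919 + salt * 104729) %%
               2147483629)
}

.rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.rand_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1), USE.NAMES = FALSE)
}

# draw alleles for an effect class at given positions
.draw_alleles <- function(effect) {
  n <- length(effect)
  ref <- .rand_base(n); alt <- .rand_alt(ref)
  fs <- effect == "FRAMESHIFT_INDEL"
  if (any(fs)) {  # 1-bp deletions: ref = anchor + deleted base
    ref[fs] <- paste0(ref[fs], .rand_base(sum(fs)))
    alt[fs] <- substr(ref[fs], 1L, 1L)
  }
  inf <- effect == "INFRAME_INDEL"
  if (any(inf)) {  # 3-bp deletions
    ref[inf] <- paste0(ref[inf], .rand_base(sum(inf)), .rand_base(sum(inf)),
                       .rand_base(sum(inf)))
    alt[inf] <- substr(ref[inf], 1L, 1L)
  }
  list(ref = ref, alt = alt)
}

.truncbeta <- function(n, shape, lo) {
  plo <- stats::pbeta(lo, shape[1], shape[2])
  stats::qbeta(plo + stats::runif(n) * (1 - plo), shape[1], shape[2])
}

# carve an event into a non-overlapping segment partition
.apply_event <- function(segs, chrom, start, end, value) {
  keep <- list(); n <- 0L
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$chrom != chrom || s$end < start || s$start > end) {
      keep[[n <- n + 1L]] <- s; next
    }
    if (s$start < start)
      keep[[n <- n + 1L]] <- data.frame(chrom = s$chrom, start = s$start,
                                        end = start - 1L,
                                        seg_mean = s$seg_mean)
    if (s$end > end)
      keep[[n <- n + 1L]] <- data.frame(chrom = s$chrom, start = end + 1L,
                                        end = s$end, seg_mean = s$seg_mean)
  }
  keep[[n + 1L]] <- data.frame(chrom = chrom, start = start, end = end,
                               seg_mean = value)
  out <- do.call(rbind, keep)
  out[order(out$chrom, out$start), , drop = FALSE]
}

.write_vcf <- function(df, path, n_chroms, chrom_length) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=somatichit synthetic cohort generator",
               sprintf("##contig=<ID=chr%d,length=%d>", seq_len(n_chroms),
                       chrom_length),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".",
                     sep = "\t"), con)
  }
  close(con)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a truth-labelled synthetic cohort on disk
#'
#' Writes, under `outdir`: per-sample per-caller tumor and normal VCFs
#' (`vcf/`), the read-count table (`counts.tsv`), the annotation table
#' (`annotations.tsv`), the expressed-gene list (`expressed_genes.txt`), the
#' copy-number segmentation (`cohort.seg`), the gene BED (`genes.bed`), the
#' external-cohort mutation counts (`external_counts.tsv`), the census gene
#' list (`census_genes.txt`), a gene-set GMT (`gene_sets.gmt`), orthogonal
#' capture counts (`capture_counts.tsv`) and the truth labels
#' (`truth_variants.tsv`, `truth_alterations.tsv`).
#'
#' @param spec A [cohort_spec()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with `dir`, `paths`, `truth_variants`,
#'   `truth_alterations` and `spec`.
#' @export
generate_cohort <- function(spec, outdir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vcfdir <- file.path(outdir, "vcf")
  dir.create(vcfdir, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  samples <- .sample_ids(spec$n_pairs)
  genes <- spec$genes
  desig_genes <- vapply(spec$designated, `[[`, character(1), "gene")
  random_genes <- genes[!genes$gene %in% desig_genes, , drop = FALSE]

  # ---- cohort-level draws -------------------------------------------------
  set.seed(.sub_seed(spec$seed, 0L, 1L))
  n_pool <- max(3L * spec$germline_per_sample, 10L)
  pool_chrom <- paste0("chr", sample(spec$n_chroms, n_pool, replace = TRUE))
  pool_pos <- sample(spec$chrom_length, n_pool, replace = TRUE)
  pool_ref <- .rand_base(n_pool); pool_alt <- .rand_alt(pool_ref)
  pool <- data.frame(chrom = pool_chrom, pos = pool_pos, ref = pool_ref,
                     alt = pool_alt, stringsAsFactors = FALSE)
  pool <- pool[!duplicated(variant_id(pool$chrom, pool$pos, pool$ref,
                                      pool$alt)), , drop = FALSE]
  pool$pop_freq_max <- round(stats::runif(nrow(pool), 0.01, 0.5), 4)

  expressed <- sort(unique(c(desig_genes,
    sample(genes$gene, round(spec$expressed_fraction * nrow(genes))))))

  # ---- per-sample variant planting ---------------------------------------
  truth <- list(); counts <- list()
  per_caller <- list()  # records per sample/tissue/caller
  callers <- names(spec$caller_sensitivity)
  for (i in seq_len(spec$n_pairs)) {
    set.seed(.sub_seed(spec$seed, i, 2L))
    sid <- samples[i]

    n_som <- stats::rnbinom(1L, mu = spec$somatic_mean,
                            size = spec$somatic_dispersion)
    coding <- stats::runif(n_som) < spec$coding_fraction
    n_cod <- sum(coding)
    eff <- rep("UNKNOWN", n_som)
    eff[coding] <- sample(names(spec$effect_mix), n_cod, replace = TRUE,
                          prob = spec$effect_mix)
    gidx <- sample(nrow(random_genes), n_som, replace = TRUE)
    chrom <- random_genes$chrom[gidx]
    pos <- integer(n_som); gene <- character(n_som)
    region <- character(n_som)
    pos[coding] <- random_genes$start[gidx[coding]] +
      sample.int(9000L, n_cod, replace = TRUE)
    gene[coding] <- random_genes$gene[gidx[coding]]
    region[coding] <- ifelse(eff[coding] == "SPLICE", "SPLICING", "EXONIC")
    # non-coding variants land between genes
    ncod <- !coding
    pos[ncod] <- random_genes$end[gidx[ncod]] + 20000L +
      sample.int(100000L, sum(ncod), replace = TRUE)
    gene[ncod] <- "."
    region[ncod] <- sample(c("INTRONIC", "UTR", "INTERGENIC"), sum(ncod),
                           replace = TRUE)
    al <- .draw_alleles(eff)
    vaf <- .truncbeta(n_som, spec$somatic_vaf_shape, spec$somatic_vaf_min)
    som <- data.frame(sample_id = sid, chrom = chrom, pos = pos,
                      ref = al$ref, alt = al$alt, origin = "SOMATIC",
                      vaf = vaf, gene = gene, region_class = region,
                      effect_class = eff, engineered = FALSE,
                      stringsAsFactors = FALSE)

    # engineered mutations in designated genes (frameshift deletions)
    for (nm in c("hom_mut", "het_loss", "mut_only")) {
      d <- spec$designated[[nm]]
      if (!(i %in% d$samples)) next
      g <- genes[genes$gene == d$gene, ]
      a <- .draw_alleles("FRAMESHIFT_INDEL")
      som <- rbind(som, data.frame(
        sample_id = sid, chrom = g$chrom, pos = g$start + 500L + i,
        ref = a$ref, alt = a$alt, origin = "SOMATIC", vaf = d$vaf,
        gene = d$gene, region_class = "EXONIC",
        effect_class = "FRAMESHIFT_INDEL", engineered = TRUE,
        stringsAsFactors = FALSE))
    }
    som <- som[!duplicated(variant_id(som$chrom, som$pos, som$ref, som$alt)),
               , drop = FALSE]

    gl_idx <- sample(nrow(pool), min(spec$germline_per_sample, nrow(pool)))
    gl <- data.frame(sample_id = sid, chrom = pool$chrom[gl_idx],
                     pos = pool$pos[gl_idx], ref = pool$ref[gl_idx],
                     alt = pool$alt[gl_idx], origin = "GERMLINE", vaf = 0.5,
                     gene = ".", region_class = "INTERGENIC",
                     effect_class = "UNKNOWN", engineered = FALSE,
                     stringsAsFactors = FALSE)
    tv <- rbind(som, gl)
    tv <- tv[!duplicated(variant_id(tv$chrom, tv$pos, tv$ref, tv$alt)), ,
             drop = FALSE]
    tv$zygosity <- ifelse(tv$origin == "GERMLINE", "HET",
                          ifelse(tv$vaf >= 0.7, "HOM", "HET"))
    truth[[i]] <- tv

    # read counts: tumor carries somatic + germline, normal only germline
    dt <- stats::rpois(nrow(tv), spec$depth_tumor)
    dn <- stats::rpois(nrow(tv), spec$depth_normal)
    t_alt <- stats::rbinom(nrow(tv), dt, tv$vaf)
    n_alt <- stats::rbinom(nrow(tv), dn,
                           ifelse(tv$origin == "GERMLINE", 0.5, 0))
    counts[[i]] <- data.frame(sample = sid, chrom = tv$chrom, pos = tv$pos,
                              ref = tv$ref, alt = tv$alt,
                              tumor_ref = dt - t_alt, tumor_alt = t_alt,
                              normal_ref = dn - n_alt, normal_alt = n_alt,
                              stringsAsFactors = FALSE)

    # caller detection + private false positives, per tissue
    for (ci in seq_along(callers)) {
      cal <- callers[ci]; sens <- spec$caller_sensitivity[ci]
      for (tis in TISSUES) {
        present <- if (tis == "TUMOR") tv else tv[tv$origin == "GERMLINE", ]
        det <- present[stats::runif(nrow(present)) < sens, , drop = FALSE]
        nfp <- spec$false_positives_per_sample
        fp <- if (nfp > 0L) {
          fr <- .rand_base(nfp)
          data.frame(chrom = paste0("chr", sample(spec$n_chroms, nfp,
                                                  replace = TRUE)),
                     pos = sample(spec$chrom_length, nfp, replace = TRUE),
                     ref = fr, alt = .rand_alt(fr), stringsAsFactors = FALSE)
        } else data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
        rec <- rbind(det[, c("chrom", "pos", "ref", "alt")], fp)
        rec <- rec[!duplicated(variant_id(rec$chrom, rec$pos, rec$ref,
                                          rec$alt)), , drop = FALSE]
        per_caller[[paste(sid, tis, cal, sep = "_")]] <-
          list(sample_id = sid, tissue = tis, caller = cal, records = rec,
               fp = fp)
      }
    }
  }
  truth_variants <- do.call(rbind, truth)
  counts_df <- do.call(rbind, counts)

  # ---- annotation table (one row per distinct key) ------------------------
  set.seed(.sub_seed(spec$seed, 0L, 3L))
  fp_keys <- do.call(rbind, lapply(per_caller, `[[`, "fp"))
  ann_src <- rbind(
    truth_variants[, c("chrom", "pos", "ref", "alt", "gene", "region_class",
                       "effect_class", "origin", "engineered")],
    if (!is.null(fp_keys) && nrow(fp_keys))
      data.frame(fp_keys, gene = ".", region_class = "INTERGENIC",
                 effect_class = "UNKNOWN", origin = "CALLER_FP",
                 engineered = FALSE, stringsAsFactors = FALSE))
  ann <- ann_src[!duplicated(variant_id(ann_src$chrom, ann_src$pos,
                                        ann_src$ref, ann_src$alt)), ,
                 drop = FALSE]
  n <- nrow(ann)
  deleterious <- rep(NA, n)
  deleterious[ann$effect_class == "MISSENSE"] <-
    stats::runif(sum(ann$effect_class == "MISSENSE")) <
      spec$missense_deleterious_rate
  deleterious[ann$effect_class %in% c("NONSENSE", "SPLICE",
                                      INDEL_EFFECTS)] <- TRUE
  deleterious[ann$effect_class == "SILENT"] <- FALSE
  # predictor verdicts: SNV coding classes only; indels/silent unscored
  verd <- matrix(".", n, length(PREDICTORS),
                 dimnames = list(NULL, PREDICTORS))
  scored <- ann$effect_class %in% c("MISSENSE", "NONSENSE", "SPLICE")
  for (p in PREDICTORS) {
    agree <- stats::runif(n) < spec$predictor_concordance
    v <- ifelse(deleterious, ifelse(agree, "D", "T"),
                ifelse(agree, "T", "D"))
    verd[scored, p] <- v[scored]
  }
  z <- rep(NA_real_, n)
  sil <- ann$effect_class == "SILENT"
  splice_hit <- sil & stats::runif(n) < spec$silent_spliceogenic_rate
  z[sil] <- round(stats::rnorm(sum(sil), 0, 0.5), 3)
  z[splice_hit] <- round(sample(c(-1, 1), sum(splice_hit), replace = TRUE) *
                           stats::runif(sum(splice_hit), 2, 3.5), 3)
  spl <- ann$effect_class == "SPLICE"
  z[spl] <- round(sample(c(-1, 1), sum(spl), replace = TRUE) *
                    stats::runif(sum(spl), 2, 4), 3)
  pf <- rep(NA_real_, n)
  germ <- ann$origin == "GERMLINE"
  pid <- match(variant_id(ann$chrom, ann$pos, ann$ref, ann$alt),
               variant_id(pool$chrom, pool$pos, pool$ref, pool$alt))
  pf[germ] <- pool$pop_freq_max[pid[germ]]
  contam <- ann$origin == "SOMATIC" & !ann$engineered &
    stats::runif(n) < spec$popfreq_contaminant_rate
  pf[contam] <- round(stats::runif(sum(contam), 0.011, 0.2), 4)
  annotations <- data.frame(ann[, c("chrom", "pos", "ref", "alt", "gene",
                                    "region_class", "effect_class")],
                            verd, spidex_dpsi_z = z, pop_freq_max = pf,
                            stringsAsFactors = FALSE)
  tid <- variant_id(truth_variants$chrom, truth_variants$pos,
                    truth_variants$ref, truth_variants$alt)
  aid <- variant_id(annotations$chrom, annotations$pos, annotations$ref,
                    annotations$alt)
  truth_variants$pop_freq_max <- annotations$pop_freq_max[match(tid, aid)]

  # ---- copy-number segmentation ------------------------------------------
  set.seed(.sub_seed(spec$seed, 0L, 4L))
  seg <- list()
  for (i in seq_len(spec$n_pairs)) {
    base <- do.call(rbind, lapply(seq_len(spec$n_chroms), function(ch) {
      br <- sort(sample(spec$chrom_length - 1L, 3L))
      data.frame(chrom = paste0("chr", ch),
                 start = c(1L, br + 1L), end = c(br, spec$chrom_length),
                 seg_mean = round(stats::rnorm(4L, 0, 0.05), 4))
    }))
    for (ev in spec$cn_profile) {
      if (i %in% ev$samples)
        base <- .apply_event(base, ev$chrom, ev$start, ev$end, ev$seg_mean)
    }
    seg[[i]] <- data.frame(sample = samples[i], base,
                           stringsAsFactors = FALSE)
  }
  seg_df <- do.call(rbind, seg)

  # ---- engineered alteration truth ---------------------------------------
  d <- spec$designated
  alt_truth <- list()
  for (i in seq_len(spec$n_pairs)) {
    status <- c(GENE52 = "WT", GENE53 = "WT", GENE58 = "WT",
                GENE59 = "WT", GENE60 = "WT")
    names(status) <- c(d$hom_mut$gene, d$mut_only$gene, d$deep_del$gene,
                       d$het_loss$gene, d$loss_only$gene)
    in_loss <- i %in% spec$loss_samples
    if (in_loss) {
      status[d$loss_only$gene] <- "ONE_HIT"
      status[d$het_loss$gene] <- "ONE_HIT"
      status[d$deep_del$gene] <- "ONE_HIT"
    }
    if (i %in% d$deep_del$samples) status[d$deep_del$gene] <- "TWO_HIT"
    if (i %in% d$hom_mut$samples) status[d$hom_mut$gene] <- "TWO_HIT"
    if (i %in% d$het_loss$samples) status[d$het_loss$gene] <- "TWO_HIT"
    if (i %in% d$mut_only$samples) status[d$mut_only$gene] <- "ONE_HIT"
    alt_truth[[i]] <- data.frame(sample_id = samples[i],
                                 gene = names(status), status = status,
                                 stringsAsFactors = FALSE)
  }
  truth_alterations <- do.call(rbind, alt_truth)
  rownames(truth_alterations) <- NULL

  # ---- external counts, census, gene sets, capture ------------------------
  set.seed(.sub_seed(spec$seed, 0L, 5L))
  hot <- sample(c(TRUE, FALSE), nrow(genes), replace = TRUE, prob = c(.6, .4))
  ext <- data.frame(gene = genes$gene,
                    n_mutated = ifelse(hot, stats::rpois(nrow(genes), 6),
                                       stats::rpois(nrow(genes), 1)),
                    stringsAsFactors = FALSE)
  ext$n_mutated[ext$gene %in% desig_genes] <-
    pmax(ext$n_mutated[ext$gene %in% desig_genes], 5L)
  census <- sort(sample(setdiff(genes$gene, desig_genes), 8L))
  gmt <- lapply(seq_len(12L), function(t) sample(genes$gene, 8L))
  names(gmt) <- sprintf("GO:%07d\tsynthetic process %d", seq_len(12L) * 11L,
                        seq_len(12L))
  captured_genes <- sort(unique(c(desig_genes,
                                  sample(genes$gene, 20L))))
  cand <- truth_variants[truth_variants$origin == "SOMATIC" &
                           truth_variants$gene %in% captured_genes, ,
                         drop = FALSE]
  cdp <- stats::rpois(nrow(cand), 200)
  cvaf <- ifelse(stats::runif(nrow(cand)) < spec$capture_nonconfirm_rate,
                 0.005, cand$vaf)
  calt <- stats::rbinom(nrow(cand), cdp, cvaf)
  capture <- data.frame(sample_id = cand$sample_id, chrom = cand$chrom,
                        pos = cand$pos, ref = cand$ref, alt = cand$alt,
                        capture_ref = cdp - calt, capture_alt = calt,
                        stringsAsFactors = FALSE)

  # ---- write everything ---------------------------------------------------
  paths <- list(
    vcf_dir = vcfdir,
    counts = file.path(outdir, "counts.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    expressed = file.path(outdir, "expressed_genes.txt"),
    seg = file.path(outdir, "cohort.seg"),
    bed = file.path(outdir, "genes.bed"),
    external_counts = file.path(outdir, "external_counts.tsv"),
    census = file.path(outdir, "census_genes.txt"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    capture = file.path(outdir, "capture_counts.tsv"),
    truth_variants = file.path(outdir, "truth_variants.tsv"),
    truth_alterations = file.path(outdir, "truth_alterations.tsv"))
  for (pc in per_caller) {
    .write_vcf(pc$records,
               file.path(vcfdir, paste0(paste(pc$sample_id, pc$tissue,
                                              pc$caller, sep = "_"), ".vcf")),
               spec$n_chroms, spec$chrom_length)
  }
  .write_tsv(counts_df, paths$counts)
  .write_tsv(annotations, paths$annotations)
  writeLines(expressed, paths$expressed)
  .write_tsv(seg_df, paths$seg)
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene,
                    0L, genes$strand)
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_tsv(ext, paths$external_counts)
  writeLines(census, paths$census)
  writeLines(vapply(seq_along(gmt), function(t)
    paste(c(names(gmt)[t], gmt[[t]]), collapse = "\t"), character(1)),
    paths$gmt)
  .write_tsv(capture, paths$capture)
  .write_tsv(truth_variants, paths$truth_variants)
  .write_tsv(truth_alterations, paths$truth_alterations)

  invisible(list(dir = outdir, paths = paths,
                 truth_variants = truth_variants,
                 truth_alterations = truth_alterations, spec = spec))
}

#' Closed-form recovery expectations for a synthetic cohort
#'
#' Per-variant probabilities that at least two of the three callers (tumor
#' consensus) or at least one caller (normal retention) detect a true
#' variant, plus the implied expected consensus size per planted variant.
#'
#' @param spec A [cohort_spec()].
#' @return List: `p_consensus_tumor`, `p_detect_normal`,
#'   `expected_consensus_per_tumor` (somatic + germline mean times
#'   `p_consensus_tumor`).
#' @export
expected_recovery <- function(spec) {
  s <- spec$caller_sensitivity
  stopifnot(length(s) == 3L)
  p0 <- prod(1 - s)
  p1 <- sum(vapply(seq_along(s), function(i) s[i] * prod(1 - s[-i]),
                   numeric(1)))
  p2 <- 1 - p0 - p1
  list(p_consensus_tumor = p2,
       p_detect_normal = 1 - p0,
       expected_consensus_per_tumor =
         (spec$somatic_mean + spec$germline_per_sample) * p2)
}
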