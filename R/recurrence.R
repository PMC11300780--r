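#' Select candidate genes by in-cohort and external recurrence
#'
#' A gene is a candidate when it carries a functional variant in at least
#' `cohort_min` cohort samples (a sample counts once per gene regardless of
#' variant multiplicity) and is mutated in at least `external_min` samples of
#' the external reference cohort. Candidates present in the supplied
#' known-driver (census) list are flagged; the remainder are the novel
#' candidates.
#'
#' @param functional Data frame of functional variants with `sample_id` and
#'   `gene` columns.
#' @param external_counts Data frame with columns `gene`, `n_mutated`
#'   (per-gene mutated-sample counts in the external cohort); genes absent
#'   from it count 0.
#' @param cohort_min,external_min Recurrence thresholds.
#' @param known_drivers Character vector of census gene symbols.
#' @return Data frame with one row per mutated gene: `gene`,
#'   `cohort_mutated_samples`, `external_mutated_samples`, `is_candidate`,
#'   `is_known_driver`.
#' @export
select_candidates <- function(functional, external_counts,
                              cohort_min = 2L, external_min = 3L,
                              known_drivers = character()) {
  if (nrow(functional) == 0L)
    return(data.frame(gene = character(), cohort_mutated_samples = integer(),
                      external_mutated_samples = integer(),
                      is_candidate = logical(), is_known_driver = logical(),
                      stringsAsFactors = FALSE))
  u <- unique(functional[, c("sample_id", "gene")])
  tab <- table(u$gene)
  ext <- external_counts$n_mutated[match(names(tab), external_counts$gene)]
  ext[is.na(ext)] <- 0L
  out <- data.frame(gene = names(tab),
                    cohort_mutated_samples = as.integer(tab),
                    external_mutated_samples = as.integer(ext),
                    stringsAsFactors = FALSE)
  out$is_candidate <- out$cohort_mutated_samples >= cohort_min &
    out$external_mutated_samples >= external_min
  out$is_known_driver <- out$gene %in% known_drivers
  out <- out[order(-out$cohort_mutated_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with population size `N`, `K` successes and
#' `n` draws, computed by summing the pmf on the log-binomial scale
#' (numerically stable for the gene-set sizes encountered here).
#'
#' @param k Observed overlap (successes drawn).
#' @param K Term size (successes in population).
#' @param n Draws (sample gene-list size).
#' @param N Population (universe) size.
#' @return The tail probability, in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (N < 0L || K < 0L || n < 0L || k < 0L || K > N || n > N || k > min(K, n))
    stop("hypergeometric bounds violated: k=", k, " K=", K, " n=", n, " N=", N)
  if (k == 0L) return(1.0)
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- sum(exp(lp))
  min(max(p, 0), 1)
}

#' Read a GMT gene-set file
#'
#' @param path Tab-delimited GMT: term, description, member genes.
#' @return Named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Per-sample hypergeometric gene-set enrichment with cross-sample recurrence
#'
#' For each sample, each term is tested for over-representation of the
#' sample's candidate genes against the universe; a term is enriched when its
#' nominal upper-tail p-value is at or below `alpha`, and recurrent when
#' enriched in at least `min_recurrent_samples` samples.
#'
#' @param sample_genes Named list: sample -> character vector of genes.
#' @param gene_sets Named list from [read_gmt()].
#' @param universe Character vector of background genes (non-empty); sample
#'   genes and set members are intersected with it before testing.
#' @param alpha Nominal significance threshold.
#' @param min_recurrent_samples Recurrence threshold across samples.
#' @param p_adjust Multiple-testing method passed to [stats::p.adjust()]
#'   within each sample (`"none"` by default).
#' @return List with `results` (one row per sample x term: `sample_id`,
#'   `term`, `term_size`, `sample_gene_count`, `overlap`, `universe_size`,
#'   `p_value`, `enriched`), `recurrent_terms`, and `membership` (gene x term
#'   logical matrix over the union of sample genes).
#' @export
enrich_per_sample <- function(sample_genes, gene_sets, universe,
                              alpha = 0.05, min_recurrent_samples = 3L,
                              p_adjust = "none") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  N <- length(universe)
  sets <- lapply(gene_sets, intersect, universe)
  rows <- list()
  for (s in names(sample_genes)) {
    genes <- intersect(unique(sample_genes[[s]]), universe)
    n <- length(genes)
    p <- vapply(sets, function(g) {
      hypergeom_upper_tail(length(intersect(g, genes)), length(g), n, N)
    }, numeric(1))
    padj <- stats::p.adjust(p, method = p_adjust)
    rows[[s]] <- data.frame(
      sample_id = s, term = names(sets),
      term_size = lengths(sets), sample_gene_count = n,
      overlap = vapply(sets, function(g) length(intersect(g, genes)),
                       integer(1)),
      universe_size = N, p_value = p, enriched = padj <= alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  counts <- tapply(res$enriched, res$term, sum)
  recurrent <- sort(names(counts)[counts >= min_recurrent_samples])
  all_genes <- sort(unique(unlist(sample_genes)))
  membership <- vapply(gene_sets, function(g) all_genes %in% g,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(all_genes, names(gene_sets)))
  else rownames(membership) <- all_genes
  list(results = res, recurrent_terms = recurrent, membership = membership)
}
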