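## Per-chromosome hypergeometric enrichment of a gene list against
## protein-coding annotation.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): drawing n genes from a
#' population of N containing K successes and observing at least k. The
#' tail is inclusive of the observed count and evaluated by `phyper` in a
#' numerically safe way down to tail magnitudes ~1e-22. Vectorized over
#' `n` and `k`.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draws.
#' @param k Observed successes among draws.
#' @return P(X >= k).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(k < 0) || any(n < 0) || any(k > n) || any(n > N) || K > N || any(k > K))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.enrichment_rows <- function(counts) {
  N <- sum(counts$n_genes)
  K <- sum(counts$n_hits)
  if (K == 0L) stop("no hits in the population: nothing to test", call. = FALSE)
  data.frame(chromosome = counts$chromosome,
             n_genes = counts$n_genes,
             n_hits = counts$n_hits,
             pct_distribution = 100 * counts$n_hits / K,
             p_value = hypergeom_upper_tail(N, K, counts$n_genes, counts$n_hits),
             stringsAsFactors = FALSE)
}

#' Per-chromosome enrichment from pre-counted totals
#'
#' Takes a table of per-chromosome gene and hit counts (e.g. exported from
#' a published per-chromosome summary) and computes the enrichment rows
#' directly, with the population and success totals obtained by summing
#' the two count columns.
#'
#' @param counts data.frame with columns `chromosome`, `n_genes`, `n_hits`.
#' @return data.frame with chromosome, n_genes, n_hits, pct_distribution,
#'   p_value.
#' @export
enrichment_from_counts <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("chromosome", "n_genes", "n_hits") %in% names(counts)))
  if (any(counts$n_hits > counts$n_genes))
    stop("n_hits cannot exceed n_genes on a chromosome", call. = FALSE)
  .enrichment_rows(counts)
}

#' Per-chromosome enrichment of a gene list
#'
#' Restricts the annotation to the requested biotype and chromosomes
#' (default: protein-coding genes on autosomes chr1-chr22), counts genes
#' and list members per chromosome, and tests each chromosome by the
#' upper-tail hypergeometric with population N = all filtered genes and
#' K = all filtered hits. Hits outside the filtered universe are dropped
#' with a warning.
#'
#' @param hits Character vector of gene ids.
#' @param annotation A `gene_annotation` data.frame.
#' @param biotype_filter Biotype to keep, or NULL for all.
#' @param chromosomes Chromosomes to keep; default the autosomes present
#'   in the annotation (chr1-chr22 naming, or everything when no such
#'   names exist).
#' @return data.frame, one row per chromosome.
#' @export
per_chromosome_enrichment <- function(hits, annotation,
                                      biotype_filter = "protein_coding",
                                      chromosomes = NULL) {
  ann <- annotation
  if (!is.null(biotype_filter)) ann <- ann[ann$biotype %in% biotype_filter, ]
  if (is.null(chromosomes)) {
    autos <- paste0("chr", 1:22)
    chromosomes <- if (any(ann$chromosome %in% autos))
      intersect(autos, unique(ann$chromosome)) else unique(ann$chromosome)
  }
  ann <- ann[ann$chromosome %in% chromosomes, ]
  if (!nrow(ann)) stop("empty gene universe after filtering", call. = FALSE)
  out_univ <- setdiff(hits, ann$gene_id)
  if (length(out_univ))
    warning(sprintf("%d hit(s) outside the filtered gene universe dropped",
                    length(out_univ)), call. = FALSE)
  hits <- intersect(hits, ann$gene_id)
  if (!length(hits)) stop("no hits in the filtered gene universe", call. = FALSE)
  chrom <- factor(ann$chromosome, levels = chromosomes)
  counts <- data.frame(
    chromosome = chromosomes,
    n_genes = as.integer(table(chrom)),
    n_hits = as.integer(table(factor(ann$chromosome[ann$gene_id %in% hits],
                                     levels = chromosomes))),
    stringsAsFactors = FALSE)
  .enrichment_rows(counts)
}
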