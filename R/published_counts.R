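## Bundled per-chromosome counts of the published MNA-neuroblastoma
## essentiality screen: autosomal protein-coding genes per chromosome and
## the 175 autosomal context-essential genes among them.

#' Published per-chromosome essential-gene counts
#'
#' The per-autosome counts of protein-coding genes and of MNA-neuroblastoma
#' essential genes (175 autosomal hits in a population of 19,046
#' protein-coding genes), as bundled with the package. Feeding this table
#' to [enrichment_from_counts()] reproduces the published per-chromosome
#' enrichment p-values, including the chromosome-17 signal at ~5e-22.
#'
#' @return data.frame with columns chromosome, n_genes, n_hits.
#' @export
nb_chromosome_counts <- function() {
  path <- system.file("extdata", "nb_essential_chromosome_counts.tsv",
                      package = "neuro17q", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
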