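## Rank-correlation machinery: Spearman correlation, correlation-of-
## correlations transcription-factor signature similarity, knockdown-logFC
## concordance, adrenergic/mesenchymal signature scores, and E-box motif
## scanning.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (tie-corrected). A constant
#' input has no defined rank correlation and yields NA with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or NA for degenerate input.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Correlation of correlations between two genes' co-expression signatures
#'
#' For every gene except the two anchors, the Spearman correlation with the
#' anchor gene and with the transcription factor across samples is
#' computed; the similarity of the two co-expression signatures is the
#' Spearman correlation between those two coefficient vectors. The anchors
#' are excluded from the gene universe (their self-correlations of 1 would
#' inflate the result); zero-variance genes are dropped.
#'
#' @param expr Genes x samples numeric matrix (optionally with a `scale`
#'   attribute from [read_matrix()]).
#' @param anchor,tf Row names of the two genes compared.
#' @param min_expr_sum Keep only genes whose row sum is at least this;
#'   `NULL` (default) applies 1 when the declared scale is FPKM (the usual
#'   at-least-1-FPKM-in-sum filter) and no filter otherwise.
#' @return List with `rho`, `profiles` (data.frame gene, r_anchor, r_tf),
#'   `n_samples`, `n_genes`.
#' @export
correlation_of_correlations <- function(expr, anchor, tf, min_expr_sum = NULL) {
  stopifnot(is.matrix(expr))
  if (!anchor %in% rownames(expr)) stop(sprintf("anchor '%s' not in matrix", anchor), call. = FALSE)
  if (!tf %in% rownames(expr)) stop(sprintf("tf '%s' not in matrix", tf), call. = FALSE)
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (is.null(min_expr_sum))
    min_expr_sum <- if (identical(attr(expr, "scale"), "FPKM")) 1 else 0
  if (identical(anchor, tf)) {
    return(list(rho = 1, profiles = NULL, n_samples = ncol(expr), n_genes = NA_integer_))
  }
  others <- setdiff(rownames(expr), c(anchor, tf))
  others <- others[rowSums(expr[others, , drop = FALSE]) >= min_expr_sum]
  v <- apply(expr[others, , drop = FALSE], 1L, stats::sd)
  if (any(v == 0)) {
    message(sprintf("%d zero-variance gene(s) dropped", sum(v == 0)))
    others <- others[v > 0]
  }
  if (length(others) < 3L) stop("fewer than 3 usable genes", call. = FALSE)
  ranks <- t(apply(expr[c(others, anchor, tf), , drop = FALSE], 1L, rank))
  cc <- stats::cor(t(ranks[others, , drop = FALSE]),
                   t(ranks[c(anchor, tf), , drop = FALSE]))
  profiles <- data.frame(gene = others, r_anchor = cc[, 1L], r_tf = cc[, 2L],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(rho = spearman_cor(profiles$r_anchor, profiles$r_tf),
       profiles = profiles, n_samples = ncol(expr),
       n_genes = length(others))
}

#' Concordance of two knockdown logFC profiles
#'
#' Spearman correlation of per-gene log fold changes over the intersection
#' of the two gene universes.
#'
#' @param logfc_a,logfc_b Named numeric vectors of per-gene logFC.
#' @return List with `rho` and `n` (shared genes used).
#' @export
knockdown_concordance <- function(logfc_a, logfc_b) {
  shared <- intersect(names(logfc_a), names(logfc_b))
  if (length(shared) < 3L)
    stop("fewer than 3 shared genes between the two profiles", call. = FALSE)
  list(rho = spearman_cor(logfc_a[shared], logfc_b[shared]), n = length(shared))
}

#' Adrenergic-minus-mesenchymal signature score
#'
#' Per sample, the mean per-gene z-score over `set_a` minus the mean over
#' `set_b`, with z-scoring per gene across samples on the log2 scale
#' (linear-scale input — declared scale FPKM or TMM — is transformed as
#' log2(v + 1); log-scale input is used as is). Positive scores indicate
#' an adrenergic-dominant sample when set_a is the adrenergic signature.
#'
#' @param expr Genes x samples matrix with a declared `scale` attribute.
#' @param set_a,set_b Character vectors of gene ids.
#' @return Named numeric vector of per-sample scores (`set_a` minus
#'   `set_b` mean z-score).
#' @export
signature_score_ratio <- function(expr, set_a, set_b) {
  stopifnot(is.matrix(expr))
  sc <- attr(expr, "scale")
  a <- intersect(set_a, rownames(expr))
  b <- intersect(set_b, rownames(expr))
  if (length(a) < length(set_a) || length(b) < length(set_b))
    message(sprintf("%d signature gene(s) absent from matrix",
                    length(set_a) - length(a) + length(set_b) - length(b)))
  if (!length(a)) stop("no gene of set_a present in the matrix", call. = FALSE)
  if (!length(b)) stop("no gene of set_b present in the matrix", call. = FALSE)
  m <- expr[unique(c(a, b)), , drop = FALSE]
  if (!is.null(sc) && sc %in% c("FPKM", "TMM")) m <- log2(m + 1)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) warning(sprintf("%d constant gene(s) dropped from signature",
                                  sum(!keep)), call. = FALSE)
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  a <- intersect(a, rownames(z)); b <- intersect(b, rownames(z))
  if (!length(a) || !length(b))
    stop("a signature set lost all genes to the constant-gene filter", call. = FALSE)
  colMeans(z[a, , drop = FALSE]) - colMeans(z[b, , drop = FALSE])
}

#' Scan a sequence for the MYC/N E-box motif
#'
#' Reports the 0-based start position of every (possibly overlapping)
#' hexamer matching CANNTG, where N is any of A/C/G/T. The motif is its
#' own reverse complement, so scanning one strand suffices. Ambiguous `N`
#' bases in the input never match (a base must be observed); characters
#' outside {A,C,G,T,N} are an error reporting the 0-based offset.
#'
#' @param sequence Single nucleotide string, case-insensitive.
#' @return Integer vector of 0-based match positions.
#' @export
ebox_scan <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("non-IUPAC character '%s' at offset %d", chars[bad[1L]],
                 bad[1L] - 1L), call. = FALSE)
  if (nchar(s) < 6L) return(integer())
  hits <- Biostrings::matchPattern("CANNTG", Biostrings::DNAString(s),
                                   fixed = "subject")
  pos <- as.integer(Biostrings::start(hits) - 1L)
  # an ambiguous N in the subject may not stand in for the motif's NN core
  has_n <- vapply(pos, function(p) any(chars[(p + 1):(p + 6)] == "N"), logical(1L))
  pos[!has_n]
}
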