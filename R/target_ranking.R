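## Multi-evidence oncogene ranking: per-criterion min-max scaling (unit or
## symmetric), orientation so that larger always means more oncogenic, and
## a composite score over the evidence a gene actually has.

#' Min-max scale one evidence row
#'
#' Unit mode maps to [0, 1]; symmetric mode to [-1, 1]. A constant row maps
#' to all zeros (no information either way). Missing values pass through.
#'
#' @param values Numeric vector with at least one finite value.
#' @param scaling "unit" or "symmetric".
#' @return Scaled values, NAs preserved.
#' @export
scale_row <- function(values, scaling = c("unit", "symmetric")) {
  scaling <- match.arg(scaling)
  ok <- is.finite(values)
  if (!any(ok)) stop("all-missing evidence row", call. = FALSE)
  rng <- range(values[ok])
  out <- rep(NA_real_, length(values))
  if (rng[1L] == rng[2L]) {
    out[ok] <- 0
    return(out)
  }
  u <- (values[ok] - rng[1L]) / (rng[2L] - rng[1L])
  out[ok] <- if (scaling == "unit") u else 2 * u - 1
  out
}

#' Criterion configuration for the evidence matrix
#'
#' @param criterion Criterion names (must match evidence column names).
#' @param orientation Per criterion, "higher_is_oncogenic" or
#'   "lower_is_oncogenic" (e.g. dependency scores, where more negative
#'   means more essential).
#' @param scaling Per criterion, "unit" (0..1, e.g. ChIP/CLIP occupancy
#'   scores) or "symmetric" (-1..1, signed evidence).
#' @return data.frame describing the criteria.
#' @export
evidence_criteria <- function(criterion,
                              orientation = "higher_is_oncogenic",
                              scaling = "symmetric") {
  orientation <- rep_len(orientation, length(criterion))
  scaling <- rep_len(scaling, length(criterion))
  if (!all(orientation %in% c("higher_is_oncogenic", "lower_is_oncogenic")))
    stop("unknown orientation", call. = FALSE)
  if (!all(scaling %in% c("unit", "symmetric")))
    stop("unknown scaling mode", call. = FALSE)
  data.frame(criterion = criterion, orientation = orientation,
             scaling = scaling, stringsAsFactors = FALSE)
}

#' Composite multi-evidence ranking
#'
#' Each criterion column is min-max scaled per its declared mode and
#' oriented so that larger means more oncogenic (lower_is_oncogenic
#' criteria are negated after scaling). The composite score is the mean of
#' the oriented scaled values over the criteria a gene has evidence for;
#' missing evidence is excluded from the mean unless `missing_as_floor`
#' replaces it by the worst oriented value of that criterion. Genes with
#' no evidence at all are excluded with a warning. Ties are broken by gene
#' id.
#'
#' @param evidence Genes x criteria numeric matrix (NAs allowed).
#' @param criteria A data.frame from [evidence_criteria()] covering every
#'   column of `evidence`.
#' @param missing_as_floor Score missing evidence as the criterion's worst
#'   value instead of dropping it (default FALSE).
#' @return List with `ranking` (data.frame gene, composite, n_criteria,
#'   rank) and `scaled` (the oriented scaled matrix, heatmap-ready).
#' @export
composite_rank <- function(evidence, criteria, missing_as_floor = FALSE) {
  stopifnot(is.matrix(evidence), !is.null(colnames(evidence)),
            !is.null(rownames(evidence)))
  if (!all(colnames(evidence) %in% criteria$criterion))
    stop("every evidence column needs a declared criterion", call. = FALSE)
  scaled <- evidence
  for (j in seq_len(ncol(evidence))) {
    cr <- criteria[criteria$criterion == colnames(evidence)[j], ]
    s <- scale_row(evidence[, j], cr$scaling)
    if (cr$orientation == "lower_is_oncogenic") s <- -s
    if (missing_as_floor && anyNA(s)) {
      floor_val <- min(s, na.rm = TRUE)
      s[is.na(s)] <- floor_val
    }
    scaled[, j] <- s
  }
  n_crit <- rowSums(!is.na(scaled))
  if (any(n_crit == 0L)) {
    warning(sprintf("%d gene(s) with no evidence excluded", sum(n_crit == 0L)),
            call. = FALSE)
  }
  keep <- n_crit > 0L
  composite <- rowMeans(scaled[keep, , drop = FALSE], na.rm = TRUE)
  ord <- order(-composite, rownames(scaled)[keep])
  ranking <- data.frame(gene = rownames(scaled)[keep][ord],
                        composite = composite[ord],
                        n_criteria = n_crit[keep][ord],
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(ranking = ranking, scaled = scaled)
}

#' Compare published co-expression signature similarities
#'
#' Recomputes the correlation-of-correlations of an anchor gene with one
#' or more transcription factors on a user-supplied processed tumor
#' expression matrix (TSV, genes x samples). Intended for checking
#' published signature-similarity values on cohorts that must be obtained
#' separately; it is a thin wrapper over [correlation_of_correlations()].
#'
#' @param expr_path Path to the expression TSV.
#' @param anchor Anchor gene id (default "IGF2BP1").
#' @param tfs Transcription factors to compare (default MYCN, PHOX2B).
#' @param scale Declared scale of the matrix.
#' @return data.frame with columns tf, rho, n_genes, n_samples.
#' @export
validate_published_correlations <- function(expr_path, anchor = "IGF2BP1",
                                            tfs = c("MYCN", "PHOX2B"),
                                            scale = "TMM") {
  if (!is.character(expr_path) || length(expr_path) != 1L || !file.exists(expr_path))
    stop("expr_path must point to an existing expression TSV", call. = FALSE)
  expr <- read_matrix(expr_path, scale = scale)
  rows <- lapply(tfs, function(tf) {
    cc <- correlation_of_correlations(expr, anchor, tf)
    data.frame(tf = tf, rho = cc$rho, n_genes = cc$n_genes,
               n_samples = cc$n_samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
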