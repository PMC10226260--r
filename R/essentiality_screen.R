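## MNA-context essentiality screen: expression filter, median-dependency
## filters, common-essential exclusion, empirical-Bayes moderated two-group
## test, BH FDR. The moderated test (prior fit by method of moments on
## log s^2, scaled-inverse-chi-square prior) is implemented here; its
## shrinkage target (d0, s0^2) is reported alongside per-gene statistics.

#' Screen parameters
#'
#' Defaults reproduce the screening rules of a 13-vs-607 cell-line screen:
#' minimum expression log2 TPM > 2 in at least floor(0.85 * 13) = 11
#' context lines (11 of 13 is ~85%), median dependency below -0.2 in the
#' context group and above -0.3 in the comparison group, hits at
#' FDR < 0.05.
#'
#' @param expr_threshold Expression threshold, log2 TPM (strict >).
#' @param expr_min_fraction Minimum fraction of context lines expressing;
#'   realized as at least `floor(expr_min_fraction * n_context)` lines,
#'   which reproduces the 11-of-13 rule at the default fraction.
#' @param dep_median_mna Context-group median must be strictly below this.
#' @param dep_median_other Comparison-group median must be strictly above this.
#' @param fdr_alpha Hit threshold on BH-adjusted p-values.
#' @return A `screen_params` list.
#' @export
screen_params <- function(expr_threshold = 2, expr_min_fraction = 0.85,
                          dep_median_mna = -0.2, dep_median_other = -0.3,
                          fdr_alpha = 0.05) {
  stopifnot(is.finite(expr_threshold), is.finite(dep_median_mna),
            is.finite(dep_median_other))
  if (expr_min_fraction <= 0 || expr_min_fraction > 1)
    stop("expr_min_fraction must be in (0, 1]", call. = FALSE)
  .check_fraction(fdr_alpha, "fdr_alpha")
  structure(list(expr_threshold = expr_threshold,
                 expr_min_fraction = expr_min_fraction,
                 dep_median_mna = dep_median_mna,
                 dep_median_other = dep_median_other,
                 fdr_alpha = fdr_alpha),
            class = "screen_params")
}

#' Expression filter
#'
#' Keeps genes expressed (strictly above `expr_threshold` log2 TPM) in at
#' least `floor(expr_min_fraction * n_context)` context-group lines.
#' Genes absent from the expression matrix are treated as unexpressed.
#'
#' @param screen A [dependency_screen()].
#' @param params A [screen_params()].
#' @param genes Optional gene universe; defaults to all dependency genes.
#' @return Character vector of kept genes.
#' @export
filter_expression <- function(screen, params = screen_params(),
                              genes = rownames(screen$dep)) {
  ctx <- screen$group == screen$context
  need <- max(1, floor(params$expr_min_fraction * sum(ctx) + 1e-9))
  absent <- setdiff(genes, rownames(screen$expr))
  if (length(absent))
    message(sprintf("%d gene(s) absent from expression matrix; treated as unexpressed",
                    length(absent)))
  present <- intersect(genes, rownames(screen$expr))
  n_expr <- rowSums(screen$expr[present, ctx, drop = FALSE] > params$expr_threshold)
  present[n_expr >= need]
}

#' Median-dependency filter
#'
#' Keeps genes whose context-group median dependency is strictly below
#' `dep_median_mna` and whose comparison-group median is strictly above
#' `dep_median_other` (selective essentiality in the context group only).
#' Genes missing from the dependency matrix are dropped.
#'
#' @inheritParams filter_expression
#' @return Character vector of kept genes.
#' @export
filter_dependency <- function(screen, params = screen_params(),
                              genes = rownames(screen$dep)) {
  missing <- setdiff(genes, rownames(screen$dep))
  if (length(missing))
    message(sprintf("%d gene(s) absent from dependency matrix; dropped",
                    length(missing)))
  genes <- intersect(genes, rownames(screen$dep))
  if (!length(genes)) return(character())
  ctx <- screen$group == screen$context
  med_a <- apply(screen$dep[genes, ctx, drop = FALSE], 1L, stats::median)
  med_b <- apply(screen$dep[genes, !ctx, drop = FALSE], 1L, stats::median)
  genes[med_a < params$dep_median_mna & med_b > params$dep_median_other]
}

#' Remove common-essential genes
#'
#' @param genes Character vector of candidate genes.
#' @param common_essential Character vector of pan-lineage essential genes.
#' @return Set difference, order preserved.
#' @export
exclude_common_essential <- function(genes, common_essential) {
  genes[!genes %in% common_essential]
}

# Newton solve of trigamma(y) = x, x > 0
.trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# method-of-moments fit of the scaled-inverse-chi-square prior on s^2:
# e_g = log(s_g^2) - digamma(d/2) + log(d/2) has mean
# log(s0^2) - digamma(d0/2) + log(d0/2) and variance
# trigamma(d/2) + trigamma(d0/2)
.fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok))
    stop("degenerate prior: every gene has zero residual variance", call. = FALSE)
  if (any(!ok))
    warning(sprintf("%d gene(s) with zero residual variance excluded from prior fit",
                    sum(!ok)), call. = FALSE)
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (length(e) < 2L || !is.finite(evar) || evar <= 0) {
    # no excess spread in the log-variances: infinite prior df, i.e. full
    # shrinkage to the common variance (their arithmetic mean)
    d0 <- Inf
    s02 <- mean(s2[ok])
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene, the group-mean difference (context minus comparison) is tested
#' with a residual variance shrunk toward an empirical-Bayes prior: the
#' per-gene variances s_g^2 (pooled, d = n1 + n2 - 2 df) are modelled as
#' scaled inverse chi-square with prior df d0 and prior variance s0^2,
#' fitted in closed form by matching moments of log s_g^2 (digamma /
#' trigamma). The posterior variance is
#' (d0 s0^2 + d s_g^2) / (d0 + d), the moderated t is the mean difference
#' over its shrunken standard error, and two-sided p-values use d0 + d
#' degrees of freedom (a normal reference when d0 is infinite, i.e. full
#' shrinkage).
#'
#' @param dep Gene x line numeric matrix.
#' @param group Per-line labels with exactly two distinct values; the
#'   tested difference is the `context` group mean minus the other group
#'   mean.
#' @param context Optional label naming the group whose mean comes first in
#'   the difference (defaults to the first distinct label).
#' @return data.frame with columns gene, diff, s2, t_mod, df_total, p; the
#'   fitted prior is attached as attributes `d0` and `s02`.
#' @export
moderated_t_test <- function(dep, group, context = NULL) {
  stopifnot(is.matrix(dep), is.numeric(dep), ncol(dep) == length(group))
  labs <- unique(group)
  if (length(labs) != 2L) stop("group must have exactly two labels", call. = FALSE)
  if (is.null(context)) context <- labs[1L]
  if (!context %in% labs) stop("context label not present in group", call. = FALSE)
  a <- group == context
  n1 <- sum(a); n2 <- sum(!a)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 lines per group", call. = FALSE)
  m <- nrow(dep)
  if (m < 1L) stop("no genes to test", call. = FALSE)
  m1 <- rowMeans(dep[, a, drop = FALSE])
  m2 <- rowMeans(dep[, !a, drop = FALSE])
  delta <- m1 - m2
  ss <- rowSums((dep[, a, drop = FALSE] - m1)^2) +
    rowSums((dep[, !a, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- ss / df
  if (m == 1L) {
    warning("single gene: no prior can be estimated; ordinary t-test used",
            call. = FALSE)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    t_mod <- ifelse(se > 0, delta / se, 0)
    out <- data.frame(gene = rownames(dep), diff = delta, s2 = s2,
                      t_mod = t_mod, df_total = df,
                      p = 2 * stats::pt(-abs(t_mod), df),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "d0") <- 0; attr(out, "s02") <- NA_real_
    return(out)
  }
  prior <- .fit_variance_prior(s2, df)
  if (is.finite(prior$d0)) {
    s2_post <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
    df_total <- prior$d0 + df
  } else {
    s2_post <- rep(prior$s02, m)
    df_total <- Inf
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, delta / se, 0)
  p <- if (is.finite(df_total)) 2 * stats::pt(-abs(t_mod), df_total)
       else 2 * stats::pnorm(-abs(t_mod))
  out <- data.frame(gene = rownames(dep), diff = delta, s2 = s2,
                    t_mod = t_mod, df_total = df_total, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment controlling the false discovery rate; values outside
#' [0, 1] are a validation error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Run the full context-essentiality screen
#'
#' Filter cascade in order: expression filter, median-dependency filter,
#' common-essential exclusion, moderated two-group test on the surviving
#' genes, BH FDR; a hit is a surviving gene with FDR below `fdr_alpha`.
#' Every intermediate flag is retained per gene.
#'
#' @param screen A [dependency_screen()].
#' @param params A [screen_params()].
#' @return data.frame with one row per gene in the dependency matrix:
#'   pass_expression, median_dep_mna, median_dep_other, pass_dependency,
#'   excluded_common, tested, t_mod, p, fdr, hit. The fitted prior (d0,
#'   s02) is attached as attributes.
#' @export
run_screen <- function(screen, params = screen_params()) {
  stopifnot(inherits(screen, "dependency_screen"))
  genes <- rownames(screen$dep)
  ctx <- screen$group == screen$context
  med_a <- apply(screen$dep[, ctx, drop = FALSE], 1L, stats::median)
  med_b <- apply(screen$dep[, !ctx, drop = FALSE], 1L, stats::median)
  keep_e <- filter_expression(screen, params, genes)
  keep_d <- filter_dependency(screen, params, keep_e)
  tested <- exclude_common_essential(keep_d, screen$common_essential)
  res <- data.frame(
    gene = genes,
    pass_expression = genes %in% keep_e,
    median_dep_mna = med_a,
    median_dep_other = med_b,
    pass_dependency = med_a < params$dep_median_mna &
      med_b > params$dep_median_other,
    excluded_common = genes %in% screen$common_essential,
    tested = genes %in% tested,
    t_mod = NA_real_, p = NA_real_, fdr = NA_real_, hit = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!length(tested)) {
    warning("no gene survives the filter cascade; empty screen result",
            call. = FALSE)
    return(res)
  }
  tt <- moderated_t_test(screen$dep[tested, , drop = FALSE], screen$group,
                         context = screen$context)
  idx <- match(tested, genes)
  res$t_mod[idx] <- tt$t_mod
  res$p[idx] <- tt$p
  res$fdr[idx] <- bh_fdr(tt$p)
  res$hit[idx] <- res$fdr[idx] < params$fdr_alpha
  attr(res, "d0") <- attr(tt, "d0")
  attr(res, "s02") <- attr(tt, "s02")
  res
}
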