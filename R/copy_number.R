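## Copy-number state calling, the 17q balance-value classifier, MYCN
## amplification calling, and cohort-level aberration frequency profiles.

#' Copy-number calling thresholds
#'
#' Canonical log2-ratio thresholds for somatic copy-number calls on shallow
#' WGS profiles: a bin is gained at log2 ratio >= +0.3 and lost at <= -0.4.
#' MYCN amplification is called when the integer copy number at the MYCN
#' locus exceeds `mna_cn` (strictly). `balance_offset` is the additive
#' constant of the 17q balance value.
#'
#' @param loss_log2 Loss threshold on the log2 scale (negative).
#' @param gain_log2 Gain threshold on the log2 scale (positive).
#' @param mna_cn Copy-number threshold for MYCN amplification (call is CN > mna_cn).
#' @param balance_offset Offset added in the balance value.
#' @return A `cn_thresholds` list.
#' @export
cn_thresholds <- function(loss_log2 = -0.4, gain_log2 = 0.3,
                          mna_cn = 4, balance_offset = 0.2) {
  stopifnot(is.finite(loss_log2), is.finite(gain_log2), is.finite(mna_cn),
            is.finite(balance_offset))
  if (!(loss_log2 < 0 && 0 < gain_log2))
    stop("need loss_log2 < 0 < gain_log2", call. = FALSE)
  structure(list(loss_log2 = loss_log2, gain_log2 = gain_log2,
                 mna_cn = mna_cn, balance_offset = balance_offset),
            class = "cn_thresholds")
}

#' Per-sample binned copy-number profile
#'
#' @param sample_id Sample identifier.
#' @param bins data.frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` and optionally `cn`. Bins must be sortable into
#'   non-overlapping order within each chromosome; they are stored sorted
#'   by (chrom, start).
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(sample_id, bins) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.data.frame(bins))
  need <- c("chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(bins)))
    stop("bins need columns chrom, start, end, log2_ratio", call. = FALSE)
  if (!all(is.finite(bins$log2_ratio)))
    stop(sprintf("non-finite log2 ratio in sample '%s'", sample_id), call. = FALSE)
  if (any(bins$end <= bins$start))
    stop(sprintf("bin with end <= start in sample '%s'", sample_id), call. = FALSE)
  ord <- order(bins$chrom, bins$start)        # stable
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  # non-overlap within chromosome
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop(sprintf("overlapping bins on %s in sample '%s'", ch, sample_id),
           call. = FALSE)
  }
  structure(list(sample_id = sample_id, bins = bins), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile '%s': %d bins on %d chromosome(s)\n",
              x$sample_id, nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Classify log2 ratios into gain / loss / neutral
#'
#' Gain iff value >= `gain_log2`, loss iff value <= `loss_log2` (both
#' inclusive), else neutral.
#'
#' @param value Numeric vector of log2 ratios (finite).
#' @param thresholds A [cn_thresholds()] object.
#' @return Character vector in {"gain","loss","neutral"}.
#' @export
classify_log2 <- function(value, thresholds = cn_thresholds()) {
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("log2 ratios must be finite numbers", call. = FALSE)
  out <- rep("neutral", length(value))
  out[value >= thresholds$gain_log2] <- "gain"
  out[value <= thresholds$loss_log2] <- "loss"
  out
}

# bins whose midpoint falls inside region
.region_bins <- function(profile, region) {
  b <- profile$bins
  mid <- (b$start + b$end) / 2
  b[b$chrom == region$chrom & mid >= region$start & mid < region$end, ,
    drop = FALSE]
}

#' Median log2 ratio over a genomic region
#'
#' Median of the per-bin log2 ratios of all bins whose midpoint lies in the
#' region; unweighted by bin length (bins are equal-width in shallow-WGS
#' practice). Even counts use the usual mean-of-middle-two convention.
#'
#' @param profile A [cn_profile()].
#' @param region A [genomic_region()].
#' @return Median log2 ratio (scalar).
#' @export
region_median <- function(profile, region) {
  b <- .region_bins(profile, region)
  if (nrow(b) == 0L)
    stop(sprintf("no bin of sample '%s' overlaps %s:%g-%g",
                 profile$sample_id, region$chrom, region$start, region$end),
         call. = FALSE)
  stats::median(b$log2_ratio)
}

#' 17q balance-value classification
#'
#' Computes the balance value bv = -median(IMP1-ter) + median(17p) + offset,
#' where 17p is the whole short arm of chromosome 17 and IMP1-ter the
#' segment from the IGF2BP1 locus to the q terminus. A sample is called
#' unbalanced iff bv <= 0 (the boundary bv = 0 is unbalanced).
#'
#' @param profile A [cn_profile()].
#' @param regions List with elements `p17` and `imp1_ter`, each a
#'   [genomic_region()].
#' @param thresholds A [cn_thresholds()]; supplies `balance_offset`.
#' @return A one-row data.frame: sample_id, median_17p, median_imp1_ter,
#'   bv, label ("balanced"/"unbalanced").
#' @export
balance_call <- function(profile, regions, thresholds = cn_thresholds()) {
  stopifnot(all(c("p17", "imp1_ter") %in% names(regions)))
  m_p <- region_median(profile, regions$p17)
  m_q <- region_median(profile, regions$imp1_ter)
  bv <- -m_q + m_p + thresholds$balance_offset
  data.frame(sample_id = profile$sample_id,
             median_17p = m_p, median_imp1_ter = m_q, bv = bv,
             label = if (bv <= 0) "unbalanced" else "balanced",
             stringsAsFactors = FALSE)
}

#' MYCN amplification call
#'
#' Copy number at the MYCN locus is the median `cn` of the bins overlapping
#' the locus region (derived as `2 * 2^log2_ratio` when no integer `cn`
#' column is present); amplified iff strictly greater than `mna_cn`.
#'
#' @param profile A [cn_profile()].
#' @param mycn_region [genomic_region()] of the MYCN locus.
#' @param thresholds A [cn_thresholds()].
#' @return List with `mna` (logical) and `cn_at_locus`.
#' @export
mna_call <- function(profile, mycn_region, thresholds = cn_thresholds()) {
  b <- .region_bins(profile, mycn_region)
  if (nrow(b) == 0L)
    stop(sprintf("MYCN region not covered in sample '%s'", profile$sample_id),
         call. = FALSE)
  cn <- if ("cn" %in% names(b) && !all(is.na(b$cn))) b$cn else 2 * 2^b$log2_ratio
  cn_locus <- stats::median(cn, na.rm = TRUE)
  list(mna = cn_locus > thresholds$mna_cn, cn_at_locus = cn_locus)
}

#' Region-level gain/loss state
#'
#' A region is called gained (lost) in a sample iff its median log2 ratio
#' crosses the gain (loss) threshold; used for cohort frequency summaries
#' of named regions such as "17q gain" or "11q loss".
#'
#' @inheritParams region_median
#' @param thresholds A [cn_thresholds()].
#' @return One of "gain", "loss", "neutral".
#' @export
region_call <- function(profile, region, thresholds = cn_thresholds()) {
  classify_log2(region_median(profile, region), thresholds)
}

#' Per-bin cohort aberration frequencies
#'
#' For a cohort of profiles sharing one bin grid, the percentage of samples
#' called gained and lost in every bin.
#'
#' @param profiles List of [cn_profile()] objects on an identical bin grid.
#' @param thresholds A [cn_thresholds()].
#' @return data.frame with chrom, start, end, gain_pct, loss_pct.
#' @export
cohort_aberration_frequencies <- function(profiles, thresholds = cn_thresholds()) {
  stopifnot(length(profiles) >= 1L)
  grid <- profiles[[1L]]$bins[, c("chrom", "start", "end")]
  for (p in profiles[-1L]) {
    g <- p$bins[, c("chrom", "start", "end")]
    if (nrow(g) != nrow(grid)) {
      stop(sprintf("bin grid of sample '%s' has %d bins, cohort grid has %d",
                   p$sample_id, nrow(g), nrow(grid)), call. = FALSE)
    }
    same <- g$chrom == grid$chrom & g$start == grid$start & g$end == grid$end
    if (!all(same)) {
      stop(sprintf("bin grid of sample '%s' differs from the cohort grid (first offending bin %d)",
                   p$sample_id, which(!same)[1L]), call. = FALSE)
    }
  }
  states <- vapply(profiles, function(p) classify_log2(p$bins$log2_ratio, thresholds),
                   character(nrow(grid)))
  if (is.null(dim(states))) states <- matrix(states, nrow = nrow(grid))
  n <- length(profiles)
  data.frame(grid,
             gain_pct = 100 * rowSums(states == "gain") / n,
             loss_pct = 100 * rowSums(states == "loss") / n)
}

#' Per-sample copy-number classification of a cohort
#'
#' Convenience wrapper applying [balance_call()] and [mna_call()] to every
#' profile.
#'
#' @param profiles List of [cn_profile()] objects.
#' @param regions List with `p17`, `imp1_ter` and `mycn` regions.
#' @param thresholds A [cn_thresholds()].
#' @return data.frame, one row per sample: sample_id, median_17p,
#'   median_imp1_ter, bv, label, mna, cn_mycn.
#' @export
classify_cohort <- function(profiles, regions, thresholds = cn_thresholds()) {
  rows <- lapply(profiles, function(p) {
    bc <- balance_call(p, regions, thresholds)
    mc <- mna_call(p, regions$mycn, thresholds)
    cbind(bc, mna = mc$mna, cn_mycn = mc$cn_at_locus)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
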