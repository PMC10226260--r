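test_that("log2 state calls respect the inclusive gain/loss thresholds", {
  thr <- cn_thresholds()
  expect_equal(classify_log2(c(0.35, -0.5, 0, 0.3, -0.4, 0.29, -0.39), thr),
               c("gain", "loss", "neutral", "gain", "loss", "neutral", "neutral"))
  expect_error(classify_log2(NaN, thr), "finite")
  expect_error(cn_thresholds(loss_log2 = 0.1), "loss_log2")
})

test_that("region median is the unweighted median of overlapping bins", {
  p <- make_profile(list(chr1 = c(0, 0, 1, 0.7, 0.1, 0.3)))
  expect_equal(region_median(p, genomic_region("chr1", 0, 30)), 0)
  expect_equal(region_median(p, genomic_region("chr1", 30, 40)), 0.7)
  expect_equal(region_median(p, genomic_region("chr1", 40, 60)), 0.2)
  expect_error(region_median(p, genomic_region("chr2", 0, 30)), "no bin")
})

test_that("balance value formula and boundary rule classify as specified", {
  thr <- cn_thresholds()
  # medians (17p, imp1_ter): (0, 0) -> bv 0.2 balanced
  b1 <- balance_call(make_profile17(0, 0, 0), toy17_regions, thr)
  expect_equal(b1$bv, 0.2)
  expect_equal(b1$label, "balanced")
  # (0, 0.5) -> bv -0.3 unbalanced
  b2 <- balance_call(make_profile17(0, 0, 0.5), toy17_regions, thr)
  expect_equal(b2$bv, -0.3)
  expect_equal(b2$label, "unbalanced")
  # boundary (0, 0.2) -> bv 0 is unbalanced
  b3 <- balance_call(make_profile17(0, 0, 0.2), toy17_regions, thr)
  expect_equal(b3$bv, 0)
  expect_equal(b3$label, "unbalanced")
})

test_that("balance value shifts by -delta under a q-only gain and is invariant to whole-chromosome shifts", {
  thr <- cn_thresholds()
  base <- balance_call(make_profile17(0.1, 0, 0.3), toy17_regions, thr)
  both <- balance_call(make_profile17(0.1 + 0.25, 0, 0.3 + 0.25), toy17_regions, thr)
  expect_equal(both$bv, base$bv)
  qonly <- balance_call(make_profile17(0.1, 0, 0.3 + 0.25), toy17_regions, thr)
  expect_equal(qonly$bv, base$bv - 0.25)
})

test_that("MYCN amplification requires copy number strictly above 4", {
  reg <- genomic_region("chr2", 0, 30)
  mk <- function(cn) make_profile(list(chr2 = log2(rep(cn, 3) / 2)),
                                  cn_by_chrom = list(chr2 = rep(cn, 3)))
  expect_true(mna_call(mk(5), reg)$mna)
  expect_false(mna_call(mk(4), reg)$mna)
  expect_false(mna_call(mk(2), reg)$mna)
  # cn derived from log2 when no cn column
  p <- make_profile(list(chr2 = rep(log2(8 / 2), 3)))
  mc <- mna_call(p, reg)
  expect_true(mc$mna)
  expect_equal(mc$cn_at_locus, 8)
  expect_error(mna_call(mk(5), genomic_region("chrX", 0, 10)), "not covered")
})

test_that("raising all log2 ratios never demotes a gain call", {
  set.seed(11)
  v <- rnorm(60, 0, 0.4)
  before <- classify_log2(v)
  after <- classify_log2(v + 0.15)
  expect_true(all(after[before == "gain"] == "gain"))
})

test_that("cohort aberration frequencies count per-bin calls on a shared grid", {
  mk <- function(id, gain) make_profile(list(chr1 = c(if (gain) 0.6 else 0, 0)),
                                        sample_id = id)
  profs <- lapply(1:10, function(i) mk(paste0("S", i), i <= 7))
  fr <- cohort_aberration_frequencies(profs)
  expect_equal(fr$gain_pct, c(70, 0))
  expect_equal(fr$loss_pct, c(0, 0))
  flat <- lapply(1:4, function(i) make_profile(list(chr1 = c(0, 0)),
                                               sample_id = paste0("F", i)))
  fr0 <- cohort_aberration_frequencies(flat)
  expect_true(all(fr0$gain_pct == 0) && all(fr0$loss_pct == 0))
  # mismatched grid rejected with the offending sample named
  bad <- make_profile(list(chr1 = c(0, 0, 0)), sample_id = "BAD")
  expect_error(cohort_aberration_frequencies(c(profs, list(bad))), "BAD")
})

test_that("profile construction enforces sorted non-overlapping finite bins", {
  expect_error(cn_profile("x", data.frame(chrom = "chr1", start = 0, end = 10,
                                          log2_ratio = Inf)), "finite")
  expect_error(cn_profile("x", data.frame(chrom = "chr1", start = c(0, 5),
                                          end = c(10, 15),
                                          log2_ratio = c(0, 0))), "overlap")
  p <- cn_profile("x", data.frame(chrom = "chr1", start = c(20, 0),
                                  end = c(30, 10), log2_ratio = c(1, 2)))
  expect_equal(p$bins$start, c(0, 20))
})
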