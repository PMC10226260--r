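# Small in-code fixtures shared across test files.

# a profile on one or more chromosomes from per-bin log2 ratios
make_profile <- function(log2_by_chrom, sample_id = "S1", bin_width = 10,
                         cn_by_chrom = NULL) {
  bins <- do.call(rbind, lapply(names(log2_by_chrom), function(ch) {
    v <- log2_by_chrom[[ch]]
    data.frame(chrom = ch,
               start = seq(0, by = bin_width, length.out = length(v)),
               end = seq(bin_width, by = bin_width, length.out = length(v)),
               log2_ratio = v, stringsAsFactors = FALSE)
  }))
  if (!is.null(cn_by_chrom)) bins$cn <- unlist(cn_by_chrom, use.names = FALSE)
  cn_profile(sample_id, bins)
}

# chr17 toy: 5 bins of 17p (0-50), 5 bins centromere-proximal q, 5 bins
# IGF2BP1..ter (100-150); regions to match
toy17_regions <- list(p17 = genomic_region("chr17", 0, 50),
                      imp1_ter = genomic_region("chr17", 100, 150))

make_profile17 <- function(p_val, mid_val, q_val, sample_id = "S1") {
  make_profile(list(chr17 = c(rep(p_val, 5), rep(mid_val, 5), rep(q_val, 5))),
               sample_id = sample_id)
}
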