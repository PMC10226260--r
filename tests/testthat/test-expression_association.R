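test_that("Spearman correlation handles monotone maps, reversals and ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x^2), 1)
  expect_equal(spearman_cor(x, rev(x)), -1)
  # tie-corrected: Pearson on average ranks
  xt <- c(1, 2, 2, 4); yt <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(xt, yt), cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  expect_warning(r <- spearman_cor(rep(1, 4), 1:4), "constant")
  expect_true(is.na(r))
  expect_error(spearman_cor(1:2, 1:2), "length >= 3")
})

test_that("rank correlations are invariant to strictly monotone transforms", {
  set.seed(31)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(spearman_cor(x, y), spearman_cor(exp(x), exp(y)))
})

test_that("correlation of correlations is 1 for identical anchors and symmetric", {
  set.seed(32)
  expr <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:20)))
  expect_equal(correlation_of_correlations(expr, "g1", "g1")$rho, 1)
  ab <- correlation_of_correlations(expr, "g1", "g2")
  ba <- correlation_of_correlations(expr, "g2", "g1")
  expect_equal(ab$rho, ba$rho)
  expect_true(all(abs(ab$profiles$r_anchor) <= 1))
  expect_error(correlation_of_correlations(expr, "missing", "g2"), "anchor")
})

test_that("independent noise gives near-zero signature similarity; shared drivers raise it", {
  set.seed(33)
  expr <- matrix(rnorm(500 * 40), 500, 40,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:40)))
  expect_lt(abs(correlation_of_correlations(expr, "g1", "g2")$rho), 0.15)
  # co-regulated anchors within a synthetic driver module correlate strongly
  sim <- simulate_cohort(sim_config(seed = 34, n_samples = 60, n_genes = 200,
                                    driver_corr = 0.8))
  cc <- correlation_of_correlations(sim$expr, "IGF2BP1", "MYCN")
  expect_gt(cc$rho, 0.5)
})

test_that("knockdown concordance works on the shared gene universe", {
  a <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  b <- setNames(c(5, 4, 3, 2, 1, 9), paste0("g", c(1:5, 9)))
  expect_equal(knockdown_concordance(a, a)$rho, 1)
  r <- knockdown_concordance(a, b)
  expect_equal(r$rho, -1)
  expect_equal(r$n, 5)
  expect_error(knockdown_concordance(a, setNames(1:2, c("g1", "g2"))),
               "shared genes")
  # rho grows with the shared latent-effect share
  set.seed(35)
  lat <- rnorm(200)
  rho_at <- sapply(c(0.2, 0.6, 0.9), function(w) {
    fa <- setNames(w * lat + (1 - w) * rnorm(200), paste0("g", 1:200))
    fb <- setNames(w * lat + (1 - w) * rnorm(200), paste0("g", 1:200))
    knockdown_concordance(fa, fb)$rho
  })
  expect_true(all(diff(rho_at) > 0))
})

test_that("signature scores separate planted expression programs", {
  set.seed(36)
  a_genes <- paste0("A", 1:10); b_genes <- paste0("B", 1:10)
  expr <- matrix(rnorm(20 * 50), 20, 50,
                 dimnames = list(c(a_genes, b_genes), paste0("s", 1:50)))
  attr(expr, "scale") <- "log2TPM"
  expect_equal(unname(signature_score_ratio(expr, a_genes, a_genes)),
               rep(0, 50))
  # one sample uniformly elevated in set A scores highest
  expr2 <- expr; expr2[a_genes, 1] <- expr2[a_genes, 1] + 2 * 2
  sc <- signature_score_ratio(expr2, a_genes, b_genes)
  expect_equal(unname(which.max(sc)), 1L)
  # two planted clusters (effect 1.5 SD) separate without overlap
  cl <- rep(c(1, -1), each = 25)
  expr3 <- expr
  expr3[a_genes, ] <- expr3[a_genes, ] + 1.5 * rep(cl, each = 10)
  expr3[b_genes, ] <- expr3[b_genes, ] - 1.5 * rep(cl, each = 10)
  sc3 <- signature_score_ratio(expr3, a_genes, b_genes)
  expect_gt(min(sc3[cl == 1]), max(sc3[cl == -1]))
  expect_error(signature_score_ratio(expr, c("nope"), b_genes), "set_a")
})

test_that("E-box scanning finds canonical and overlapping motifs, 0-based", {
  expect_equal(ebox_scan("CACGTG"), 0L)
  expect_equal(ebox_scan("AAAAAA"), integer())
  expect_equal(ebox_scan("cacgtg"), 0L)                  # case-insensitive
  expect_equal(ebox_scan("TTCAGCTGTT"), 2L)
  expect_equal(ebox_scan("CACATGCACGTG"), c(0L, 6L))
  expect_equal(ebox_scan("CACGCATGTG"), 4L)
  expect_equal(ebox_scan("CACGTGCACGTGCACGTG"), c(0L, 6L, 12L))
  # ambiguous N never satisfies the motif
  expect_equal(ebox_scan("CANNTG"), integer())
  expect_error(ebox_scan("CAXGTG"), "offset 2")
})

test_that("E-box counts on random sequence match the 1/256 expectation", {
  set.seed(37)
  L <- 100000
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  n_hits <- length(ebox_scan(s))
  lambda <- (L - 5) / 256
  expect_lt(abs(n_hits - lambda), 4 * sqrt(lambda))
})

test_that("E-box positions mirror under reverse complement", {
  set.seed(38)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- ebox_scan(s)
  rev <- ebox_scan(rc)
  expect_equal(sort((2000 - 6) - rev), fwd)
})
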