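# small hand-built screen: 13 context lines vs 20 others
make_screen <- function(dep, expr = NULL, common = character()) {
  nA <- 13L; nB <- 20L
  group <- c(rep("MNA", nA), rep("other", nB))
  if (is.null(expr)) {
    expr <- matrix(3, nrow(dep), nA + nB, dimnames = dimnames(dep))
  }
  dependency_screen(dep, expr, group, common)
}

test_that("expression filter realizes the at-least-11-of-13 rule", {
  dep <- matrix(0, 3, 33, dimnames = list(c("g12", "g10", "gEq"), NULL))
  colnames(dep) <- paste0("L", 1:33)
  expr <- dep
  expr["g12", 1:12] <- 3     # 12 of 13 context lines above threshold
  expr["g10", 1:10] <- 3     # only 10 of 13
  expr["gEq", 1:13] <- 2     # exactly 2.0 everywhere: strict > fails
  scr <- make_screen(dep, expr)
  kept <- filter_expression(scr)
  expect_true("g12" %in% kept)
  expect_false("g10" %in% kept)
  expect_false("gEq" %in% kept)
  # generalized fraction rule: f = 0.85 of 13 context lines is 11
  expect_equal(floor(screen_params()$expr_min_fraction * 13), 11)
  # a gene in exactly 11 of 13 is the boundary and is kept
  expr["g10", 1:11] <- 3
  kept11 <- filter_expression(make_screen(dep, expr))
  expect_true("g10" %in% kept11)
})

test_that("dependency filter demands selective essentiality in the context group", {
  dep <- matrix(0, 3, 33, dimnames = list(c("keep", "shallow", "both"), paste0("L", 1:33)))
  dep["keep", 1:13] <- -0.5;   dep["keep", 14:33] <- -0.1
  dep["shallow", 1:13] <- -0.1; dep["shallow", 14:33] <- -0.1
  dep["both", 1:13] <- -0.25;  dep["both", 14:33] <- -0.35
  scr <- make_screen(dep)
  kept <- filter_dependency(scr)
  expect_equal(kept, "keep")
})

test_that("common-essential exclusion is a plain set difference", {
  expect_equal(exclude_common_essential(c("A", "B", "C"), "B"), c("A", "C"))
  expect_equal(exclude_common_essential(c("A", "B"), c("X", "Y")), c("A", "B"))
  expect_equal(exclude_common_essential(c("A", "B"), c("A", "B")), character())
})

test_that("moderated t is zero with p one for identical group means", {
  set.seed(1)
  dep <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(paste0("g", 1:50), NULL))
  dep[1, ] <- rep(c(-1, 1), 10)                   # equal means by construction
  group <- rep(c("MNA", "other"), each = 10)
  dep[1, group == "other"] <- dep[1, group == "MNA"]
  tt <- moderated_t_test(dep, group, context = "MNA")
  expect_equal(tt$t_mod[1], 0)
  expect_equal(tt$p[1], 1)
})

test_that("equal per-gene variances collapse shrinkage to the ordinary t", {
  # with no spread in the s_g^2 the prior degenerates (d0 infinite) and the
  # shrunken variance equals the common variance, so t_mod is exactly the
  # ordinary pooled t; the established empirical-Bayes fitter agrees
  base <- c(-1.5, -0.5, 0.5, 1.5)                 # fixed within-group pattern
  dep <- t(sapply(1:30, function(g) c(base + g / 10, base - g / 10)))
  rownames(dep) <- paste0("g", 1:30)
  group <- rep(c("MNA", "other"), each = 4)
  tt <- moderated_t_test(dep, group, context = "MNA")
  expect_equal(attr(tt, "d0"), Inf)
  ordinary <- apply(dep, 1, function(x)
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic)
  expect_equal(tt$t_mod, unname(ordinary), tolerance = 1e-10)
  design <- cbind(1, as.integer(group == "MNA"))
  fit <- limma::eBayes(limma::lmFit(dep, design))
  expect_equal(tt$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
})

test_that("the variance prior is recovered from data generated under it", {
  set.seed(202)
  d0 <- 4; s02 <- 0.04; d <- 18; m <- 200
  sigma2 <- d0 * s02 / rchisq(m, d0)              # scaled inverse chi-square
  s2 <- sigma2 * rchisq(m, d) / d
  # build a matrix whose pooled variances are exactly s2
  n1 <- n2 <- 10
  patt <- scale(rnorm(n1), center = TRUE, scale = FALSE)
  patt <- patt / sqrt(sum(patt^2))
  dep <- t(sapply(seq_len(m), function(g)
    c(patt * sqrt(s2[g] * d / 2), patt * sqrt(s2[g] * d / 2))))
  rownames(dep) <- paste0("g", seq_len(m))
  tt <- moderated_t_test(dep, rep(c("MNA", "other"), each = 10))
  expect_lt(abs(attr(tt, "d0") - d0) / d0, 0.25)
  expect_lt(abs(attr(tt, "s02") - s02) / s02, 0.25)
})

test_that("moderated t matches the brute-force oracle and limma", {
  set.seed(77)
  dep <- matrix(rnorm(300 * 18, sd = rep(runif(300, 0.5, 2), 18)), 300, 18,
                dimnames = list(paste0("g", 1:300), NULL))
  group <- rep(c("MNA", "other"), c(8, 10))
  tt <- moderated_t_test(dep, group, context = "MNA")
  orc <- oracle_moderated_t(dep, group, context = "MNA")
  expect_equal(tt$t_mod, orc$t, tolerance = 1e-8)
  expect_equal(tt$p, orc$p, tolerance = 1e-8)
  # independent cross-check against the established empirical-Bayes fitter
  design <- cbind(1, as.integer(group == "MNA"))
  fit <- limma::eBayes(limma::lmFit(dep, design))
  expect_equal(tt$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(attr(tt, "d0"), unname(fit$df.prior), tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(100)
  adj <- bh_fdr(p)
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted common essentials with strong effects in both groups are never hits", {
  cfg <- sim_config(seed = 21, n_genes = 400, n_cell_lines_group_b = 60,
                    n_planted_essential = 20, n_common_essential = 15)
  scr <- simulate_dependency_screen(cfg)
  res <- run_screen(scr$screen)
  expect_equal(sum(res$hit[res$gene %in% scr$truth$common_essential]), 0)
  expect_true(all(res$excluded_common[res$gene %in% scr$truth$common_essential]))
})

test_that("the filter cascade is order-insensitive in its final gene set", {
  cfg <- sim_config(seed = 22, n_genes = 300, n_cell_lines_group_b = 40)
  scr <- simulate_dependency_screen(cfg)$screen
  params <- screen_params()
  genes <- rownames(scr$dep)
  a <- exclude_common_essential(
    filter_dependency(scr, params, filter_expression(scr, params, genes)),
    scr$common_essential)
  b <- filter_expression(scr, params,
    exclude_common_essential(filter_dependency(scr, params, genes),
                             scr$common_essential))
  expect_setequal(a, b)
})

test_that("an empty candidate set yields a warning, not an error", {
  dep <- matrix(0, 4, 33, dimnames = list(paste0("g", 1:4), paste0("L", 1:33)))
  scr <- make_screen(dep, expr = dep)       # nothing expressed
  expect_warning(res <- run_screen(scr), "no gene survives")
  expect_equal(sum(res$hit), 0)
  expect_true(all(is.na(res$p)))
})

test_that("degenerate inputs raise the documented errors", {
  dep <- matrix(0, 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(moderated_t_test(dep, rep(c("MNA", "other"), each = 3)),
               "degenerate")
  one <- matrix(rnorm(6), 1, 6, dimnames = list("g1", NULL))
  expect_warning(moderated_t_test(one, rep(c("MNA", "other"), each = 3)),
                 "single gene")
  expect_error(moderated_t_test(matrix(rnorm(8), 2, 4,
                                       dimnames = list(c("a", "b"), NULL)),
                                c("MNA", "other", "other", "other")),
               "2 lines per group")
})
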