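## Seeded synthetic-cohort and dependency-screen generators with known
## ground truth, so that every downstream stage is testable without
## external data. Defaults emulate the study conditions: ~100 tumors, 79%
## 17q gain of which 35% unbalanced, 17% MYCN-amplified, and a dependency
## screen of 13 MYCN-amplified lines against 607 others.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: 100 tumors with 17q gain
#' prevalence 0.79, unbalanced-17q prevalence 0.35 and MYCN-amplification
#' prevalence 0.17; shallow-WGS-like log2-ratio noise of sd 0.1; a
#' dependency screen of 13 vs 607 cell lines with 40 planted
#' context-essential genes at effect -0.5 and score noise sd 0.15; a
#' co-expressed driver module targeting pairwise correlation 0.8; and
#' survival with hazard ratio 5 for high-risk (MNA or unbalanced) samples
#' at 30% censoring.
#'
#' @param seed Master seed; every component derives a named sub-seed from
#'   it, so outputs are byte-identical under a fixed seed.
#' @param n_samples Number of tumors.
#' @param n_bins_per_chrom Copy-number bins per chromosome.
#' @param chrom_lengths Named vector of chromosome lengths (bp); must
#'   include "chr2" (MYCN) and "chr17".
#' @param prevalence_17q_gain,prevalence_unbalanced,prevalence_mna Event
#'   prevalences in [0,1]; unbalanced samples are a subset of 17q-gained
#'   ones, so `prevalence_unbalanced <= prevalence_17q_gain`.
#' @param cn_noise_sd Gaussian sd of per-bin log2 ratios.
#' @param n_genes Genes in the annotation / expression matrix and in the
#'   dependency screen.
#' @param n_cell_lines_group_a,n_cell_lines_group_b Cell lines in the
#'   context (MNA) and comparison groups.
#' @param n_planted_essential Context-essential genes planted in group A.
#' @param dependency_effect Mean dependency-score shift of planted genes in
#'   group A (negative = essential).
#' @param dependency_noise_sd Dependency-score noise sd.
#' @param driver_corr Target pairwise co-expression correlation of the
#'   driver module (latent-factor construction).
#' @param hazard_ratio_highrisk Hazard multiplier for MNA-or-unbalanced
#'   samples.
#' @param censor_rate Fraction of samples censored.
#' @param unexpressed_fraction Fraction of screen genes with near-zero
#'   expression (exercises the expression filter).
#' @param n_common_essential Pan-lineage essential genes planted with
#'   strong negative scores in both groups.
#' @param n_driver_module Genes co-regulated with the two driver anchors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 100L,
                       n_bins_per_chrom = 50L,
                       chrom_lengths = c(chr1 = 2.0e8, chr2 = 2.4e8, chr17 = 8.3e7),
                       prevalence_17q_gain = 0.79,
                       prevalence_unbalanced = 0.35,
                       prevalence_mna = 0.17,
                       cn_noise_sd = 0.1,
                       n_genes = 500L,
                       n_cell_lines_group_a = 13L,
                       n_cell_lines_group_b = 607L,
                       n_planted_essential = 40L,
                       dependency_effect = -0.5,
                       dependency_noise_sd = 0.15,
                       driver_corr = 0.8,
                       hazard_ratio_highrisk = 5,
                       censor_rate = 0.3,
                       unexpressed_fraction = 0.1,
                       n_common_essential = 30L,
                       n_driver_module = 30L) {
  cfg <- list(
    seed = .check_count(seed, "seed", min = 0L),
    n_samples = .check_count(n_samples, "n_samples"),
    n_bins_per_chrom = .check_count(n_bins_per_chrom, "n_bins_per_chrom", min = 4L),
    chrom_lengths = chrom_lengths,
    prevalence_17q_gain = .check_fraction(prevalence_17q_gain, "prevalence_17q_gain"),
    prevalence_unbalanced = .check_fraction(prevalence_unbalanced, "prevalence_unbalanced"),
    prevalence_mna = .check_fraction(prevalence_mna, "prevalence_mna"),
    cn_noise_sd = cn_noise_sd,
    n_genes = .check_count(n_genes, "n_genes", min = 4L),
    n_cell_lines_group_a = .check_count(n_cell_lines_group_a, "n_cell_lines_group_a", min = 2L),
    n_cell_lines_group_b = .check_count(n_cell_lines_group_b, "n_cell_lines_group_b", min = 2L),
    n_planted_essential = .check_count(n_planted_essential, "n_planted_essential", min = 0L),
    dependency_effect = dependency_effect,
    dependency_noise_sd = dependency_noise_sd,
    driver_corr = driver_corr,
    hazard_ratio_highrisk = hazard_ratio_highrisk,
    censor_rate = .check_fraction(censor_rate, "censor_rate"),
    unexpressed_fraction = .check_fraction(unexpressed_fraction, "unexpressed_fraction"),
    n_common_essential = .check_count(n_common_essential, "n_common_essential", min = 0L),
    n_driver_module = .check_count(n_driver_module, "n_driver_module", min = 0L))
  if (is.null(names(cfg$chrom_lengths)) ||
      !all(c("chr2", "chr17") %in% names(cfg$chrom_lengths)))
    stop("chrom_lengths must be named and include chr2 and chr17", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (cfg$prevalence_unbalanced > cfg$prevalence_17q_gain)
    stop("prevalence_unbalanced cannot exceed prevalence_17q_gain", call. = FALSE)
  if (abs(cfg$driver_corr) > 1) stop("driver_corr must be in [-1, 1]", call. = FALSE)
  if (cfg$hazard_ratio_highrisk <= 0) stop("hazard_ratio_highrisk must be positive", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Genome landmarks of the simulated genome
#'
#' Fixed proportional positions matching the human loci: the chr17
#' centromere at 0.30 of the chromosome, the IGF2BP1 locus at 0.58 of
#' chr17, and the MYCN locus at 0.066 of chr2.
#'
#' @param config A [sim_config()].
#' @return List of [genomic_region()]s: `p17` (whole 17p), `imp1_ter`
#'   (IGF2BP1 to 17q terminus), `mycn` (MYCN locus window), plus scalar
#'   positions `centromere_17`, `igf2bp1_start`, `mycn_start`.
#' @export
genome_landmarks <- function(config) {
  len17 <- unname(config$chrom_lengths[["chr17"]])
  len2 <- unname(config$chrom_lengths[["chr2"]])
  cen <- round(0.30 * len17)
  igf <- round(0.58 * len17)
  myc <- round(0.066 * len2)
  half <- max(1, round(len2 / config$n_bins_per_chrom / 4))
  list(p17 = genomic_region("chr17", 0, cen),
       imp1_ter = genomic_region("chr17", igf, len17),
       mycn = genomic_region("chr2", myc - half, myc + half),
       centromere_17 = cen, igf2bp1_start = igf, mycn_start = myc)
}

# equal-width bin grid for one genome
.bin_grid <- function(config) {
  do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    edges <- round(seq(0, len, length.out = config$n_bins_per_chrom + 1L))
    data.frame(chrom = ch, start = edges[-length(edges)], end = edges[-1L],
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a tumor cohort with planted 17q and MYCN events
#'
#' Copy-number bins are drawn as log2 ratio ~ Normal(event mean,
#' `cn_noise_sd`): +log2(3/2) (one extra copy) on gained regions, 0
#' elsewhere. Unbalanced samples gain only the IGF2BP1-to-terminus segment
#' of chr17; the remaining 17q-gained samples gain all of chr17 (balanced
#' gain). MYCN-amplified samples carry integer CN 8 at the MYCN locus bin.
#' Expression for the two driver anchors (IGF2BP1, MYCN) and a driver
#' module is drawn from a shared latent factor achieving pairwise
#' correlation ~ `driver_corr`. Survival is exponential with the hazard
#' multiplied by `hazard_ratio_highrisk` for MNA-or-unbalanced samples; a
#' `censor_rate` fraction of samples is censored at a uniform fraction of
#' its event time.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (gene_annotation), `profiles` (list of
#'   [cn_profile()]), `expr` (genes x samples log2TPM matrix), `meta`
#'   (cohort metadata data.frame), `truth` (per-sample ground-truth labels
#'   and the driver-module gene set).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .sub_seeds(config$seed, c("labels", "genes", "cn", "expr", "surv",
                                     "dep_plant", "dep"))
  lm <- genome_landmarks(config)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  ## ground-truth labels
  set.seed(seeds[["labels"]])
  unbal <- stats::runif(n) < config$prevalence_unbalanced
  p_extra <- if (config$prevalence_unbalanced < 1)
    (config$prevalence_17q_gain - config$prevalence_unbalanced) /
      (1 - config$prevalence_unbalanced) else 0
  full_gain <- !unbal & stats::runif(n) < p_extra
  mna <- stats::runif(n) < config$prevalence_mna
  highrisk <- mna | unbal

  ## gene annotation: two anchored drivers plus uniformly placed genes
  set.seed(seeds[["genes"]])
  n_other <- config$n_genes - 2L
  chroms <- names(config$chrom_lengths)
  probs <- config$chrom_lengths / sum(config$chrom_lengths)
  g_chrom <- sample(chroms, n_other, replace = TRUE, prob = probs)
  g_start <- floor(stats::runif(n_other) * (config$chrom_lengths[g_chrom] - 6e4))
  ann <- data.frame(
    gene_id = c("IGF2BP1", "MYCN", sprintf("GENE%04d", seq_len(n_other))),
    symbol = c("IGF2BP1", "MYCN", sprintf("GENE%04d", seq_len(n_other))),
    chromosome = c("chr17", "chr2", g_chrom),
    start = c(lm$igf2bp1_start, lm$mycn_start, g_start),
    end = c(lm$igf2bp1_start + 6e4, lm$mycn_start + 6e4, g_start + 6e4),
    strand = ".", biotype = "protein_coding", stringsAsFactors = FALSE)
  cent <- data.frame(chromosome = chroms,
                     position = round(0.4 * unname(config$chrom_lengths)))
  cent$position[cent$chromosome == "chr17"] <- lm$centromere_17
  ann$arm <- .assign_arm(ann$chromosome, ann$start, cent)
  ann <- .validate_annotation(ann)

  ## copy-number profiles on a shared grid
  set.seed(seeds[["cn"]])
  grid <- .bin_grid(config)
  mid <- (grid$start + grid$end) / 2
  on17 <- grid$chrom == "chr17"
  on17q_imp <- on17 & mid >= lm$igf2bp1_start
  mycn_bin <- grid$chrom == "chr2" & mid >= lm$mycn$start & mid < lm$mycn$end
  profiles <- lapply(seq_len(n), function(i) {
    cn_true <- rep(2, nrow(grid))
    if (full_gain[i]) cn_true[on17] <- 3
    if (unbal[i]) cn_true[on17q_imp] <- 3
    if (mna[i]) cn_true[mycn_bin] <- 8
    l2 <- log2(cn_true / 2) + stats::rnorm(nrow(grid), 0, config$cn_noise_sd)
    cn_profile(sample_ids[i], data.frame(grid, log2_ratio = l2, cn = cn_true))
  })
  names(profiles) <- sample_ids

  ## expression: latent-factor driver module anchored on IGF2BP1 and MYCN
  set.seed(seeds[["expr"]])
  module <- c("IGF2BP1", "MYCN",
              ann$gene_id[-(1:2)][seq_len(min(config$n_driver_module, n_other))])
  mu <- stats::rnorm(config$n_genes, 4, 1)
  f <- stats::rnorm(n)
  rho <- config$driver_corr
  expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                 dimnames = list(ann$gene_id, sample_ids))
  in_mod <- ann$gene_id %in% module
  expr[in_mod, ] <- sqrt(abs(rho)) * sign(rho) *
    matrix(f, sum(in_mod), n, byrow = TRUE) +
    sqrt(1 - abs(rho)) * expr[in_mod, ]
  expr <- expr + mu
  attr(expr, "scale") <- "log2TPM"

  ## survival: exponential, baseline median 5 years, HR for high risk
  set.seed(seeds[["surv"]])
  lambda0 <- log(2) / 1825
  tt <- stats::rexp(n, rate = lambda0 * ifelse(highrisk, config$hazard_ratio_highrisk, 1))
  cens <- stats::runif(n) < config$censor_rate
  os_time <- ifelse(cens, stats::runif(n) * tt, tt)
  meta <- data.frame(
    sample_id = sample_ids,
    inss_stage = ifelse(highrisk, "4", sample(c("1", "2", "3", "4S"), n, TRUE)),
    mna_status = as.integer(mna),
    balance_17q = ifelse(unbal, "unbalanced", "balanced"),
    os_time = os_time, os_event = as.integer(!cens),
    stringsAsFactors = FALSE)

  truth <- list(
    samples = data.frame(
      sample_id = sample_ids,
      seg17 = ifelse(unbal, "q_gain", ifelse(full_gain, "full_gain", "none")),
      balance_label = ifelse(unbal, "unbalanced", "balanced"),
      mna = mna,
      risk_group = ifelse(highrisk, "high", "low"),
      stringsAsFactors = FALSE),
    driver_module = module)

  list(annotation = ann, profiles = profiles, expr = expr, meta = meta,
       truth = truth)
}

#' Dependency screen container
#'
#' @param dep Gene x cell-line matrix of dependency scores (more negative =
#'   more essential).
#' @param expr Gene x cell-line matrix of log2 TPM expression.
#' @param group Per-line labels; exactly two distinct values.
#' @param common_essential Character vector of pan-lineage essential genes.
#' @param context Label of the context group tested for selective
#'   essentiality (default "MNA").
#' @return A `dependency_screen` object.
#' @export
dependency_screen <- function(dep, expr, group, common_essential = character(),
                              context = "MNA") {
  stopifnot(is.matrix(dep), is.matrix(expr), ncol(dep) == length(group))
  if (length(unique(group)) != 2L)
    stop("group must have exactly two labels", call. = FALSE)
  if (!context %in% group)
    stop(sprintf("context label '%s' absent from group", context), call. = FALSE)
  if (!identical(colnames(dep), colnames(expr)))
    stop("dep and expr must share the same cell lines in the same order", call. = FALSE)
  structure(list(dep = dep, expr = expr, group = group,
                 common_essential = common_essential, context = context),
            class = "dependency_screen")
}

#' Simulate a two-group dependency screen with planted essentials
#'
#' Background dependency scores are Normal(0, `dependency_noise_sd`) in
#' both groups; `n_planted_essential` genes get mean `dependency_effect` in
#' the context group only; `n_common_essential` genes get a strong negative
#' mean (-1) in both groups and are listed as common essentials.
#' Expression is Normal(4, 1) log2 TPM for expressed genes; a configured
#' fraction of background genes is near zero to exercise the expression
#' filter (planted and common-essential genes are always expressed, so the
#' planted signal is recoverable by design).
#'
#' @param config A [sim_config()].
#' @return List with `screen` (a [dependency_screen()]) and `truth`
#'   (planted and common-essential gene ids).
#' @export
simulate_dependency_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_planted_essential + config$n_common_essential > config$n_genes)
    stop("n_planted_essential + n_common_essential exceeds n_genes", call. = FALSE)
  seeds <- .sub_seeds(config$seed, c("labels", "genes", "cn", "expr", "surv",
                                     "dep_plant", "dep"))
  nA <- config$n_cell_lines_group_a
  nB <- config$n_cell_lines_group_b
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  lines <- c(sprintf("MNA%02d", seq_len(nA)), sprintf("OTH%03d", seq_len(nB)))
  group <- c(rep("MNA", nA), rep("other", nB))

  set.seed(seeds[["dep_plant"]])
  planted <- sample(genes, config$n_planted_essential)
  common <- sample(setdiff(genes, planted), config$n_common_essential)

  set.seed(seeds[["dep"]])
  dep <- matrix(stats::rnorm(length(genes) * length(lines), 0,
                             config$dependency_noise_sd),
                length(genes), length(lines),
                dimnames = list(genes, lines))
  dep[planted, group == "MNA"] <- dep[planted, group == "MNA"] +
    config$dependency_effect
  dep[common, ] <- dep[common, ] - 1

  expressed <- stats::runif(length(genes)) >= config$unexpressed_fraction
  expressed[genes %in% c(planted, common)] <- TRUE
  expr <- matrix(0, length(genes), length(lines),
                 dimnames = list(genes, lines))
  expr[expressed, ] <- stats::rnorm(sum(expressed) * length(lines), 4, 1)
  expr[!expressed, ] <- pmax(stats::rnorm(sum(!expressed) * length(lines), 0, 0.1), 0)

  list(screen = dependency_screen(dep, expr, group, common, context = "MNA"),
       truth = list(planted = planted, common_essential = common))
}
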