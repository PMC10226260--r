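# neuro17q

Chromosome-17q imbalance classification, MYCN-amplified-context
essentiality screening and multi-evidence oncogene ranking for
neuroblastoma genomics.

Neuroblastoma tumors frequently gain chromosome arm 17q, and the adverse
form is *unbalanced* 17q — more 17q than 17p within the same tumor,
typically from an unbalanced translocation. This package implements, as
tested reusable R functions, the analysis chain that connects that
copy-number phenotype to candidate oncogenes:

* **Copy-number calling and the 17q balance value.** Per-bin log2-ratio
  states (gain at >= +0.3, loss at <= -0.4) and a per-sample balance value

  bv = -median(IMP1-ter) + median(17p) + 0.2

  where `17p` is the median log2 ratio over the short arm and `IMP1-ter`
  the median from the *IGF2BP1* locus to the 17q terminus; bv <= 0 calls
  the sample unbalanced. *MYCN* amplification (MNA) is called when copy
  number at the *MYCN* locus exceeds 4.
* **MNA-context essentiality screen** over CRISPR dependency matrices
  (e.g. 13 MNA vs 607 other cell lines): expression filter
  (log2 TPM > 2 in >= 11 of 13 context lines), selective-dependency
  median filters (context median < -0.2, others median > -0.3),
  common-essential exclusion, then an empirical-Bayes moderated t-test
  (scaled-inverse-chi-square prior on the per-gene variances, fitted by
  moments of log s²) with Benjamini–Hochberg FDR < 0.05.
* **Per-chromosome hypergeometric enrichment** of a gene list against
  autosomal protein-coding annotation: P(X >= k) for
  X ~ hypergeometric(N, K, n), stable down to ~1e-22.
* **Co-expression signature similarity** (correlation of correlations of
  Spearman profiles), knockdown-logFC concordance, adrenergic-minus-
  mesenchymal signature scores, and MYC/N E-box (CANNTG) scanning.
* **Survival analysis**: Kaplan–Meier, two-group log-rank, and expression
  dichotomization by median or best cut-off (flagged as
  optimization-biased).
* **Multi-evidence composite ranking**: per-criterion min-max scaling to
  [0,1] or [-1,1], orientation so larger = more oncogenic, mean over
  available evidence.
* **Seeded synthetic cohorts** with planted 17q gains, unbalanced
  segments, MNA, co-expressed driver modules, risk-dependent survival and
  planted essential genes, so every stage is testable without external
  data.

## Worked example

```r
library(neuro17q)

cfg <- sim_config(seed = 11)                 # 100 tumors, study-like prevalences
sim <- simulate_cohort(cfg)
calls <- classify_cohort(sim$profiles, genome_landmarks(cfg))
head(calls, 3)
#>   sample_id  median_17p median_imp1_ter        bv    label   mna cn_mycn
#> 1      S001 -0.02415612      0.02616005 0.1496838 balanced  TRUE       8
#> 2      S002  0.60764819      0.60308575 0.2045624 balanced FALSE       2
#> 3      S003  0.01523357     -0.07819062 0.2934242 balanced  TRUE       8
```

Sample S002 gained all of chromosome 17 (both medians ~ +0.6): bv stays at
~0.2 and the sample is balanced. The cohort contains 30 unbalanced and 13
MNA samples at seed 11, and the calls match the generator's ground truth
for all 100 tumors.

```r
scr <- simulate_dependency_screen(sim_config(seed = 11, n_genes = 2000))
res <- run_screen(scr$screen)
sum(res$tested); sum(res$hit)
#> [1] 40
#> [1] 40
mean(scr$truth$planted %in% res$gene[res$hit])
#> [1] 1
```

All 40 planted context-essential genes survive the filter cascade and are
recovered at FDR < 0.05 with no false hits.

```r
enr <- enrichment_from_counts(nb_chromosome_counts())
enr[enr$chromosome %in% c("chr1", "chr2", "chr17"), ]
#>    chromosome n_genes n_hits pct_distribution   p_value
#> 1        chr1    2048     22           12.571 2.497e-01
#> 2        chr2    1247     17            9.714 6.680e-02
#> 17      chr17    1188     52           29.714 5.047e-22
```

Of the 175 autosomal context-essential genes, 52 (29.7%) sit on
chromosome 17 — a hypergeometric upper-tail p of 5.047e-22 against the
19,046-gene universe; no other chromosome is enriched.

```r
grp <- ifelse(sim$truth$samples$risk_group == "high", "high-risk", "low-risk")
lr <- logrank_test(sim$meta$os_time, sim$meta$os_event, grp)
#> log-rank chi-square 32.37, p = 1.28e-08
```

High-risk samples (MNA or unbalanced 17q, simulated hazard ratio 5)
separate sharply in survival.

See `vignettes/neuro17q-methods.Rmd` for the models, parameter defaults,
numerical decisions and limitations.

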