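# msburden

Dissecting the genetic architecture of multiple sclerosis (MS) risk in a
founder population — such as Ashkenazi Jews (AJ) embedded in a larger
European case–control or trio cohort — takes a chain of standard but
fiddly population-genetics steps. `msburden` implements that chain as a
tested R pipeline for statistical geneticists:

- **Ancestry extraction** from genome-wide SNP data: allele-sharing (IBS)
  distances, classical multidimensional scaling, Ward clustering, and
  reference-panel-anchored cluster labelling; PC1-threshold classification
  for trio cohorts (a trio is "AJ" iff at least one parent is).
- **Polygenic burden**: the MS genetic burden score
  `MSGB_s = Σ_i ln(OR_i) · d_{s,i}` over a catalogue of confirmed non-HLA
  risk variants (dosage `d` counts risk alleles), compared between cases
  and controls by a one-sided Wilcoxon test.
- **Association**: per-marker logistic regression with covariates and
  separation flagging, Nagelkerke pseudo-R², carrier frequencies, and the
  step-wise conditional HLA scan (the top HLA allele — not the top SNP —
  is conditioned on at each step; the scan stops when nothing passes the
  per-step Bonferroni threshold).
- **Trio TDT**: phase-free transmission counting with per-marker Mendelian
  exclusion and the classical `χ² = (T−U)²/(T+U)` test, `OR = T/U`.
- **Meta-analysis**: Fisher's combined probability (`X² = −2Σ ln pᵢ`,
  df = 2k), inverse-variance fixed effects, DerSimonian–Laird random
  effects, SE reconstruction from printed OR/p pairs, and
  Benjamini–Hochberg FDR for genome-wide screens.
- **LD decay**: two-locus haplotype frequencies by EM from unphased
  genotypes, D′/r², and distance-binned decay profiles with equal-size
  group subsampling.
- **QC and I/O**: MAF/missingness filtering, greedy sliding-window LD
  pruning (pairwise r² < 0.1), and text PED/MAP + TSV readers/writers.
- **A synthetic cohort generator** (`simulate_cohort()`) producing
  two-population cohorts, HLA haplotypes, ascertained case–control arms
  and Mendelian trios with the statistical structure the analyses assume,
  so the whole pipeline is testable without any restricted genotype data.

## Worked example

```r
library(msburden)

cfg <- sim_config(n_per_pop = 300, m_snps = 4000, n_trios = 60, seed = 2026)
cohort <- simulate_cohort(cfg)

qc <- filter_variants(cohort$geno)
D    <- allele_sharing_distance(qc$geno)
tree <- ward_tree(D)
ref  <- setNames(rep("AJ", sum(cohort$samples$reference_panel)),
                 cohort$samples$sample_id[cohort$samples$reference_panel])
lab  <- label_clusters(tree, K = 2, reference = ref)
mean(lab$label == cohort$samples$population)
#> [1] 0.975

aj     <- lab$sample_id[lab$label == "AJ"]
keep   <- cohort$samples$sample_id %in% aj
scores <- msgb(cohort$geno[keep, ], cfg$risk_table)
cmp    <- compare_burden(scores, cohort$samples$status[keep])
#> MSGB: mean case 29.122, mean control 26.996, d = 2.126,
#>       one-sided p = 9.02e-16

allele_scan(cohort$hla[keep, ], cohort$samples$status[keep], r2 = TRUE)
#>      marker    or      p nagelkerke_r2 flag
#> 1 DRB1_1501 5.159 0.0030       0.04687
#> 2 DQB1_0602 5.159 0.0030       0.04687
#> 3    B_3801 0.595 0.3513       0.00503
#> 4    C_1203 0.595 0.3513       0.00503
#> 5    A_6802 2.250 0.0963       0.01316

fisher_combine(c(0.0072, 0.0728, 0.0455))
#> Fisher combined: X2 = 21.29 on 6 df, p = 0.0016
```

Reading the output: 97.5 % of the simulated individuals are assigned to
their true population from genotypes alone; within the recovered AJ subset
the planted 110-SNP burden is higher in cases than controls (difference of
means d = 2.13, one-sided Wilcoxon p ≈ 9e-16); the planted class II risk
haplotype (DRB1\*15:01-like, per-copy OR 3 in the generator) is recovered
with OR ≈ 5.2 and explains ~4.7 % of liability (Nagelkerke r²); and
combining three per-study p-values of 0.0072, 0.0728 and 0.0455 by
Fisher's method gives a meta p of 0.0016.

The vignette (`vignettes/msburden-methods.Rmd`) documents the models,
parameter choices and numerical conventions in detail.

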