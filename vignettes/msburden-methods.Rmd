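---
title: "Models and methods behind msburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msburden)
```

# Scope

`msburden` re-implements, as a tested pipeline, the statistical machinery
used to dissect multiple sclerosis (MS) genetic risk in a founder population
such as Ashkenazi Jews (AJ) embedded in a larger European cohort: extracting
genetic ancestry from genome-wide SNP data, scoring polygenic burden,
testing HLA alleles and SNPs for association in case–control and trio
designs, combining evidence across studies, and profiling linkage
disequilibrium (LD) decay. Because the original cohorts are not
distributable, the package ships a synthetic cohort generator that
reproduces the *statistical structure* those analyses assume; every stage is
validated against it.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults encode the study
conditions the pipeline targets:

* **Two diverged subpopulations.** Per-variant ancestral frequencies are
  drawn uniformly on (0.1, 0.9); each population's frequency is a
  Balding–Nichols Beta draw with parameters $p(1-f)/f$ and $(1-p)(1-f)/f$,
  so $f$ acts as an Fst-like divergence knob. No quantitative AJ/EUNW
  divergence is published for this design, so the default `fst = 0.01` is a
  deliberately conservative placeholder, exposed in `sim_config()`; the
  ancestry-recovery checks run at this value. A Hudson-type
  variance-components estimator applied to genotypes simulated from the
  drawn frequencies recovers $f$ to within sampling error (a frozen test).
* **HLA haplotypes.** Classical alleles are planted on haplotype classes
  drawn per chromosome, so alleles declared on one class (the
  DRB1\*15:01–DQB1\*06:02 class II pair; the protective class I
  B\*38:01–C\*12:03 pair) co-occur with dosage correlation near 1. Default
  carrier frequencies are ~5 % for the class II risk haplotype in the
  founder population versus ~17.5 % elsewhere (haplotype frequency $q$
  solves $1-(1-q)^2 = \text{carrier}$), with a per-copy odds ratio of 3.
* **Polygenic background.** 110 unlinked risk SNPs with odds ratios equally
  spaced over 1.2–1.4, the weak-effect regime of the confirmed non-HLA
  catalogue. Risk variants share frequencies across the two populations so
  that planted effects, not drift, drive case–control contrasts.
* **Disease labels.** $P(\text{case}\mid d) =
  \operatorname{logit}^{-1}(\alpha + \sum_i w_i d_i)$ with $w_i = \ln OR_i$;
  $\alpha$ is solved numerically so the marginal prevalence matches the
  configured baseline (default 0.2, a case–control mix rather than a
  population prevalence). Case–control arms are assembled by rejection
  sampling until quotas are met, mirroring ascertainment without modelling
  incidence.
* **Trios.** Each proband inherits, independently per site, one allele from
  each parent, so Mendelian consistency holds by construction (a tested
  invariant). A configurable fraction of trios (default one third) has
  exactly one non-AJ parent; a trio is "AJ" iff at least one parent is AJ,
  and transmissions from both parents of mixed trios are counted.
* **LD.** Optional Li–Stephens-style founder copying: haplotypes are mosaic
  copies of a small founder pool with per-base switch probability
  $1-e^{-r\,\text{gap}}$. This gives direct control of the decay rate (and
  of cross-group contrasts via the pool size) far more cheaply than
  coalescent simulation. It does **not** model mutation, gene conversion,
  variable recombination maps, or realistic demographic history, so LD
  checks are qualitative (ordering of binned medians), never calibrated to
  real decay curves.
* **Reproducibility.** One master integer seed; each stage derives its own
  sub-seed through a fixed integer recurrence, so stage order never
  perturbs downstream draws and a fixed seed yields bit-identical cohorts.

What passing these simulations shows — and does not show: they demonstrate
that each estimator recovers what was planted under the package's own
generative assumptions (unlinked background SNPs, logistic liability,
random mating within population). They cannot certify behaviour under real
genotyping artefacts, cryptic relatedness, or fine-scale admixture.

# Ancestry extraction

The original analysis fed haplotype-based IBD sharing into multidimensional
scaling and Ward clustering. Here the distance is the deterministic
allele-sharing (IBS) distance $d(i,j) = \frac{1}{m}\sum_k |d_{ik} -
d_{jk}|/2$ over shared non-missing sites: the downstream stages consume the
distance only through its ordering, and the IBS substitute preserves that
contract without re-implementing a haplotype HMM. Pairs with no shared
non-missing site raise an error rather than silently imputing.

Classical (Torgerson) MDS is computed by double-centering
(`stats::cmdscale`); for a Euclidean-embeddable matrix the coordinate
distances reproduce the input to 1e-8 (tested). Requesting more dimensions
than there are positive eigenvalues returns fewer with a warning — with the
default `k = 50` on small cohorts this is routine, not exceptional. Ward
clustering uses the Ward.D2 convention (`stats::hclust`).

Cluster labelling is reference-anchored: after cutting the tree into $K$
clusters (default 3, matching the three-cluster structure typical of these
cohorts; $K=2$ for clean two-population simulations), the cluster with the
highest fraction of reference-panel AJ samples is labelled AJ, the largest
remaining cluster EUNW, everything else OTHER. An evenly split reference
panel is an error, not a guess. For trio cohorts — where relatedness
distorts cluster geometry — members are classified on the first MDS axis
instead: PC1 is sign-anchored so the reference-AJ mean is positive
(eigenvectors are sign-ambiguous), and the default threshold is the
midpoint of the reference AJ and EUNW means. Probands land near the
parental PC1 mean, which the tests confirm on simulated trios.

# Polygenic burden (MSGB)

The MS genetic burden score is
$\text{MSGB}_s = \sum_i \ln(OR_i)\, d_{s,i}$ over the non-HLA risk
catalogue, with $d$ the risk-allele dosage (flipped to $2-d$ where the
matrix counts the other allele). Missing dosages are imputed as $2\hat p$
(twice the cohort risk-allele frequency): the source analyses are silent on
missingness, and this choice keeps scores comparable across individuals
with different call rates while leaving complete data untouched. Case
versus control burden is compared by a **one-sided** Wilcoxon rank-sum test
(cases higher), one-sided because the score is built exclusively from risk
alleles; the test is exact by enumeration when the smaller group has at
most 10 observations and no ties occur, otherwise the tie-corrected normal
approximation is used. The reported effect `d` is the difference of group
means — a location-shift estimate would be equally defensible; the mean
difference is adopted and documented here once.

# Case–control association

Per-marker logistic regression uses binomial IRLS (`stats::glm.fit`,
deviance tolerance 1e-8, 50 iterations) with Wald standard errors from the
inverse information. Complete or quasi-complete separation — every carrier
a case, say — is *flagged* (any $|\beta| > 15$ or non-convergence) and the
p-value withheld, rather than thrown: downstream scans must be able to step
over such markers. Markers with fewer than 5 carriers, constant dosage, or
all-missing dosage are skipped with a log message. Nagelkerke's
$r^2 = \frac{1 - \exp\{(2/n)(\ell_0-\ell_1)\}}{1 - \exp\{(2/n)\ell_0\}}$
is the "risk explained" metric; it is exercised against hand-computed
likelihood arithmetic on a 2×2 fixture.

The step-wise conditional HLA scan implements the published selection rule
exactly: at each step all markers (SNPs and HLA alleles) are scanned
conditional on previously selected alleles; the most significant **HLA
allele** is selected next even if a SNP is more significant and even if the
allele itself misses Bonferroni; the scan stops when no marker at all
passes the per-step Bonferroni threshold. The threshold denominator is the
number of markers actually tested that step (the source shows only a fixed
0.05 line without its denominator). A separated allele is flagged and the
next-best selected. Note an inherent property of an $\alpha = 0.05$ stop
rule: a null marker sneaks past Bonferroni in roughly 5 % of datasets, so
occasional one-step overruns on pure-null panels are expected behaviour,
not a defect.

# Trio TDT

Transmission counting needs no phase: with $h$ heterozygous parents and $a$
counted-allele copies forced by homozygous parents, the proband dosage
minus $a$ is the number of counted-allele transmissions from heterozygous
parents; values outside $[0, h]$ are Mendelian violations, excluded
per-marker with a count (per-family exclusion would discard information the
design keeps). The test is the classical
$\chi^2 = (T-U)^2/(T+U)$ on 1 df with $OR = T/U$ and **no continuity
correction** — the worked 12:4 example (OR 3.00, p 0.0455) pins that
convention. HLA alleles are collapsed allele-vs-rest to 0/1/2 dosages and
run through the same path.

# Meta-analysis

Both Fisher's combined probability ($X^2 = -2\sum\ln p_i$, df $=2k$) and
DerSimonian–Laird random effects (with the usual truncation
$\tau^2 = \max\{0, (Q-\text{df})/(\sum w - \sum w^2/\sum w)\}$) are
provided, alongside inverse-variance fixed effects and SE reconstruction
from printed OR/p pairs ($SE = |\ln OR|/z$). The combined columns of the
kind of HLA summary table this pipeline targets are numerically consistent
with Fisher's method over the three per-study p-values, so Fisher is the
reproduction path; random effects serves the genome-wide SNP meta-analysis.
A printed p of 0.0000 cannot be log-combined and is rejected loudly.
Chi-square tails come from `pchisq`, which is exact for these purposes.
Genome-wide screens are gated by Benjamini–Hochberg at FDR < 0.1 via
`p.adjust`.

# LD decay

Unphased two-locus haplotype frequencies are estimated by EM over the
double-heterozygote phase ambiguity (uniform start, tolerance 1e-10 on the
frequencies, 1000 iteration cap); every other genotype class has known
composition, so the E-step only splits the AaBb count. The observed-data
log-likelihood is non-decreasing and the estimate matches direct counting
whenever phase is known (both tested, the latter also against a grid-search
likelihood oracle). From haplotype frequencies, $D = f_{AB} - p_Ap_B$,
$D' = |D|/D_{\max}$ and $r^2 = D^2/[p_A(1-p_A)p_B(1-p_B)]$. Decay profiles
subsample every group to the same size (seeded) before binning pairs by
distance — mirroring the equal-n design of cross-population LD comparisons —
and report median $D'$ and $r^2$ per log-spaced bin to 500 kb (no published
bin edges exist; log spacing resolves the short range where decay is
fastest). Monomorphic pairs inside a subsample are skipped; empty bins are
emitted with missing medians.

# Quality control

Variants are dropped for MAF < 1 % and then missingness > 0.1 %, in that
order, with disjoint accounting. LD pruning is the greedy sliding-window
rule (defaults 50 variants / step 5 — the dominant convention; only the
$r^2 < 0.1$ ceiling is prescribed by the source), removing the later member
of any offending pair; determinism given input order is part of the
contract, and an exhaustive re-check of surviving pairs backs the ceiling.
Pruning runs after any panel merging, matching the order of operations in
the source's description. Hardy–Weinberg and sample-level QC are out of
scope.

# Problem sizes used by the test-suite calibrations

The simulation checks run at the sizes the analyses are designed around:
log-OR recovery at 2000 per arm × 20 replicates (tolerance ±0.15 covers
~3 sampling SDs); ancestry recovery at 200 per population × 5000 SNPs ×
10 replicates (≥98 % label agreement); burden power at 500 per arm with the
110-SNP catalogue × 20 replicates; TDT type-I error on 10,000 null trios ×
150 markers × 20 replicates (band 0.04–0.06); BH false-discovery proportion
over 1000 screens of 1000 nulls. `scripts/acceptance.R` re-runs the same
measurements from scratch under a caller-supplied seed.

# Known limitations

* The IBS distance is a stand-in for haplotype-based IBD sharing; on very
  recently diverged populations IBD carries more signal than IBS, so real
  separations may be easier than the simulated ones at equal Fst.
* The generator's unlinked-background assumption means pruning is exercised
  on founder-copying LD only; interactions between pruning and ancestry
  inference on real chip data are untested.
* Carrier-frequency contrasts, cluster counts and score differences
  reported for any real cohort are data-dependent and are not reproduction
  targets; only the summary-statistic arithmetic (meta-analysis, TDT
  worked counts) and the planted-effect recoveries are.
* HLA imputation itself is out of scope; the pipeline consumes imputed
  allele dosages and an allele mask chosen upstream.
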