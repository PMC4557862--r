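Package: msburden
Title: Polygenic Burden, Ancestry and HLA Association Analysis for Founder-Population Case-Control and Trio Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for dissecting the genetic architecture of multiple
    sclerosis risk in founder populations such as Ashkenazi Jews. Provides
    genetic-ancestry extraction from genome-wide SNP data (allele-sharing
    distances, classical multidimensional scaling, Ward clustering and
    reference-anchored labelling), a log-odds-ratio weighted polygenic burden
    score (MSGB), case-control logistic association with Nagelkerke pseudo-R2
    and a step-wise conditional HLA scan, the trio transmission
    disequilibrium test, summary-statistic meta-analysis (Fisher's combined
    probability, inverse-variance fixed effects and DerSimonian-Laird random
    effects), two-locus linkage-disequilibrium estimation via EM with
    distance-binned decay profiles, and a synthetic cohort generator that
    reproduces the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
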