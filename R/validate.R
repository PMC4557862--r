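# Simulation-based calibration checks. Cohort-dependent numbers from any
# real study (cluster counts, pruned-SNP totals, observed score differences)
# cannot be reproduced without the original genotypes; these routines verify
# instead that each stage of the pipeline recovers what the generator
# planted, at the study-like problem sizes the package is designed around.

#' Planted log-OR recovery by the logistic scan
#'
#' For each replicate, plants a single risk variant at a given odds ratio in
#' a population, ascertains equal case/control arms, and re-estimates the
#' log-OR with \code{\link{allele_scan}}.
#'
#' @param or planted odds ratio.
#' @param n_per_arm cases and controls sampled per replicate.
#' @param n_seeds number of replicates.
#' @param p risk-allele frequency.
#' @param prevalence population prevalence used by the liability model.
#' @param seed master seed.
#' @return Numeric vector of estimated betas (truth is \code{log(or)}).
#' @export
validate_log_or_recovery <- function(or = 1.3, n_per_arm = 2000,
                                     n_seeds = 20, p = 0.3,
                                     prevalence = 0.2, seed = 1L) {
  vapply(seq_len(n_seeds), function(s) {
    ss <- .sub_seed(seed, 100 + s)
    set.seed(ss)
    n_pop <- ceiling(n_per_arm / min(prevalence, 1 - prevalence)) * 2L
    d <- matrix(stats::rbinom(n_pop, 2L, p), ncol = 1,
                dimnames = list(NULL, "v1"))
    rt <- risk_weight_table("v1", "A", or)
    y <- assign_case_status(d, risk_table = rt,
                            baseline_prevalence = prevalence,
                            seed = .sub_seed(ss, 1))
    idx <- c(which(y == 1L)[seq_len(n_per_arm)],
             which(y == 0L)[seq_len(n_per_arm)])
    allele_scan(d[idx, , drop = FALSE],
                rep(c(1L, 0L), each = n_per_arm))$beta
  }, numeric(1))
}

#' End-to-end ancestry recovery rate
#'
#' Simulates a two-population cohort, applies the QC frequency filter, runs
#' the allele-sharing distance, Ward clustering and reference-anchored
#' labelling, and scores agreement with the simulated population labels.
#'
#' @param fst divergence between the populations.
#' @param n_per_pop samples per population.
#' @param m_snps background SNPs before QC.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @return Numeric vector of per-replicate labelling accuracies in [0, 1].
#' @export
validate_ancestry_recovery <- function(fst = 0.01, n_per_pop = 200,
                                       m_snps = 5000, n_seeds = 10,
                                       seed = 1L) {
  vapply(seq_len(n_seeds), function(s) {
    ss <- .sub_seed(seed, 200 + s)
    cc <- simulate_cohort(sim_config(n_per_pop = n_per_pop,
                                     m_snps = m_snps, fst = fst,
                                     risk_table = NULL,
                                     seed = ss))
    qc <- filter_variants(cc$geno, maf_min = 0.01, miss_max = 1)
    D <- allele_sharing_distance(qc$geno)
    tr <- ward_tree(D)
    ref_ids <- cc$samples$sample_id[cc$samples$reference_panel]
    lab <- label_clusters(tr, K = 2,
                          reference = stats::setNames(
                            rep("AJ", length(ref_ids)), ref_ids))
    mean(lab$label == cc$samples$population)
  }, numeric(1))
}

#' Burden-score power under planted catalogue effects
#'
#' Plants the full weak-effect risk catalogue, ascertains case/control arms,
#' and records the one-sided Wilcoxon p of the case-versus-control burden
#' comparison per replicate.
#'
#' @param risk_table planted catalogue (default: 110 SNPs, ORs 1.2-1.4).
#' @param n_per_arm samples per arm.
#' @param prevalence population prevalence.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @return Numeric vector of one-sided p-values.
#' @export
validate_msgb_power <- function(risk_table = default_risk_table(),
                                n_per_arm = 500, prevalence = 0.2,
                                n_seeds = 20, seed = 1L) {
  m <- nrow(risk_table)
  vapply(seq_len(n_seeds), function(s) {
    ss <- .sub_seed(seed, 300 + s)
    set.seed(ss)
    n_pop <- ceiling(n_per_arm / min(prevalence, 1 - prevalence)) * 2L
    p <- stats::runif(m, 0.2, 0.8)
    d <- matrix(stats::rbinom(n_pop * m, 2L, rep(p, each = n_pop)),
                n_pop, m, dimnames = list(NULL, risk_table$variant))
    y <- assign_case_status(d, risk_table = risk_table,
                            baseline_prevalence = prevalence,
                            seed = .sub_seed(ss, 1))
    idx <- c(which(y == 1L)[seq_len(n_per_arm)],
             which(y == 0L)[seq_len(n_per_arm)])
    G <- geno_matrix(d[idx, , drop = FALSE],
                     data.frame(id = risk_table$variant, chrom = 1L,
                                pos = seq_len(m), allele1 = "A",
                                allele2 = "G", stringsAsFactors = FALSE))
    compare_burden(msgb(G, risk_table),
                   rep(c("case", "control"), each = n_per_arm))$p
  }, numeric(1))
}

#' TDT type-I error on null trios
#'
#' Simulates unascertained trios at null markers and measures the fraction
#' of markers rejected at the given level.
#'
#' @param n_trios trios per replicate.
#' @param m_markers null markers per replicate.
#' @param alpha nominal level.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @return Numeric vector of per-replicate rejection fractions.
#' @export
validate_tdt_type1 <- function(n_trios = 10000, m_markers = 150,
                               alpha = 0.05, n_seeds = 20, seed = 1L) {
  vapply(seq_len(n_seeds), function(s) {
    ss <- .sub_seed(seed, 400 + s)
    set.seed(ss)
    freqs <- stats::runif(m_markers, 0.2, 0.8)
    ts <- simulate_trio_cohort(freqs, n_trios = n_trios,
                               fraction_mixed = 0, seed = .sub_seed(ss, 1))
    scan <- tdt_scan(ts)
    mean(scan$p < alpha, na.rm = TRUE)
  }, numeric(1))
}

#' Realized false-discovery proportion of BH on null screens
#'
#' @param n_screens number of simulated genome-wide screens.
#' @param m null tests per screen.
#' @param q BH level.
#' @param seed master seed.
#' @return Mean realized FDP (false discoveries over max(discoveries, 1)).
#' @export
validate_bh_fdr <- function(n_screens = 1000, m = 1000, q = 0.1,
                            seed = 1L) {
  set.seed(.sub_seed(seed, 500))
  fdp <- vapply(seq_len(n_screens), function(i) {
    disc <- bh_fdr(stats::runif(m), q = q)
    sum(disc) / max(1L, sum(disc))   # all hypotheses null
  }, numeric(1))
  mean(fdp)
}

#' Step-wise scan recovery of two independent HLA effects
#'
#' Plants one risk and one protective HLA allele (uncorrelated) among null
#' SNPs and checks that the conditional scan selects exactly those two
#' alleles, in order of significance, and then stops.
#'
#' @param n samples per replicate.
#' @param or_risk,or_prot planted per-copy odds ratios.
#' @param n_null_snps null SNPs scanned alongside the alleles.
#' @param n_seeds replicates.
#' @param seed master seed.
#' @return Logical vector: per-replicate exact recovery.
#' @export
validate_stepwise_recovery <- function(n = 2000, or_risk = 2.0,
                                       or_prot = 0.5, n_null_snps = 20,
                                       n_seeds = 10, seed = 1L) {
  vapply(seq_len(n_seeds), function(s) {
    set.seed(.sub_seed(seed, 600 + s))
    hla <- cbind(HLA_risk = stats::rbinom(n, 2, 0.15),
                 HLA_prot = stats::rbinom(n, 2, 0.2))
    eta <- log(or_risk) * hla[, 1] + log(or_prot) * hla[, 2] - 0.5
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    snps <- matrix(stats::rbinom(n * n_null_snps, 2, 0.3), n, n_null_snps,
                   dimnames = list(NULL, paste0("snp", seq_len(n_null_snps))))
    res <- stepwise_conditional_scan(snps, hla, y)
    if (!setequal(res$selected, c("HLA_risk", "HLA_prot"))) return(FALSE)
    # selection follows significance order of the unconditional scan
    step1 <- res$steps[[1]]
    top <- step1$marker[step1$marker %in% colnames(hla)]
    p1 <- step1$p[match(top, step1$marker)]
    res$selected[1] == top[which.min(p1)]
  }, logical(1))
}
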