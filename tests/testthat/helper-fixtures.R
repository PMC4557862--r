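# Shared fixture builders: tiny genotype matrices and cohorts constructed in
# code so no binary data ships with the package.

toy_geno <- function(dosages, pos = NULL, chrom = 1L, allele1 = "A",
                     allele2 = "G") {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  geno_matrix(dosages,
              data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = pos, allele1 = allele1, allele2 = allele2,
                         stringsAsFactors = FALSE))
}

# Dosage matrix with prescribed per-variant MAF / missingness, built
# deterministically (no RNG) by laying out counts.
geno_with_maf <- function(n, maf, miss = rep(0, length(maf))) {
  m <- length(maf)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    n_miss <- round(miss[j] * n)
    n_obs <- n - n_miss
    n_alt <- round(maf[j] * 2 * n_obs)
    d <- integer(n_obs)
    d[seq_len(n_alt %/% 2)] <- 2L
    if (n_alt %% 2 == 1) d[n_alt %/% 2 + 1] <- 1L
    dos[, j] <- c(d, rep(NA_integer_, n_miss))
  }
  toy_geno(dos)
}

# Two-population case-control cohort at a single planted risk variant.
planted_or_cohort <- function(or, n_per_arm, p = 0.3, prevalence = 0.2,
                              seed = 1L) {
  set.seed(seed)
  n_pop <- ceiling(n_per_arm / min(prevalence, 1 - prevalence)) * 2L
  d <- matrix(stats::rbinom(n_pop, 2L, p), ncol = 1,
              dimnames = list(NULL, "v1"))
  rt <- risk_weight_table("v1", "A", or)
  y <- assign_case_status(d, risk_table = rt, baseline_prevalence = prevalence,
                          seed = seed + 1L)
  cases <- which(y == 1L)[seq_len(n_per_arm)]
  ctrls <- which(y == 0L)[seq_len(n_per_arm)]
  idx <- c(cases, ctrls)
  list(dosage = d[idx, , drop = FALSE],
       y = rep(c(1L, 0L), each = n_per_arm))
}

# Hudson Fst estimator (ratio of averages, sample-size corrected) from two
# genotype matrices -- the independent oracle for the divergence knob.
hudson_fst <- function(G1, G2) {
  n1 <- nrow(G1); n2 <- nrow(G2)
  p1 <- colMeans(G1) / 2
  p2 <- colMeans(G2) / 2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
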