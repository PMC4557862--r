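test_that("zero divergence collapses both populations onto the ancestral draw", {
  fr <- draw_subpop_freqs(100, fst = 0, seed = 3)
  expect_identical(fr$pops[[1]], fr$ancestral)
  expect_identical(fr$pops[[2]], fr$ancestral)
  fr2 <- draw_subpop_freqs(50, fst = 0, ancestral_range = c(0.5, 0.5),
                           seed = 9)
  expect_true(all(fr2$pops[[1]] == 0.5))
  expect_error(draw_subpop_freqs(10, fst = 1), "fst")
  expect_error(draw_subpop_freqs(10, fst = -0.1), "fst")
})

test_that("the divergence knob is calibrated: Hudson Fst ~ fst", {
  # oracle: variance-components (Hudson) estimator on genotypes simulated at
  # the generated frequencies, averaged over replicate seeds
  est <- vapply(1:20, function(s) {
    fr <- draw_subpop_freqs(10000, fst = 0.01, seed = s)
    g1 <- simulate_genotypes(fr$pops[[1]], 100, seed = s * 31 + 1)$dosages
    g2 <- simulate_genotypes(fr$pops[[2]], 100, seed = s * 31 + 2)$dosages
    hudson_fst(g1, g2)
  }, numeric(1))
  expect_true(abs(mean(est) - 0.01) < 0.003)
})

test_that("genotype simulation honours fixed alleles and is seed-deterministic", {
  g <- simulate_genotypes(c(1, 0, 0.5), 50, seed = 4)
  expect_true(all(g$dosages[, 1] == 2))
  expect_true(all(g$dosages[, 2] == 0))
  g2 <- simulate_genotypes(c(1, 0, 0.5), 50, seed = 4)
  expect_identical(g$dosages, g2$dosages)
  expect_error(simulate_genotypes(c(0.5, 0.5), 10, positions = c(5, 5)),
               "strictly increasing")
})

test_that("founder-copying creates LD that decays with distance", {
  pos <- sort(sample.int(1e6, 800))
  fr <- rep(0.5, 800)
  g <- simulate_genotypes(fr, 100, ld = list(pool_size = 20,
                                             recomb_per_bp = 1e-5),
                          positions = pos, seed = 11)
  expect_equal(g$dosages,
               g$haplotypes[seq(1, 199, 2), ] + g$haplotypes[seq(2, 200, 2), ])
  # direct haplotype counting of r2 in a near and a far distance bin
  r2_of <- function(i, j) {
    ha <- g$haplotypes[, i]; hb <- g$haplotypes[, j]
    if (sd(ha) == 0 || sd(hb) == 0) return(NA_real_)
    cor(ha, hb)^2
  }
  near <- far <- c()
  for (i in seq(1, 790, by = 9)) {
    for (j in seq(i + 1, 800, by = 9)) {
      d <- pos[j] - pos[i]
      if (d < 1e4) near <- c(near, r2_of(i, j))
      else if (d > 2e5 && d < 5e5) far <- c(far, r2_of(i, j))
    }
  }
  expect_gt(length(near), 5); expect_gt(length(far), 5)
  expect_gt(median(near, na.rm = TRUE), median(far, na.rm = TRUE))
})

test_that("HLA haplotype planting hits carrier targets and links alleles", {
  spec <- default_hla_spec()
  # frequency 0 -> all dosages 0
  spec0 <- spec; spec0$freq_AJ <- 0
  h0 <- plant_hla_haplotypes(spec0, 50, "freq_AJ", seed = 2)
  expect_true(all(h0$dosages == 0))
  # 5% carrier target at n = 10000 within a binomial band
  h <- plant_hla_haplotypes(spec, 10000, "freq_AJ", seed = 5)
  carrier <- mean(h$dosages[, "DRB1_1501"] >= 1)
  expect_true(abs(carrier - 0.05) < 0.01)
  # linked alleles co-occur on the same chromosome: dosage correlation ~ 1
  spec2 <- data.frame(allele = c("X1", "X2"), haplotype = "H",
                      freq_AJ = 0.1, or = 1)
  h2 <- plant_hla_haplotypes(spec2, 4000, "freq_AJ", seed = 6)
  expect_gt(cor(h2$dosages[, 1], h2$dosages[, 2]), 0.9)
  # over-full locus rejected
  spec3 <- data.frame(allele = c("a", "b"), haplotype = c("h1", "h2"),
                      freq_AJ = c(0.7, 0.6), or = 1)
  expect_error(plant_hla_haplotypes(spec3, 10), "sum")
})

test_that("case assignment matches the logistic liability model", {
  set.seed(21)
  d <- matrix(rbinom(10000, 2, 0.5), ncol = 1, dimnames = list(NULL, "v1"))
  # all ORs 1 -> prevalence equals baseline up to binomial error
  rt_null <- risk_weight_table("v1", "A", 1)
  y <- assign_case_status(d, risk_table = rt_null,
                          baseline_prevalence = 0.2, seed = 3)
  expect_true(abs(mean(y) - 0.2) < 3 * sqrt(0.2 * 0.8 / 10000))
  # single variant OR = 2: empirical odds ratio between dosage 2 and 0 ~ 4
  set.seed(22)
  d2 <- matrix(rbinom(20000, 2, 0.5), ncol = 1, dimnames = list(NULL, "v1"))
  rt <- risk_weight_table("v1", "A", 2)
  y2 <- assign_case_status(d2, risk_table = rt, baseline_prevalence = 0.3,
                           seed = 4)
  odds <- function(v) mean(v) / (1 - mean(v))
  ratio <- odds(y2[d2 == 2]) / odds(y2[d2 == 0])
  expect_true(abs(ratio - 4) < 1)
  expect_error(assign_case_status(d, risk_table = rt_null,
                                  baseline_prevalence = 1.2),
               "prevalence")
  expect_error(
    assign_case_status(d, risk_table = risk_weight_table("zz", "A", 2),
                       baseline_prevalence = 0.2),
    "absent")
})

test_that("trios are Mendelian-consistent with the requested mixture", {
  ts <- simulate_trio_cohort(runif(50, 0.2, 0.8), n_trios = 200,
                             fraction_mixed = 1 / 3, seed = 14)
  expect_equal(sum(ts$meta$pop_mother == "OTHER"), round(200 / 3))
  expect_true(all(ts$meta$aj_trio))
  # construction guarantee: zero Mendelian violations at every variant
  viol <- 0L
  for (j in seq_len(ncol(ts$father))) {
    ct <- count_transmissions(ts$father[, j], ts$mother[, j],
                              ts$proband[, j])
    viol <- viol + ct$n_mendel_excluded
  }
  expect_identical(viol, 0L)
  ts0 <- simulate_trio_cohort(runif(10), n_trios = 5, fraction_mixed = 0,
                              seed = 1)
  expect_true(all(ts0$meta$pop_mother == "AJ"))
  expect_error(simulate_trio_cohort(numeric(0), n_trios = 5), "empty")
})

test_that("a fixed master seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_per_pop = 60, m_snps = 300, n_trios = 10, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$samples, b$samples)
  expect_identical(a$hla, b$hla)
  expect_identical(a$trios$proband, b$trios$proband)
})

test_that("empirical allele frequencies converge to the specification", {
  fr <- draw_subpop_freqs(300, fst = 0.02, seed = 8)
  g <- simulate_genotypes(fr$pops[[1]], 10000, seed = 9)
  err <- abs(colMeans(g$dosages) / 2 - fr$pops[[1]])
  # standard error of a frequency at n = 1e4 is < 0.005; allow 4 SEs
  expect_lt(max(err), 4 * sqrt(0.5 * 0.5 / 20000))
})
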