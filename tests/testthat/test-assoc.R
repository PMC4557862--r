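# 2x2 fixture used throughout: 10/5 exposed case/control, 5/10 unexposed.
fixture_2x2 <- function() {
  x <- c(rep(1, 15), rep(0, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  list(x = x, y = y)
}

test_that("logistic fit on a binary predictor equals the 2x2 closed form", {
  f <- fixture_2x2()
  fit <- logistic_fit(f$y, cbind(1, f$x))
  expect_equal(unname(fit$beta[2]), log(4), tolerance = 1e-4)
  expect_equal(unname(fit$se[2]), sqrt(0.6), tolerance = 1e-4)
  expect_false(fit$separation)

  # balanced null design: beta exactly 0 by symmetry
  y0 <- c(1, 0, 1, 0); x0 <- c(1, 1, 0, 0)
  fit0 <- logistic_fit(y0, cbind(1, x0))
  expect_equal(unname(fit0$beta[2]), 0, tolerance = 1e-8)

  # y identical to x: complete separation flagged, not thrown
  ys <- rep(c(1, 0), each = 10); xs <- ys
  fits <- logistic_fit(ys, cbind(1, xs))
  expect_true(fits$separation)

  expect_error(logistic_fit(rep(1, 10), cbind(1, rnorm(10))), "both classes")
  expect_error(logistic_fit(c(0, 1), cbind(1, c(0, 1), c(1, 0))),
               "more observations")
})

test_that("Nagelkerke r2 matches direct likelihood arithmetic", {
  # oracle: saturated-vs-null log-likelihoods of the 2x2 fixture
  ll_null <- 30 * log(0.5)
  ll_full <- 20 * log(2 / 3) + 10 * log(1 / 3)
  expect_equal(nagelkerke_r2(ll_full, ll_null, 30), 0.1427, tolerance = 1e-3)
  f <- fixture_2x2()
  fit1 <- logistic_fit(f$y, cbind(1, f$x))
  fit0 <- logistic_fit(f$y, matrix(1, 30))
  expect_equal(fit1$loglik, ll_full, tolerance = 1e-6)
  expect_equal(fit0$loglik, ll_null, tolerance = 1e-6)
  expect_equal(nagelkerke_r2(ll_full, ll_null, 30), 0.1427825,
               tolerance = 1e-4)
  expect_equal(nagelkerke_r2(ll_null, ll_null, 30), 0)
  # a perfectly predictive model approaches the upper bound
  expect_equal(nagelkerke_r2(0, -1000, 30), 1)
  expect_error(nagelkerke_r2(0, -1, 0), "positive")
  expect_error(nagelkerke_r2(-5, -1, 10), "ll_full")
})

test_that("carrier frequency counts individuals with >= 1 copy", {
  expect_equal(carrier_frequency(c(0, 0, 0)), 0)
  expect_equal(carrier_frequency(c(1, 2, 0, 0)), 0.5)
  expect_equal(carrier_frequency(c(1, NA, 0, NA)), 0.5)
  expect_error(carrier_frequency(c(NA, NA)), "non-missing")
  # closed form 1 - (1 - q)^2 at the DRB1*15:01-like haplotype frequency
  q <- 0.0257
  set.seed(33)
  d <- rbinom(10000, 2, q)
  expect_true(abs(carrier_frequency(d) - (1 - (1 - q)^2)) <
                4 * sqrt(0.05 * 0.95 / 10000))
})

test_that("allele scan recovers planted effects and skips degenerate markers", {
  pc <- planted_or_cohort(2, n_per_arm = 1000, seed = 41)
  recs <- allele_scan(pc$dosage, pc$y, r2 = TRUE)
  expect_equal(nrow(recs), 1)
  expect_lt(abs(recs$beta - log(2)), 0.25)
  expect_true(recs$nagelkerke_r2 > 0 && recs$nagelkerke_r2 < 1)
  # constant and rare markers skipped with a message
  mat <- cbind(v_const = rep(1, 20), v_rare = c(1, rep(0, 19)),
               v_ok = rep(c(0, 1, 2, 1), 5))
  y <- rep(c(1, 0), 10)
  expect_message(recs2 <- allele_scan(mat, y), "skipped")
  expect_equal(recs2$marker, "v_ok")
})

test_that("null markers yield uniform Wald p-values", {
  set.seed(91)
  n <- 1000; m <- 300
  mat <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(NULL, paste0("s", 1:m)))
  y <- rbinom(n, 1, 0.5)
  recs <- allele_scan(mat, y)
  ks <- suppressWarnings(stats::ks.test(recs$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stepwise conditional scan selects planted independent HLA effects", {
  set.seed(101)
  n <- 2000
  hla <- cbind(HLA_risk = rbinom(n, 2, 0.15),
               HLA_prot = rbinom(n, 2, 0.2),
               HLA_null = rbinom(n, 2, 0.1))
  eta <- log(2) * hla[, 1] + log(0.5) * hla[, 2] - 0.5
  y <- rbinom(n, 1, plogis(eta))
  snps <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
                 dimnames = list(NULL, paste0("snp", 1:20)))
  res <- stepwise_conditional_scan(snps, hla, y)
  expect_setequal(res$selected, c("HLA_risk", "HLA_prot"))
  expect_equal(res$stop_reason, "no marker passes Bonferroni")
  # selection ordered by significance and never repeated
  expect_false(anyDuplicated(res$selected) > 0)

  # pure null: no selections, stop at step one
  y0 <- rbinom(n, 1, 0.3)
  res0 <- stepwise_conditional_scan(snps, hla, y0)
  expect_length(res0$selected, 0)
  expect_length(res0$steps, 1)
})

test_that("conditioning on a selected allele absorbs its LD proxies", {
  set.seed(111)
  n <- 2000
  hla_d <- rbinom(n, 2, 0.2)
  # 10 SNPs in high LD with the allele: copy with small error
  snps <- sapply(1:10, function(i)
    ifelse(runif(n) < 0.95, hla_d, rbinom(n, 2, 0.2)))
  colnames(snps) <- paste0("tag", 1:10)
  y <- rbinom(n, 1, plogis(log(2.5) * hla_d - 0.8))
  hla <- cbind(HLA_eff = hla_d)
  res <- stepwise_conditional_scan(snps, hla, y)
  step1 <- res$steps[[1]]
  thr1 <- res$thresholds[1]
  expect_true(any(step1$p[step1$marker %in% colnames(snps)] <= thr1,
                  na.rm = TRUE))
  expect_equal(res$selected, "HLA_eff")
  # after conditioning, the tag SNPs fall silent
  if (length(res$steps) > 1) {
    step2 <- res$steps[[2]]
    expect_false(any(step2$p[step2$marker %in% colnames(snps)] <=
                       res$thresholds[2], na.rm = TRUE))
  }
})
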