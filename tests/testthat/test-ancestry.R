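test_that("allele-sharing distance matches hand-computed values", {
  G <- toy_geno(rbind(c(0, 1, 2), c(2, 1, 0), c(0, 1, 2)))
  D <- allele_sharing_distance(G)
  expect_equal(dim(D), c(3, 3))
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D[1, 2], (2 + 0 + 2) / 3 / 2)       # hand computation
  expect_equal(D[1, 3], 0)                         # identical rows
  Gmax <- toy_geno(rbind(c(0, 0), c(2, 2)))
  expect_equal(allele_sharing_distance(Gmax)[1, 2], 1)  # opposite homozygotes
})

test_that("missing-aware distance equals the dense path on shared sites", {
  set.seed(31)
  X <- matrix(rbinom(200, 2, 0.4), 10, 20)
  D_full <- allele_sharing_distance(toy_geno(X))
  Xm <- X; Xm[1, 3] <- NA
  D_miss <- allele_sharing_distance(toy_geno(Xm))
  # pair (1, j) now averages over 19 shared sites
  for (j in 2:10) {
    expect_equal(D_miss[1, j], mean(abs(X[1, -3] - X[j, -3])) / 2)
    expect_equal(D_miss[2, j], D_full[2, j])
  }
  # a pair with no shared sites is an error
  Xz <- rbind(c(1, NA), c(NA, 1))
  expect_error(allele_sharing_distance(toy_geno(Xz)), "zero non-missing")
})

test_that("classical MDS recovers line geometry and embeddable distances", {
  # 1-D points at 0, 1, 3 -> centered coordinates (-4/3, -1/3, 5/3)
  pts <- c(0, 1, 3)
  D <- as.matrix(dist(pts))
  # collinear points embed in one dimension: asking for 2 warns and returns 1
  expect_warning(fit <- classical_mds(D, k = 2), "positive eigenvalues")
  expect_equal(fit$k, 1L)
  x <- fit$points[, 1]
  if (x[1] > 0) x <- -x
  expect_equal(unname(x), c(-4 / 3, -1 / 3, 5 / 3), tolerance = 1e-8)

  # Euclidean-embeddable D reproduced exactly by coordinate distances
  set.seed(12)
  Y <- matrix(rnorm(40), 10, 4)
  D2 <- as.matrix(dist(Y))
  f2 <- suppressWarnings(classical_mds(D2, k = 9))
  expect_lt(max(abs(as.matrix(dist(f2$points)) - D2)), 1e-8)

  expect_equal(suppressWarnings(
    unname(classical_mds(matrix(0, 3, 3), k = 1)$points[, 1])),
    rep(0, 3))
  expect_error(classical_mds(D, k = 0), "k")
})

test_that("Ward tree separates well-spaced 1-D clusters", {
  pts <- c(a = 0, b = 0.1, c = 10, d = 10.1)
  D <- as.matrix(dist(pts))
  tr <- ward_tree(D)
  cut2 <- cutree(tr, 2)
  expect_equal(unname(cut2["a"]), unname(cut2["b"]))
  expect_equal(unname(cut2["c"]), unname(cut2["d"]))
  expect_false(cut2["a"] == cut2["c"])
  # identical points merge first at height 0
  Dz <- as.matrix(dist(c(0, 0, 5)))
  expect_equal(ward_tree(Dz)$height[1], 0)
  expect_error(ward_tree(matrix(0, 1, 1)), "2")
})

test_that("reference-anchored labelling recovers simulated populations", {
  acc <- vapply(1:10, function(s) {
    fr <- draw_subpop_freqs(2000, fst = 0.05, seed = s)
    g1 <- simulate_genotypes(fr$pops[[1]], 50, seed = s * 7 + 1)$dosages
    g2 <- simulate_genotypes(fr$pops[[2]], 50, seed = s * 7 + 2)$dosages
    G <- toy_geno(rbind(g1, g2))
    truth <- rep(c("AJ", "EUNW"), each = 50)
    D <- allele_sharing_distance(G)
    tr <- ward_tree(D)
    ref <- setNames(rep("AJ", 10), rownames(D)[1:10])
    lab <- label_clusters(tr, K = 2, reference = ref)
    mean(lab$label == truth)
  }, numeric(1))
  expect_gte(min(acc), 0.95)
  # no AJ reference is a precondition failure
  D <- as.matrix(dist(rnorm(10)))
  rownames(D) <- colnames(D) <- paste0("S", 1:10)
  expect_error(label_clusters(ward_tree(D), 2,
                              setNames("EUNW", "S1")), "AJ")
})

test_that("trio members classify by anchored PC1 and the one-AJ-parent rule", {
  set.seed(55)
  fr <- draw_subpop_freqs(3000, fst = 0.05, seed = 5)
  n <- 40
  g_aj <- simulate_genotypes(fr$pops[[1]], n, seed = 6)$dosages
  g_eu <- simulate_genotypes(fr$pops[[2]], n, seed = 7)$dosages
  X <- rbind(g_aj, g_eu)
  ids <- c(paste0("AJ", 1:n), paste0("EU", 1:n))
  G <- geno_matrix(X, data.frame(id = paste0("v", 1:3000), chrom = 1,
                                 pos = 1:3000, allele1 = "A", allele2 = "G"),
                   ids)
  coords <- classical_mds(allele_sharing_distance(G), k = 5)
  ref <- setNames(rep(c("AJ", "EUNW"), each = 5),
                  c(paste0("AJ", 1:5), paste0("EU", 1:5)))
  trios <- data.frame(father = c("AJ10", "EU10", "AJ11"),
                      mother = c("AJ12", "EU12", "EU11"),
                      proband = c("AJ13", "EU13", "AJ14"),
                      stringsAsFactors = FALSE)
  res <- classify_trio_members(coords, ref, trios)
  expect_equal(res$trios$aj_trio, c(TRUE, FALSE, TRUE))
  # members called AJ are exactly the simulated AJ samples
  expect_true(mean((res$members$label == "AJ") ==
                     grepl("^AJ", res$members$sample_id)) >= 0.95)
  # a trio with an unknown parent is skipped (NA flag) with a message
  trios_bad <- data.frame(father = "nope", mother = "AJ1", proband = "AJ2")
  expect_message(res2 <- classify_trio_members(coords, ref, trios_bad),
                 "skipped")
  expect_true(is.na(res2$trios$aj_trio))
})

test_that("proband PC1 sits near the parental mean in simulated trios", {
  fr <- draw_subpop_freqs(2000, fst = 0.05, seed = 19)
  ts <- simulate_trio_cohort(fr$pops[[1]], fr$pops[[2]], n_trios = 30,
                             fraction_mixed = 0.5, seed = 20)
  X <- rbind(ts$father, ts$mother, ts$proband)
  ids <- c(paste0("F", 1:30), paste0("M", 1:30), paste0("C", 1:30))
  G <- geno_matrix(X, data.frame(id = paste0("v", 1:2000), chrom = 1,
                                 pos = 1:2000, allele1 = "A", allele2 = "G"),
                   ids)
  coords <- classical_mds(allele_sharing_distance(G), k = 2)
  pc1 <- coords$points[, 1]
  mid <- (pc1[1:30] + pc1[31:60]) / 2
  resid <- pc1[61:90] - mid
  expect_lt(max(abs(resid - mean(resid))), 2 * max(sd(pc1)))
})

test_that("cohort frequency dendrograms group cohorts by population", {
  fr <- draw_subpop_freqs(4000, fst = 0.01, seed = 23)
  fmat <- rbind(
    A1 = colMeans(simulate_genotypes(fr$pops[[1]], 80, seed = 1)$dosages) / 2,
    A2 = colMeans(simulate_genotypes(fr$pops[[1]], 80, seed = 2)$dosages) / 2,
    B1 = colMeans(simulate_genotypes(fr$pops[[2]], 80, seed = 3)$dosages) / 2,
    B2 = colMeans(simulate_genotypes(fr$pops[[2]], 80, seed = 4)$dosages) / 2)
  tr <- cohort_frequency_dendrogram(fmat)
  cl <- cutree(tr, 2)
  expect_equal(unname(cl["A1"]), unname(cl["A2"]))
  expect_equal(unname(cl["B1"]), unname(cl["B2"]))
  expect_false(cl["A1"] == cl["B1"])
  # identical cohorts merge at height zero; first merge joins the closest pair
  f3 <- rbind(x = rep(0.4, 100), y = rep(0.4, 100), z = rep(0.5, 100))
  tr3 <- cohort_frequency_dendrogram(f3)
  expect_equal(tr3$height[1], 0)
  expect_error(cohort_frequency_dendrogram(f3[1, , drop = FALSE]), "2")
})
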