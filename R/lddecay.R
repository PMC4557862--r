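# Two-locus LD estimation (D, D-prime, r-squared) from unphased genotypes
# via EM over the double-heterozygote phase ambiguity, and distance-binned
# decay profiles comparing sample groups.

#' EM estimation of two-locus haplotype frequencies
#'
#' From unphased two-locus dosage vectors (0/1/2 at loci A and B), estimates
#' the four haplotype frequencies by expectation-maximisation over the
#' double-heterozygote phase ambiguity. All genotype classes except the
#' double heterozygote have known haplotype composition; the E-step splits
#' the AaBb class between (AB, ab) and (Ab, aB) in proportion to the current
#' frequency products. Uniform start, tolerance 1e-10 on the haplotype
#' frequencies, at most 1000 iterations; the observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param ga,gb dosage vectors (copies of allele A at locus 1, allele B at
#'   locus 2); pairwise-complete observations are used.
#' @return List of class \code{hap_freqs}: \code{f_ab} (named length-4
#'   vector: AB, Ab, aB, ab), \code{p_a}, \code{p_b}, \code{loglik},
#'   \code{iterations}.
#' @export
em_hapfreq <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (!length(ga)) stop("no complete two-locus observations")
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    stop("monomorphic locus: LD undefined")
  # counts of the 9 genotype classes
  n <- table(factor(ga, 0:2), factor(gb, 0:2))
  N <- 2 * sum(n)
  # fixed haplotype contributions from unambiguous classes
  # dosage ga counts A copies, gb counts B copies
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  add <- function(base, cls, counts) { base[cls] <- base[cls] + counts; base }
  base <- add(base, "ab", 2 * n["0", "0"])
  base <- add(base, "ab", n["0", "1"]); base <- add(base, "aB", n["0", "1"])
  base <- add(base, "aB", 2 * n["0", "2"])
  base <- add(base, "ab", n["1", "0"]); base <- add(base, "Ab", n["1", "0"])
  base <- add(base, "aB", n["1", "2"]); base <- add(base, "AB", n["1", "2"])
  base <- add(base, "Ab", 2 * n["2", "0"])
  base <- add(base, "Ab", n["2", "1"]); base <- add(base, "AB", n["2", "1"])
  base <- add(base, "AB", 2 * n["2", "2"])
  ndh <- n["1", "1"]  # double heterozygotes

  f <- rep(0.25, 4); names(f) <- names(base)
  ll_old <- -Inf; it <- 0L
  repeat {
    it <- it + 1L
    # E-step: split double hets by phase probability
    cis <- f["AB"] * f["ab"]
    trans <- f["Ab"] * f["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base
    cnt["AB"] <- cnt["AB"] + ndh * w
    cnt["ab"] <- cnt["ab"] + ndh * w
    cnt["Ab"] <- cnt["Ab"] + ndh * (1 - w)
    cnt["aB"] <- cnt["aB"] + ndh * (1 - w)
    f_new <- cnt / N
    ll <- .hap_loglik(f_new, base, ndh)
    if (max(abs(f_new - f)) < 1e-10 || it >= 1000L) { f <- f_new; break }
    f <- f_new; ll_old <- ll
  }
  structure(list(f_ab = f, p_a = f["AB"] + f["Ab"], p_b = f["AB"] + f["aB"],
                 loglik = .hap_loglik(f, base, ndh), iterations = it),
            class = "hap_freqs")
}

# Observed-data log-likelihood given haplotype freqs; `base` carries the
# unambiguous haplotype counts, ndh the double-het genotype count.
.hap_loglik <- function(f, base, ndh) {
  f <- pmax(f, 1e-300)
  sum(base * log(f)) + ndh * log(2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"]))
}

#' Haplotype frequencies by direct counting of phased haplotypes
#'
#' @param ha,hb 0/1 haplotype allele vectors (one entry per chromosome).
#' @return A \code{hap_freqs} object, as from \code{\link{em_hapfreq}}.
#' @export
count_hapfreq <- function(ha, hb) {
  ok <- !is.na(ha) & !is.na(hb)
  ha <- ha[ok]; hb <- hb[ok]
  f <- c(AB = mean(ha == 1 & hb == 1), Ab = mean(ha == 1 & hb == 0),
         aB = mean(ha == 0 & hb == 1), ab = mean(ha == 0 & hb == 0))
  structure(list(f_ab = f, p_a = f["AB"] + f["Ab"], p_b = f["AB"] + f["aB"],
                 loglik = NA_real_, iterations = 0L),
            class = "hap_freqs")
}

#' Two-locus LD coefficients from haplotype frequencies
#'
#' \eqn{D = f_{AB} - p_A p_B}; \eqn{D' = D / D_{max}} with
#' \eqn{D_{max} = \min\{p_A(1-p_B), (1-p_A)p_B\}} for D > 0 and
#' \eqn{\min\{p_A p_B, (1-p_A)(1-p_B)\}} for D < 0;
#' \eqn{r^2 = D^2 / [p_A(1-p_A)p_B(1-p_B)]}.
#'
#' @param h a \code{hap_freqs} object.
#' @return List with \code{d}, \code{dprime}, \code{r2}.
#' @export
ld_stats <- function(h) {
  pa <- as.numeric(h$p_a); pb <- as.numeric(h$p_b)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    stop("allele frequency at boundary: LD undefined")
  d <- as.numeric(h$f_ab["AB"]) - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(d = d,
       dprime = if (dmax > 0) abs(d) / dmax else 0,
       r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Distance-binned LD decay profile by sample group
#'
#' For each group, subsamples the same number of individuals (seeded), then
#' estimates D' and r-squared by EM for every within-chromosome variant pair
#' closer than \code{max_dist}, and reports the median of each statistic per
#' distance bin. Log-spaced bins by default. Empty bins are emitted with
#' missing medians.
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param groups vector of group labels aligned with the samples.
#' @param bins vector of bin edges in bp (default: log-spaced from 1 kb to
#'   \code{max_dist}).
#' @param n_subsample individuals per group (default: smallest group size).
#' @param max_dist maximum pair distance in bp (default 5e5).
#' @param seed integer seed for the subsampling.
#' @return Data frame: group, bin_lo, bin_hi, median_dprime, median_r2,
#'   n_pairs.
#' @export
decay_profile <- function(G, groups, bins = NULL, n_subsample = NULL,
                          max_dist = 5e5, seed = 1L) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(G$dosages))
  if (is.null(bins))
    bins <- unique(round(exp(seq(log(1e3), log(max_dist), length.out = 9))))
  glev <- unique(groups)
  sizes <- table(groups)
  if (is.null(n_subsample)) n_subsample <- min(sizes)
  if (any(sizes < n_subsample))
    stop("n_subsample exceeds a group size")
  set.seed(seed)
  sub <- lapply(glev, function(g)
    sample(which(groups == g), n_subsample))
  names(sub) <- glev

  v <- G$variants
  pairs <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) &&
             v$pos[idx[b]] - v$pos[idx[a]] < max_dist) {
        pairs[[length(pairs) + 1L]] <- c(idx[a], idx[b])
        b <- b + 1L
      }
    }
  }
  out <- list()
  for (g in glev) {
    rows <- sub[[g]]
    dp <- r2 <- dist_bp <- rep(NA_real_, length(pairs))
    for (k in seq_along(pairs)) {
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      dist_bp[k] <- abs(v$pos[j] - v$pos[i])
      h <- tryCatch(em_hapfreq(G$dosages[rows, i], G$dosages[rows, j]),
                    error = function(e) NULL)
      if (is.null(h)) next
      s <- tryCatch(ld_stats(h), error = function(e) NULL)
      if (is.null(s)) next
      dp[k] <- s$dprime; r2[k] <- s$r2
    }
    bin_id <- cut(dist_bp, breaks = c(0, bins), right = FALSE)
    for (bi in seq_len(length(bins))) {
      lo <- c(0, bins)[bi]; hi <- bins[bi]
      inb <- which(!is.na(bin_id) & as.integer(bin_id) == bi & !is.na(dp))
      out[[length(out) + 1L]] <- data.frame(
        group = g, bin_lo = lo, bin_hi = hi,
        median_dprime = if (length(inb)) stats::median(dp[inb]) else NA_real_,
        median_r2 = if (length(inb)) stats::median(r2[inb]) else NA_real_,
        n_pairs = length(inb), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
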