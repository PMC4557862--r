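# Variant-level QC: the marker filter (MAF >= 1%, missingness <= 0.1%)
# followed by greedy sliding-window LD pruning to pairwise r^2 < 0.1.

#' Filter variants on minor allele frequency and missingness
#'
#' Keeps variants with MAF >= \code{maf_min} AND missing-call rate
#' <= \code{miss_max}. The two removal categories are disjoint and applied
#' in that order, so the report accounts for every removal exactly once.
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum missing-call rate (default 0.001).
#' @return List with \code{geno} (filtered matrix) and \code{report}
#'   (\code{n_input}, \code{n_removed_maf}, \code{n_removed_missing},
#'   \code{n_kept}, \code{surviving_ids}).
#' @export
filter_variants <- function(G, maf_min = 0.01, miss_max = 0.001) {
  stopifnot(inherits(G, "geno_matrix"))
  if (ncol(G$dosages) == 0) stop("empty genotype matrix")
  maf <- minor_allele_freqs(G)
  miss <- missing_rates(G)
  fail_maf <- maf < maf_min | is.nan(maf)
  fail_miss <- !fail_maf & miss > miss_max
  keep <- !fail_maf & !fail_miss
  if (!any(keep))
    warning("all variants removed by QC thresholds")
  out <- G[, which(keep)]
  list(geno = out,
       report = list(n_input = ncol(G$dosages),
                     n_removed_maf = sum(fail_maf),
                     n_removed_missing = sum(fail_miss),
                     n_kept = sum(keep),
                     surviving_ids = G$variants$id[keep]))
}

# Pairwise-complete squared Pearson correlation of two dosage vectors.
.r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of \code{window} variants (advanced by \code{step}),
#' any pair of surviving variants with squared dosage correlation above
#' \code{r2_max} has its later member (by position order) removed. The scan
#' is deterministic given the input order. r^2 here is composite LD —
#' squared Pearson correlation of 0/1/2 dosages — so unphased data suffice.
#'
#' @param G a \code{\link{geno_matrix}} with variants position-sorted within
#'   each chromosome.
#' @param window window size in variants (default 50).
#' @param step step size in variants (default 5).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.1).
#' @return Character vector of surviving variant ids.
#' @export
ld_prune <- function(G, window = 50L, step = 5L, r2_max = 0.1) {
  stopifnot(inherits(G, "geno_matrix"))
  v <- G$variants
  for (ch in unique(v$chrom)) {
    pos <- v$pos[v$chrom == ch]
    if (is.unsorted(pos, strictly = FALSE))
      stop("variants not position-sorted within chromosome ", ch,
           "; sort before pruning")
  }
  m <- ncol(G$dosages)
  keep <- rep(TRUE, m)
  chroms <- unique(v$chrom)
  for (ch in chroms) {
    idx <- which(v$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window - 1L, length(idx)))]
      alive <- win[keep[win]]
      if (length(alive) > 1) {
        for (a in seq_len(length(alive) - 1L)) {
          i <- alive[a]
          if (!keep[i]) next
          for (b in seq(a + 1L, length(alive))) {
            j <- alive[b]
            if (!keep[j]) next
            if (.r2_pair(G$dosages[, i], G$dosages[, j]) > r2_max)
              keep[j] <- FALSE
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  G$variants$id[keep]
}
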