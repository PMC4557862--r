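# The MSGB polygenic burden score and case-control burden comparison.

#' Multiple sclerosis genetic burden (MSGB) score
#'
#' The weighted sum of risk-allele dosages,
#' \eqn{\mathrm{MSGB}_s = \sum_i w_i d_{s,i}} with \eqn{w_i = \ln(OR_i)}
#' from the published catalogue. Dosages are re-oriented to count the risk
#' allele (flipped to \code{2 - d} where the matrix counts the other
#' allele). A missing dosage is imputed as twice the cohort risk-allele
#' frequency, keeping scores comparable across individuals with different
#' missingness.
#'
#' @param G a \code{\link{geno_matrix}} containing every risk variant.
#' @param weights a \code{\link{risk_weight_table}}.
#' @return Named numeric vector of per-sample scores.
#' @export
msgb <- function(G, weights) {
  idx <- match(weights$variant, G$variants$id)
  if (anyNA(idx))
    stop("risk variants absent from genotype matrix: ",
         paste(weights$variant[is.na(idx)], collapse = ", "))
  D <- G$dosages[, idx, drop = FALSE]
  flip <- G$variants$allele1[idx] != weights$risk_allele
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  p_risk <- colMeans(D, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(D)) > 0)) {
    D[is.na(D[, j]), j] <- 2 * p_risk[j]
  }
  scores <- as.vector(D %*% weights$weight)
  names(scores) <- rownames(G$dosages)
  scores
}

#' Compare burden scores between cases and controls
#'
#' Reports the difference of group means d = mean(case) - mean(control) and
#' a one-sided Wilcoxon rank-sum p-value for cases carrying higher burden
#' (one-sided because the score is built from risk alleles). The test is
#' exact (enumeration) when the smaller group has <= 10 observations and no
#' ties are present; otherwise the normal approximation with tie correction
#' is used.
#'
#' @param scores numeric vector of MSGB scores.
#' @param groups vector aligned with \code{scores}; "case"/"control",
#'   logical (TRUE = case), or 0/1.
#' @return List with \code{mean_case}, \code{mean_control}, \code{d},
#'   \code{p} (one-sided), \code{n_case}, \code{n_control},
#'   \code{method} ("exact" or "normal").
#' @export
compare_burden <- function(scores, groups) {
  if (is.character(groups) || is.factor(groups)) {
    g <- as.character(groups) == "case"
  } else g <- as.logical(groups)
  keep <- !is.na(scores) & !is.na(g)
  scores <- scores[keep]; g <- g[keep]
  x <- scores[g]; y <- scores[!g]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  exact <- min(length(x), length(y)) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = !exact))
  list(mean_case = mean(x), mean_control = mean(y),
       d = mean(x) - mean(y), p = wt$p.value,
       n_case = length(x), n_control = length(y),
       method = if (exact) "exact" else "normal")
}
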