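# Combining evidence across studies: Fisher's combined probability,
# inverse-variance fixed effects, DerSimonian-Laird random effects, SE
# reconstruction from printed OR/p pairs, and Benjamini-Hochberg FDR.

#' Fisher's combined probability test
#'
#' \eqn{X^2 = -2\sum_i \ln p_i} on \eqn{2k} degrees of freedom. Decreasing
#' any input p never increases the combined p, and the statistic is
#' permutation invariant.
#'
#' @param p vector of per-study p-values, all in (0, 1].
#' @return List with \code{x2}, \code{df}, \code{p}.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]; a printed 0 cannot be combined")
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(x2 = x2, df = df,
       p = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Reconstruct a log-OR standard error from a printed OR and p
#'
#' Inverts the two-sided Wald test: \eqn{SE = |\ln OR| / z} with z the
#' two-sided normal quantile of p. Needed to meta-analyse summary rows that
#' print only OR and P.
#'
#' @param or odds ratio (> 0, != 1).
#' @param p two-sided p-value in (0, 1).
#' @return The standard error of ln(OR).
#' @export
se_from_summary <- function(or, p) {
  if (or <= 0) stop("OR must be positive")
  if (abs(or - 1) < .Machine$double.eps^0.5)
    stop("OR = 1: z-equation degenerate, SE unrecoverable")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  z <- stats::qnorm(1 - p / 2)
  abs(log(or)) / z
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Weights \eqn{w_i = 1/SE_i^2}; pooled \eqn{\beta = \sum w\beta / \sum w},
#' \eqn{SE = 1/\sqrt{\sum w}}; two-sided normal p.
#'
#' @param betas per-study log-ORs.
#' @param ses per-study standard errors (> 0).
#' @return List with \code{beta}, \code{se}, \code{z}, \code{p}, \code{q}
#'   (Cochran heterogeneity statistic), \code{df}.
#' @export
ivw_fixed <- function(betas, ses) {
  if (length(betas) != length(ses)) stop("betas and ses must align")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  b <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- b / se
  q <- sum(w * (betas - b)^2)
  list(beta = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       q = q, df = length(betas) - 1L)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance \eqn{\tau^2 = \max\{0, (Q - df)/(\sum w - \sum
#' w^2/\sum w)\}} estimated from the fixed-effect Cochran Q, then
#' inverse-variance pooling with weights \eqn{1/(SE_i^2 + \tau^2)}. With
#' homogeneous studies (Q <= df) the estimate truncates to zero and the
#' result equals the fixed-effect fit.
#'
#' @param betas per-study log-ORs (>= 2 studies).
#' @param ses per-study standard errors.
#' @return List with \code{beta}, \code{se}, \code{z}, \code{p},
#'   \code{tau2}, \code{q}, \code{df}.
#' @export
dl_random <- function(betas, ses) {
  if (length(betas) < 2) stop("random-effects pooling needs >= 2 studies")
  fe <- ivw_fixed(betas, ses)
  w <- 1 / ses^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (fe$q - fe$df) / denom) else 0
  ws <- 1 / (ses^2 + tau2)
  b <- sum(ws * betas) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- b / se
  list(beta = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       tau2 = tau2, q = fe$q, df = fe$df)
}

#' Benjamini-Hochberg FDR discovery flags
#'
#' Step-up procedure at level \code{q}: a p-value is a discovery iff its
#' BH-adjusted value is <= q.
#'
#' @param p vector of p-values in (0, 1].
#' @param q target false-discovery rate (default 0.1).
#' @return Logical vector of discovery flags aligned with \code{p}.
#' @export
bh_fdr <- function(p, q = 0.1) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}
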