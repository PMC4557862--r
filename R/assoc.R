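# Case-control association: logistic regression with covariates, Nagelkerke
# pseudo-R2, per-marker scans, carrier frequencies, and the step-wise
# conditional HLA scan.

#' Logistic regression fit with separation detection
#'
#' Maximum-likelihood logistic regression via binomial IRLS (deviance
#' tolerance 1e-8, at most 50 iterations) with Wald standard errors from the
#' inverse observed information. Complete or quasi-complete separation —
#' any coefficient escaping |beta| > 15, or a non-converged fit — is flagged
#' rather than raised, mirroring the situation where every carrier of an
#' allele is a case.
#'
#' @param y 0/1 outcome vector containing both classes.
#' @param X design matrix including an intercept column.
#' @return List with \code{beta}, \code{se}, \code{loglik}, \code{converged},
#'   \code{separation}, \code{n}.
#' @export
logistic_fit <- function(y, X) {
  X <- as.matrix(X)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome must contain both classes")
  if (nrow(X) <= ncol(X))
    stop("need more observations than design columns")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 50)))
  beta <- fit$coefficients
  separation <- any(abs(beta[!is.na(beta)]) > 15) || !fit$converged
  # Wald SEs from the unscaled covariance of the IRLS working model
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  se <- rep(NA_real_, length(beta))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(diag(cov))
  ll <- -fit$deviance / 2
  list(beta = beta, se = se, loglik = ll, converged = fit$converged,
       separation = separation, n = length(y))
}

#' Nagelkerke pseudo-R-squared
#'
#' \deqn{r^2 = \frac{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}}
#'                  {1 - \exp\{(2/n)\,\ell_0\}}}
#' the Cox-Snell ratio rescaled to a [0, 1] range; the "risk explained"
#' metric for a fitted variant.
#'
#' @param ll_full log-likelihood of the full model.
#' @param ll_null log-likelihood of the intercept-only model
#'   (\code{ll_full >= ll_null}).
#' @param n number of observations.
#' @return The pseudo-R-squared, in [0, 1].
#' @export
nagelkerke_r2 <- function(ll_full, ll_null, n) {
  if (n <= 0) stop("n must be positive")
  if (ll_full < ll_null - 1e-8)
    stop("ll_full must be >= ll_null")
  cs <- 1 - exp((2 / n) * (ll_null - ll_full))
  max_cs <- 1 - exp((2 / n) * ll_null)
  if (max_cs <= 0) return(0)
  min(1, max(0, cs / max_cs))
}

#' Carrier frequency
#'
#' Fraction of individuals carrying at least one copy of the allele, over
#' non-missing calls.
#' @param dosages 0/1/2 dosage vector (NA allowed).
#' @return Fraction in [0, 1].
#' @export
carrier_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("no non-missing dosages")
  mean(d >= 1)
}

# Fit one marker with covariates; returns an association record row.
.fit_marker <- function(marker_id, d, y, covar, r2 = FALSE) {
  ok <- !is.na(d) & !is.na(y)
  if (!is.null(covar)) ok <- ok & stats::complete.cases(covar)
  d <- d[ok]; yy <- y[ok]
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (!is.null(covar))
    X <- cbind(X, as.matrix(covar)[ok, , drop = FALSE])
  fit <- logistic_fit(yy, X)
  beta <- unname(fit$beta[2]); se <- fit$se[2]
  p <- if (fit$separation || is.na(se)) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))
  rec <- data.frame(
    marker = marker_id, beta = beta, se = se, or = exp(beta), p = p,
    n = fit$n,
    covariates = if (is.null(covar)) "" else
      paste(colnames(covar), collapse = "+"),
    nagelkerke_r2 = NA_real_,
    flag = if (fit$separation) "separation" else "",
    stringsAsFactors = FALSE)
  if (r2 && !fit$separation) {
    X0 <- X[, -2, drop = FALSE]
    fit0 <- logistic_fit(yy, X0)
    rec$nagelkerke_r2 <- nagelkerke_r2(fit$loglik, fit0$loglik, fit$n)
  }
  rec
}

#' Per-marker association scan
#'
#' Fits an additive-dosage logistic model per marker (SNP dosages and/or
#' 0/1/2-recoded HLA alleles), adjusted for the supplied covariates, and
#' reports Wald statistics. Markers with fewer than \code{min_carriers}
#' carriers, constant dosage, or all-missing dosage are skipped with a log
#' message.
#'
#' @param dosage_mat samples x markers dosage matrix (column names = marker
#'   ids).
#' @param phenotype 0/1 vector (or "case"/"control").
#' @param covariates optional data frame / matrix of covariates (e.g. age,
#'   sex and the leading MDS axes).
#' @param min_carriers minimum carrier count to test a marker (default 5).
#' @param r2 also compute Nagelkerke r-squared per marker (default FALSE).
#' @return Data frame of association records, one row per tested marker.
#' @export
allele_scan <- function(dosage_mat, phenotype, covariates = NULL,
                        min_carriers = 5L, r2 = FALSE) {
  y <- if (is.character(phenotype) || is.factor(phenotype))
    as.integer(as.character(phenotype) == "case") else as.integer(phenotype)
  dosage_mat <- as.matrix(dosage_mat)
  out <- vector("list", ncol(dosage_mat))
  for (j in seq_len(ncol(dosage_mat))) {
    d <- dosage_mat[, j]
    id <- colnames(dosage_mat)[j]
    if (all(is.na(d)) || length(unique(d[!is.na(d)])) < 2) {
      message("marker ", id, " skipped: constant or all-missing dosage")
      next
    }
    if (sum(d >= 1, na.rm = TRUE) < min_carriers) {
      message("marker ", id, " skipped: fewer than ", min_carriers,
              " carriers")
      next
    }
    out[[j]] <- .fit_marker(id, d, y, covariates, r2 = r2)
  }
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs)) recs <- .fit_marker("x", c(0, 1), c(0, 1), NULL)[0, ]
  rownames(recs) <- NULL
  recs
}

#' Step-wise conditional HLA scan
#'
#' At each step every marker (SNPs and HLA alleles) is scanned conditional
#' on the previously selected HLA alleles plus the base covariates. The most
#' significant HLA allele is then selected as the next conditioning
#' covariate — even if a SNP is more significant, and even if that allele
#' does not itself pass Bonferroni. The scan stops when no SNP or HLA allele
#' passes the per-step Bonferroni threshold (alpha divided by the number of
#' markers actually tested that step). An allele hitting separation in a
#' step is flagged and the next-best allele is selected instead.
#'
#' @param snp_mat samples x SNPs dosage matrix (may have 0 columns).
#' @param hla_mat samples x HLA-alleles dosage matrix (>= 1 column).
#' @param phenotype 0/1 or "case"/"control" vector.
#' @param covariates optional base covariate data frame.
#' @param alpha family-wise level for the Bonferroni stop rule (default
#'   0.05).
#' @param max_steps safety cap on the number of selection steps.
#' @return List with \code{selected} (alleles in selection order),
#'   \code{steps} (per-step full scan records), \code{thresholds} (per-step
#'   Bonferroni cutoffs), \code{stop_reason}.
#' @export
stepwise_conditional_scan <- function(snp_mat, hla_mat, phenotype,
                                      covariates = NULL, alpha = 0.05,
                                      max_steps = 20L) {
  hla_mat <- as.matrix(hla_mat)
  if (ncol(hla_mat) < 1) stop("at least one HLA allele required")
  snp_mat <- if (is.null(snp_mat)) matrix(numeric(0), nrow(hla_mat), 0)
             else as.matrix(snp_mat)
  selected <- character(0)
  steps <- list()
  thresholds <- numeric(0)
  stop_reason <- "max_steps"
  for (s in seq_len(max_steps)) {
    cond <- if (length(selected))
      hla_mat[, selected, drop = FALSE] else NULL
    covar <- covariates
    if (!is.null(cond)) {
      covar <- if (is.null(covar)) as.data.frame(cond)
               else cbind(as.data.frame(covar), as.data.frame(cond))
    }
    test_hla <- setdiff(colnames(hla_mat), selected)
    mat <- cbind(snp_mat, hla_mat[, test_hla, drop = FALSE])
    recs <- allele_scan(mat, phenotype, covar)
    recs$is_hla <- recs$marker %in% test_hla
    n_tests <- nrow(recs)
    thr <- alpha / max(1L, n_tests)
    steps[[s]] <- recs
    thresholds <- c(thresholds, thr)
    if (!any(recs$p <= thr, na.rm = TRUE)) {
      stop_reason <- "no marker passes Bonferroni"
      break
    }
    hla_ok <- recs[recs$is_hla & !is.na(recs$p), , drop = FALSE]
    if (!nrow(hla_ok)) {
      stop_reason <- "no testable HLA allele remains"
      break
    }
    pick <- hla_ok$marker[which.min(hla_ok$p)]
    selected <- c(selected, pick)
    if (length(selected) == ncol(hla_mat)) {
      stop_reason <- "all HLA alleles selected"
      break
    }
  }
  list(selected = selected, steps = steps, thresholds = thresholds,
       stop_reason = stop_reason)
}
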