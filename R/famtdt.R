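# Trio transmission counting and the transmission disequilibrium test.

#' Count transmissions from heterozygous parents
#'
#' For a biallelic marker (an HLA allele is treated allele-vs-rest), each
#' heterozygous parent contributes one transmission: to T if the counted
#' allele was passed to the affected proband, else to U. Homozygous parents
#' are uninformative. Phase is never needed: with \eqn{h} heterozygous
#' parents and \eqn{a} copies contributed by homozygous carrier parents, the
#' number of counted-allele transmissions from heterozygous parents is the
#' proband dosage minus \eqn{a}. Mendelian-inconsistent trios are excluded
#' for that marker and counted.
#'
#' @param father,mother,proband 0/1/2 dosage vectors over trios (one marker),
#'   or a \code{trio_set} passed as \code{father} with \code{marker} naming
#'   the variant.
#' @param marker variant id, when a \code{trio_set} is given.
#' @return List with \code{T}, \code{U}, \code{n_informative} (heterozygous
#'   parents counted), \code{n_mendel_excluded}.
#' @export
count_transmissions <- function(father, mother = NULL, proband = NULL,
                                marker = NULL) {
  if (inherits(father, "trio_set")) {
    ts <- father
    j <- match(marker, ts$variant_ids)
    if (is.na(j)) stop("marker ", marker, " not in trio set")
    proband <- ts$proband[, j]; mother <- ts$mother[, j]
    father <- ts$father[, j]
  }
  ok <- !is.na(father) & !is.na(mother) & !is.na(proband)
  f <- father[ok]; m <- mother[ok]; c <- proband[ok]
  hets <- (f == 1) + (m == 1)
  hom_copies <- (f == 2) + (m == 2)      # copies forced by homozygous parents
  t_het <- c - hom_copies                # counted-allele transmissions
  mendel_ok <- t_het >= 0 & t_het <= hets
  n_excl <- sum(!mendel_ok) + sum(!ok)
  t_het <- t_het[mendel_ok]; hets <- hets[mendel_ok]
  T <- sum(t_het)
  U <- sum(hets) - T
  if (T + U == 0)
    warning("no heterozygous parents at this marker; TDT undefined")
  list(T = T, U = U, n_informative = sum(hets), n_mendel_excluded = n_excl)
}

#' Transmission disequilibrium test
#'
#' The classical McNemar-type TDT: \eqn{\chi^2 = (T-U)^2/(T+U)} on 1 df,
#' with \eqn{OR = T/U} (undefined when U = 0). No continuity correction.
#'
#' @param T transmitted count from heterozygous parents.
#' @param U untransmitted count.
#' @return List with \code{T}, \code{U}, \code{or}, \code{chi2}, \code{p}.
#' @export
tdt <- function(T, U) {
  if (T < 0 || U < 0) stop("counts must be nonnegative")
  if (T + U == 0) stop("T + U must be positive; no informative parents")
  chi2 <- (T - U)^2 / (T + U)
  list(T = T, U = U,
       or = if (U > 0) T / U else NA_real_,
       chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' TDT scan over every marker of a trio set
#'
#' @param trios a \code{trio_set}.
#' @param markers variant ids to test (default: all).
#' @param aj_only restrict to AJ-flagged trios (default TRUE; transmissions
#'   from both parents of mixed trios are counted).
#' @return Data frame with one row per marker: T, U, or, chi2, p,
#'   n_informative, n_mendel_excluded.
#' @export
tdt_scan <- function(trios, markers = NULL, aj_only = TRUE) {
  stopifnot(inherits(trios, "trio_set"))
  if (is.null(markers)) markers <- trios$variant_ids
  keep <- if (aj_only) which(trios$meta$aj_trio) else
    seq_len(nrow(trios$father))
  out <- lapply(markers, function(mk) {
    j <- match(mk, trios$variant_ids)
    ct <- suppressWarnings(count_transmissions(
      trios$father[keep, j], trios$mother[keep, j], trios$proband[keep, j]))
    if (ct$T + ct$U == 0)
      return(data.frame(marker = mk, T = 0, U = 0, or = NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        n_informative = 0, n_mendel_excluded =
                          ct$n_mendel_excluded, stringsAsFactors = FALSE))
    tt <- tdt(ct$T, ct$U)
    data.frame(marker = mk, T = tt$T, U = tt$U, or = tt$or, chi2 = tt$chi2,
               p = tt$p, n_informative = ct$n_informative,
               n_mendel_excluded = ct$n_mendel_excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
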