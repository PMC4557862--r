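#' Construct a genotype matrix
#'
#' The central container of the pipeline: an individuals-by-variants dosage
#' matrix coded 0/1/2 (copies of the counted allele) with \code{NA} for
#' missing calls, plus per-variant metadata.
#'
#' @param dosages numeric or integer matrix, samples in rows, variants in
#'   columns; entries in \{0, 1, 2, NA\}.
#' @param variants data frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{allele1}, \code{allele2}; \code{allele1} is the
#'   counted allele (a dosage of 2 means two copies of \code{allele1}).
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants))
  req <- c("id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variant count (", nrow(variants), ") != matrix width (",
         ncol(dosages), ")")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants\n")
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat("  missing calls:", nm, "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a \code{geno_matrix}.
#' @param i sample index (logical, integer or character).
#' @param j variant index.
#' @param ... unused.
#' @return A \code{geno_matrix} restricted to the selected samples/variants.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(j)) j <- match(j, x$variants$id)
  geno_matrix(x$dosages[i, j, drop = FALSE], x$variants[j, , drop = FALSE],
              rownames(x$dosages)[seq_len(nrow(x$dosages))][i])
}

#' Counted-allele frequencies
#'
#' @param G a \code{geno_matrix}.
#' @return Numeric vector: per-variant frequency of the counted allele
#'   (\code{allele1}), computed over non-missing calls.
#' @export
allele_freqs <- function(G) {
  colMeans(G$dosages, na.rm = TRUE) / 2
}

#' Per-variant minor allele frequency
#' @param G a \code{geno_matrix}.
#' @return Numeric vector of MAFs in [0, 0.5].
#' @export
minor_allele_freqs <- function(G) {
  p <- allele_freqs(G)
  pmin(p, 1 - p)
}

#' Per-variant missing-call rate
#' @param G a \code{geno_matrix}.
#' @return Fraction of missing calls per variant.
#' @export
missing_rates <- function(G) {
  colMeans(is.na(G$dosages))
}
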