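# Text PED/MAP and TSV readers/writers. Text PLINK dialect rather than binary
# BED: fixtures stay human-inspectable and desk-scale cohorts load in well
# under a second.

.ped_status_levels <- c(`1` = "control", `2` = "case", `0` = "unknown",
                        `-9` = "unknown")

#' Read genotypes from text PED/MAP files
#'
#' Parses the PLINK text dialect: a MAP file (chrom, id, cM, position) and a
#' PED file (FID, IID, PAT, MAT, SEX, PHENO followed by two allele columns
#' per variant). Alleles are recoded to dosage of the dataset minor allele,
#' determined per variant at load; ties are broken toward the
#' alphabetically first observed allele so that coding is deterministic.
#' \code{"0 0"} genotypes become missing.
#'
#' @param ped path to the PED file.
#' @param map path to the MAP file.
#' @return A list with components \code{geno} (a \code{\link{geno_matrix}};
#'   \code{allele1} in its variant table is the counted minor allele) and
#'   \code{samples} (a data frame with sample/family/parent ids, sex, and
#'   \code{status} decoded as control/case/unknown).
#' @export
read_ped_map <- function(ped, map) {
  if (!file.exists(ped)) stop("PED file not found: ", ped)
  if (!file.exists(map)) stop("MAP file not found: ", map)
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) == 3) mp <- cbind(mp[, 1:2], 0, mp[, 3])
  names(mp) <- c("chrom", "id", "cm", "pos")
  m <- nrow(mp)

  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) stop("empty PED file: ", ped)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m
  len <- lengths(toks)
  if (any(len != want)) {
    bad <- which(len != want)[1]
    stop("PED line ", bad, ": expected ", want, " fields, found ", len[bad])
  }
  tk <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(
    family_id = tk[, 1], sample_id = tk[, 2],
    paternal_id = tk[, 3], maternal_id = tk[, 4],
    sex = suppressWarnings(as.integer(tk[, 5])),
    status = unname(.ped_status_levels[tk[, 6]]),
    stringsAsFactors = FALSE)
  samples$status[is.na(samples$status)] <- "unknown"

  a1 <- tk[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tk[, 6 + 2 * seq_len(m), drop = FALSE]
  ok <- c("A", "C", "G", "T", "1", "2", "0")
  bad <- matrix(!(a1 %in% ok) | !(a2 %in% ok), nrow = n)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("PED line ", idx[1], ", variant ", mp$id[idx[2]],
         ": allele not in {A,C,G,T,1,2,0}")
  }

  dos <- matrix(NA_integer_, n, m)
  counted <- other <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    missing_call <- x1 == "0" | x2 == "0"
    obs <- c(x1[!missing_call], x2[!missing_call])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("variant ", mp$id[j], ": more than two alleles observed")
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor allele counted; tie -> first (alphabetical) allele
    minor <- if (cnt[2] < cnt[1]) alleles[2] else alleles[1]
    counted[j] <- minor
    other[j] <- setdiff(alleles, minor)[1]
    if (is.na(other[j])) other[j] <- minor
    d <- (x1 == minor) + (x2 == minor)
    d[missing_call] <- NA_integer_
    dos[, j] <- d
  }
  variants <- data.frame(id = mp$id, chrom = mp$chrom, pos = mp$pos,
                         allele1 = counted, allele2 = other,
                         stringsAsFactors = FALSE)
  list(geno = geno_matrix(dos, variants, samples$sample_id),
       samples = samples)
}

#' Write genotypes to text PED/MAP files
#'
#' Inverse of \code{\link{read_ped_map}}: dosages are expanded back to
#' two-allele genotype columns (missing becomes \code{0 0}).
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param samples optional sample data frame as returned by
#'   \code{read_ped_map}; defaults to unrelated unknown-status samples.
#' @param ped,map output paths.
#' @return Invisibly, the PED path.
#' @export
write_ped_map <- function(geno, samples = NULL, ped, map) {
  v <- geno$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos),
    map, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(geno$dosages)
  if (is.null(samples)) {
    samples <- data.frame(family_id = rownames(geno$dosages),
                          sample_id = rownames(geno$dosages),
                          paternal_id = "0", maternal_id = "0",
                          sex = 0L, status = "unknown",
                          stringsAsFactors = FALSE)
  }
  status_code <- c(control = "1", case = "2", unknown = "0")[samples$status]
  status_code[is.na(status_code)] <- "0"
  gcols <- matrix("0", n, 2 * ncol(geno$dosages))
  for (j in seq_len(ncol(geno$dosages))) {
    d <- geno$dosages[, j]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$allele1[j], v$allele2[j]))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$allele1[j], v$allele2[j]))
    gcols[, 2 * j - 1] <- g1
    gcols[, 2 * j] <- g2
  }
  out <- cbind(samples$family_id, samples$sample_id, samples$paternal_id,
               samples$maternal_id, as.character(samples$sex), status_code,
               gcols)
  writeLines(apply(out, 1, paste, collapse = " "), ped)
  invisible(ped)
}

#' Read a typed TSV table with schema validation
#'
#' @param path path to a tab-separated file with a header row.
#' @param required character vector of column names that must be present.
#' @return A data frame; the strings \code{"NA"}, \code{""} and \code{"-9"}
#'   are normalised to \code{NA}.
#' @export
read_tsv_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         na.strings = c("NA", "", "-9"))
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  x
}

#' Read a risk-weight table
#'
#' Loads a table of confirmed risk variants (variant id, risk allele,
#' published odds ratio) and computes the per-variant weight
#' \eqn{w = \ln(\mathrm{OR})} used by the polygenic burden score.
#'
#' @param path TSV with columns \code{variant}, \code{risk_allele}, \code{or}.
#' @return Data frame with an added \code{weight} column.
#' @export
read_risk_table <- function(path) {
  x <- read_tsv_table(path, required = c("variant", "risk_allele", "or"))
  risk_weight_table(x$variant, x$risk_allele, x$or)
}

#' Construct a risk-weight table in memory
#'
#' @param variant character vector of variant ids.
#' @param risk_allele counted risk allele per variant.
#' @param or published odds ratio per variant; must be positive.
#' @return Data frame with columns variant, risk_allele, or, weight = ln(or).
#' @export
risk_weight_table <- function(variant, risk_allele, or) {
  if (any(!is.finite(or)) || any(or <= 0))
    stop("odds ratios must be positive and finite")
  if (anyDuplicated(variant)) stop("duplicate variant ids in risk table")
  data.frame(variant = as.character(variant),
             risk_allele = as.character(risk_allele),
             or = as.numeric(or), weight = log(as.numeric(or)),
             stringsAsFactors = FALSE)
}

# Canonical column order of an association-record table.
.assoc_cols <- c("marker", "beta", "se", "or", "p", "n", "covariates",
                 "nagelkerke_r2", "flag")

#' Write association records to TSV
#'
#' Columns are emitted in a fixed declared order so that write/read/write
#' round trips are byte identical.
#'
#' @param records data frame of association records.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(records, path) {
  cols <- intersect(.assoc_cols, names(records))
  cols <- c(cols, setdiff(names(records), cols))
  records <- records[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read association records written by \code{\link{write_results}}
#' @param path TSV path.
#' @return Data frame of records.
#' @export
read_results <- function(path) {
  # "NA" alone marks missing here, so empty flag strings survive round trips
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  if (!"marker" %in% names(x)) stop("results table lacks column: marker")
  x$flag[is.na(x$flag)] <- ""
  x
}
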