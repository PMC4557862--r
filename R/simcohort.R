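# Synthetic cohort generator. Emulates the statistical structure the
# downstream analyses assume: two diverged European-like subpopulations (one
# founder/"AJ-like" with a characterized reference panel), differential HLA
# haplotype frequencies, ~110 weak non-HLA risk SNPs, tunable LD decay, and
# case ascertainment under a logistic liability model. Trios follow Mendelian
# transmission exactly.

# Derive a stage sub-seed from the global seed: a fixed integer recurrence so
# stage order never perturbs reproducibility. Kept below 2^31.
.sub_seed <- function(seed, k) {
  (as.double(seed) * 48271 + k * 16807) %% 2147483587
}

#' Draw diverged subpopulation allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are drawn uniformly on \code{ancestral_range}; each
#' population's frequency is then a Beta draw with parameters
#' \eqn{p(1-f)/f} and \eqn{(1-p)(1-f)/f}, so the between-population variance
#' is controlled by the Fst-like divergence \code{fst}. With \code{fst = 0}
#' both populations equal the ancestral draw exactly.
#'
#' @param m number of variants.
#' @param fst divergence parameter in [0, 1).
#' @param ancestral_range interval for the ancestral frequency, within (0, 1).
#' @param seed integer seed.
#' @param n_pop number of populations to draw (default 2).
#' @return List with \code{ancestral} (length-m vector) and \code{pops}
#'   (list of \code{n_pop} length-m frequency vectors).
#' @export
draw_subpop_freqs <- function(m, fst, ancestral_range = c(0.1, 0.9),
                              seed = 1L, n_pop = 2L) {
  if (!is.numeric(fst) || fst < 0 || fst >= 1)
    stop("fst must be in [0, 1)")
  if (ancestral_range[1] < 0 || ancestral_range[2] > 1 ||
      ancestral_range[1] > ancestral_range[2])
    stop("ancestral_range must be an interval within (0, 1)")
  set.seed(seed)
  p <- stats::runif(m, ancestral_range[1], ancestral_range[2])
  pops <- vector("list", n_pop)
  for (k in seq_len(n_pop)) {
    if (fst == 0) {
      pops[[k]] <- p
    } else {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      pops[[k]] <- stats::rbeta(m, a, b)
    }
  }
  list(ancestral = p, pops = pops)
}

#' Simulate genotypes, optionally with LD via founder-haplotype copying
#'
#' Without \code{ld}, dosages are independent Binomial(2, p) per site. With
#' \code{ld = list(pool_size =, recomb_per_bp =)}, a pool of founder
#' haplotypes is drawn site-wise from the frequencies and each sample
#' haplotype is a Li-Stephens-style mosaic copy of the pool: the founder
#' being copied switches between adjacent sites with probability
#' \code{1 - exp(-recomb_per_bp * gap)}, so pairwise r-squared decays with
#' base-pair distance at a controlled rate.
#'
#' @param freqs per-site allele frequencies (counted allele).
#' @param n number of diploid individuals.
#' @param ld \code{NULL} for linkage equilibrium, else a list with
#'   \code{pool_size} and \code{recomb_per_bp}.
#' @param positions strictly increasing base-pair coordinates (required with
#'   \code{ld}); defaults to unit spacing.
#' @param seed integer seed.
#' @return List with \code{dosages} (n x m integer matrix) and
#'   \code{haplotypes} (2n x m 0/1 matrix; \code{NULL} without \code{ld};
#'   rows 2i-1 and 2i are individual i's two haplotypes).
#' @export
simulate_genotypes <- function(freqs, n, ld = NULL, positions = NULL,
                               seed = 1L) {
  stopifnot(n >= 1)
  m <- length(freqs)
  if (is.null(positions)) positions <- seq_len(m)
  if (length(positions) != m) stop("positions length must match freqs")
  if (m > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  set.seed(seed)
  if (is.null(ld)) {
    dos <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
    return(list(dosages = dos, haplotypes = NULL))
  }
  pool <- ld$pool_size
  founders <- matrix(stats::rbinom(pool * m, 1L, rep(freqs, each = pool)),
                     pool, m)
  gaps <- if (m > 1) diff(positions) else numeric(0)
  p_switch <- 1 - exp(-ld$recomb_per_bp * gaps)
  haps <- matrix(0L, 2L * n, m)
  for (h in seq_len(2L * n)) {
    idx <- integer(m)
    idx[1] <- sample.int(pool, 1L)
    if (m > 1) {
      sw <- stats::runif(m - 1) < p_switch
      for (j in 2:m) idx[j] <- if (sw[j - 1]) sample.int(pool, 1L) else idx[j - 1]
    }
    haps[h, ] <- founders[cbind(idx, seq_len(m))]
  }
  dos <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
         haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  list(dosages = dos, haplotypes = haps)
}

#' Validate an HLA haplotype specification
#'
#' The specification is a data frame with one row per classical allele:
#' \code{allele} (name), \code{haplotype} (haplotype class label; alleles
#' sharing a label ride the same simulated chromosome), one frequency column
#' per population (e.g. \code{freq_AJ}, \code{freq_EUNW}), and \code{or}
#' (per-copy odds ratio used by the liability model).
#' @keywords internal
.check_hla_spec <- function(hla_spec, freq_col) {
  if (!freq_col %in% names(hla_spec))
    stop("hla_spec lacks frequency column ", freq_col)
  f <- hla_spec[[freq_col]]
  if (any(f < 0 | f > 1)) stop("HLA haplotype frequencies must be in [0, 1]")
  hf <- tapply(f, hla_spec$haplotype, max)  # per-haplotype frequency
  if (sum(hf) > 1 + 1e-12)
    stop("HLA haplotype frequencies sum to ", round(sum(hf), 4),
         " > 1; no room for the residual 'other' haplotype")
  hf
}

#' Plant classical HLA alleles on simulated haplotypes
#'
#' Each individual receives two haplotype-class draws from the categorical
#' distribution over declared haplotype classes plus a residual "other"
#' class. Alleles declared on the same haplotype class co-occur on the same
#' simulated chromosome, reproducing tight class-I linkage such as
#' B*38:01-C*12:03.
#'
#' @param hla_spec data frame; see Details of \code{\link{simulate_cohort}}.
#' @param n number of individuals.
#' @param freq_col name of the frequency column to use.
#' @param seed integer seed.
#' @return List with \code{dosages} (n x alleles matrix, 0/1/2) and
#'   \code{hap_classes} (n x 2 character matrix of haplotype class labels).
#' @export
plant_hla_haplotypes <- function(hla_spec, n, freq_col = "freq_AJ",
                                 seed = 1L) {
  hf <- .check_hla_spec(hla_spec, freq_col)
  classes <- names(hf)
  probs <- c(as.numeric(hf), 1 - sum(hf))
  labs <- c(classes, ".other")
  set.seed(seed)
  draw <- matrix(sample(labs, 2L * n, replace = TRUE, prob = probs), n, 2L)
  dos <- matrix(0L, n, nrow(hla_spec),
                dimnames = list(NULL, hla_spec$allele))
  for (i in seq_len(nrow(hla_spec))) {
    cl <- hla_spec$haplotype[i]
    present <- hla_spec[[freq_col]][i] > 0
    if (present)
      dos[, i] <- (draw[, 1] == cl) + (draw[, 2] == cl)
  }
  list(dosages = dos, hap_classes = draw)
}

# Shared liability: eta = sum_i w_i d_i over SNP risk variants + HLA allele
# log-ORs; alpha calibrated so the marginal prevalence matches.
.liability <- function(genotypes, hla_dosages, risk_table, hla_spec) {
  eta <- 0
  if (!is.null(risk_table) && nrow(risk_table)) {
    idx <- match(risk_table$variant, colnames(genotypes))
    if (anyNA(idx))
      stop("risk variants absent from genotype matrix: ",
           paste(risk_table$variant[is.na(idx)], collapse = ", "))
    D <- genotypes[, idx, drop = FALSE]
    D[is.na(D)] <- 0
    eta <- eta + as.vector(D %*% risk_table$weight)
  }
  if (!is.null(hla_spec) && !is.null(hla_dosages) && nrow(hla_spec)) {
    idx <- match(hla_spec$allele, colnames(hla_dosages))
    keep <- !is.na(idx)
    if (any(keep))
      eta <- eta + as.vector(hla_dosages[, idx[keep], drop = FALSE] %*%
                               log(hla_spec$or[keep]))
  }
  eta
}

#' Assign case/control labels under a logistic liability model
#'
#' \eqn{P(\mathrm{case} \mid d) = \mathrm{logit}^{-1}(\alpha + \sum_i w_i
#' d_i)} with the intercept \eqn{\alpha} solved numerically so the marginal
#' prevalence over the supplied individuals equals
#' \code{baseline_prevalence}. Labels are drawn independently.
#'
#' @param genotypes n x m dosage matrix with variant ids as column names.
#' @param hla_dosages optional n x alleles HLA dosage matrix.
#' @param risk_table risk-weight table (\code{\link{risk_weight_table}}).
#' @param hla_spec optional HLA spec with \code{allele} and \code{or}.
#' @param baseline_prevalence target marginal case fraction, in (0, 1).
#' @param seed integer seed.
#' @return Integer vector of labels (1 = case, 0 = control).
#' @export
assign_case_status <- function(genotypes, hla_dosages = NULL,
                               risk_table = NULL, hla_spec = NULL,
                               baseline_prevalence = 0.2, seed = 1L) {
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  eta <- .liability(genotypes, hla_dosages, risk_table, hla_spec)
  f <- function(a) mean(stats::plogis(a + eta)) - baseline_prevalence
  alpha <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  set.seed(seed)
  as.integer(stats::runif(nrow(genotypes)) < stats::plogis(alpha + eta))
}

#' Simulate ascertained case-control trios with Mendelian transmission
#'
#' Parents are drawn from per-population haplotype frequencies; each proband
#' inherits, independently at every site, one allele from each parent
#' (an explicitly Mendelian gamete draw). A fraction of trios has exactly
#' one non-AJ parent ("mixed" trios). Probands are ascertained as cases by
#' rejection sampling under the logistic liability model; with a null risk
#' model every conceived child is accepted.
#'
#' @param freqs_aj,freqs_other per-site parental allele frequencies for the
#'   AJ-like and the other population.
#' @param n_trios number of trios.
#' @param fraction_mixed fraction of trios with one non-AJ parent, in [0,1].
#' @param risk_table optional risk-weight table driving ascertainment.
#' @param baseline_prevalence prevalence used by the ascertainment model.
#' @param variant_ids ids for the simulated variants.
#' @param max_reject rejection-sampling cap per trio.
#' @param seed integer seed.
#' @return A \code{trio_set}: list with dosage matrices \code{father},
#'   \code{mother}, \code{proband} (n_trios x m), \code{variant_ids}, and
#'   \code{meta} (data frame with per-parent population labels and the trio
#'   AJ flag: at least one AJ parent).
#' @export
simulate_trio_cohort <- function(freqs_aj, freqs_other = freqs_aj,
                                 n_trios, fraction_mixed = 0,
                                 risk_table = NULL,
                                 baseline_prevalence = 0.2,
                                 variant_ids = NULL, max_reject = 1000L,
                                 seed = 1L) {
  stopifnot(n_trios >= 1)
  if (fraction_mixed < 0 || fraction_mixed > 1)
    stop("fraction_mixed must be in [0, 1]")
  if (!length(freqs_aj)) stop("empty parent frequency pool")
  m <- length(freqs_aj)
  if (is.null(variant_ids)) variant_ids <- paste0("rs", seq_len(m))
  set.seed(seed)
  n_mixed <- round(fraction_mixed * n_trios)
  mixed <- c(rep(TRUE, n_mixed), rep(FALSE, n_trios - n_mixed))

  alpha <- 0
  if (!is.null(risk_table) && nrow(risk_table)) {
    # calibrate the intercept on a parental-population reference sample
    ref <- matrix(stats::rbinom(2000L * m, 2L, rep(freqs_aj, each = 2000L)),
                  2000L, m, dimnames = list(NULL, variant_ids))
    eta_ref <- .liability(ref, NULL, risk_table, NULL)
    alpha <- stats::uniroot(function(a)
      mean(stats::plogis(a + eta_ref)) - baseline_prevalence,
      c(-50, 50), tol = 1e-10)$root
  }
  w <- if (!is.null(risk_table) && nrow(risk_table)) {
    wv <- numeric(m); names(wv) <- variant_ids
    wv[risk_table$variant] <- risk_table$weight
    wv
  } else NULL

  fa <- mo <- ch <- matrix(0L, n_trios, m,
                           dimnames = list(NULL, variant_ids))
  pop_f <- pop_m <- character(n_trios)
  draw_parent <- function(pop) {
    p <- if (pop == "AJ") freqs_aj else freqs_other
    # two phased haplotypes per parent
    rbind(stats::rbinom(m, 1L, p), stats::rbinom(m, 1L, p))
  }
  for (t in seq_len(n_trios)) {
    pop_f[t] <- "AJ"
    pop_m[t] <- if (mixed[t]) "OTHER" else "AJ"
    hf <- draw_parent(pop_f[t])
    hm <- draw_parent(pop_m[t])
    for (att in seq_len(max_reject)) {
      gf <- hf[cbind(sample(1:2, m, replace = TRUE), seq_len(m))]
      gm <- hm[cbind(sample(1:2, m, replace = TRUE), seq_len(m))]
      child <- gf + gm
      if (is.null(w)) break
      if (stats::runif(1) < stats::plogis(alpha + sum(w * child))) break
      if (att == max_reject) break
    }
    fa[t, ] <- hf[1, ] + hf[2, ]
    mo[t, ] <- hm[1, ] + hm[2, ]
    ch[t, ] <- child
  }
  structure(list(
    father = fa, mother = mo, proband = ch, variant_ids = variant_ids,
    meta = data.frame(trio = seq_len(n_trios), pop_father = pop_f,
                      pop_mother = pop_m,
                      aj_trio = pop_f == "AJ" | pop_m == "AJ",
                      stringsAsFactors = FALSE)),
    class = "trio_set")
}

#' @export
print.trio_set <- function(x, ...) {
  cat("trio_set:", nrow(x$father), "trios x", ncol(x$father), "variants;",
      sum(x$meta$aj_trio), "AJ trios\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of the cohort generator. Defaults encode
#' the study conditions the pipeline is designed around: two subpopulations
#' at divergence fst = 0.01, a DRB1*15:01-like risk haplotype at ~2.6%
#' haplotype frequency in the founder population (5% carriers) versus ~10%
#' (15-20% carriers) elsewhere, a linked protective class-I haplotype, and
#' 110 weak non-HLA risk SNPs with odds ratios 1.2-1.4.
#'
#' @param n_per_pop individuals per population.
#' @param m_snps number of background SNPs.
#' @param fst divergence fraction in [0, 1).
#' @param ld_pool_size founder haplotype pool size (\code{NULL}: no LD).
#' @param recomb_per_bp per-base founder switch rate.
#' @param risk_table risk-weight table; default: 110 SNPs, ORs
#'   equally spaced in [1.2, 1.4].
#' @param hla_spec HLA haplotype spec data frame; see
#'   \code{\link{plant_hla_haplotypes}}.
#' @param baseline_prevalence case fraction in (0, 1).
#' @param n_trios number of trios to simulate (0 for none).
#' @param fraction_mixed fraction of trios with one non-AJ parent.
#' @param seed master integer seed; all stage draws derive from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_per_pop = 200L, m_snps = 2000L, fst = 0.01,
                       ld_pool_size = NULL, recomb_per_bp = 1e-8,
                       risk_table = default_risk_table(),
                       hla_spec = default_hla_spec(),
                       baseline_prevalence = 0.2, n_trios = 0L,
                       fraction_mixed = 1 / 3, seed = 1L) {
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  structure(list(n_per_pop = n_per_pop, m_snps = m_snps, fst = fst,
                 ld_pool_size = ld_pool_size, recomb_per_bp = recomb_per_bp,
                 risk_table = risk_table, hla_spec = hla_spec,
                 baseline_prevalence = baseline_prevalence,
                 n_trios = n_trios, fraction_mixed = fraction_mixed,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default 110-variant risk-weight table
#'
#' Emulates the confirmed non-HLA risk catalogue: 110 weak risk SNPs with
#' odds ratios equally spaced across 1.2-1.4.
#' @param n_variants number of risk variants.
#' @param or_range odds-ratio range.
#' @return A \code{\link{risk_weight_table}}.
#' @export
default_risk_table <- function(n_variants = 110L, or_range = c(1.2, 1.4)) {
  risk_weight_table(paste0("risk", seq_len(n_variants)), "A",
                    seq(or_range[1], or_range[2], length.out = n_variants))
}

#' Default HLA haplotype specification
#'
#' One DRB1*15:01-DQB1*06:02 class-II risk haplotype (carrier frequency
#' ~5\% in the founder population, ~15-20\% elsewhere; per-copy OR ~3) and a
#' linked protective class-I haplotype B*38:01-C*12:03, more common in the
#' founder population. Haplotype frequencies q solve carrier = 1-(1-q)^2.
#' @return Data frame with columns allele, haplotype, freq_AJ, freq_EUNW, or.
#' @export
default_hla_spec <- function() {
  q_aj <- 1 - sqrt(1 - 0.05)      # 5% carriers  -> q = 0.0253
  q_eu <- 1 - sqrt(1 - 0.175)     # 17.5% carriers -> q = 0.0917
  data.frame(
    allele = c("DRB1_1501", "DQB1_0602", "B_3801", "C_1203", "A_6802"),
    haplotype = c("DR15", "DR15", "B38C12", "B38C12", "A68"),
    freq_AJ = c(q_aj, q_aj, 0.06, 0.06, 0.04),
    freq_EUNW = c(q_eu, q_eu, 0.015, 0.015, 0.02),
    or = c(3.0, 3.0, 0.7, 0.7, 1.5),
    stringsAsFactors = FALSE)
}

#' Simulate a full study cohort
#'
#' Runs the generator end to end: subpopulation frequencies, genotypes
#' (optionally with LD), HLA dosages, case/control labels, a
#' well-characterized AJ reference panel, and optionally trios. All stage
#' seeds derive from \code{config$seed} through a fixed counter recurrence,
#' so a fixed seed yields a bit-identical cohort.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{sim_cohort}: list with \code{geno}
#'   (\code{\link{geno_matrix}}), \code{haplotypes} (or NULL),
#'   \code{samples} (data frame: sample_id, population, status,
#'   reference_panel), \code{hla} (dosage matrix), \code{freqs} (the drawn
#'   per-population frequencies), \code{trios} (a \code{trio_set} or NULL),
#'   and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  seed <- cfg$seed
  fr <- draw_subpop_freqs(cfg$m_snps, cfg$fst, seed = .sub_seed(seed, 1))
  positions <- sort(sample.int(100e6, cfg$m_snps))  # follows freq draw's RNG
  ld <- if (!is.null(cfg$ld_pool_size))
    list(pool_size = cfg$ld_pool_size, recomb_per_bp = cfg$recomb_per_bp)
  n <- cfg$n_per_pop
  g1 <- simulate_genotypes(fr$pops[[1]], n, ld, positions,
                           seed = .sub_seed(seed, 2))
  g2 <- simulate_genotypes(fr$pops[[2]], n, ld, positions,
                           seed = .sub_seed(seed, 3))
  m_bg <- cfg$m_snps

  # risk SNPs: drawn at the ancestral frequency in both populations so planted
  # effects, not drift, drive case-control contrasts
  rt <- cfg$risk_table
  n_risk <- if (is.null(rt)) 0L else nrow(rt)
  if (n_risk) {
    set.seed(.sub_seed(seed, 4))
    p_risk <- stats::runif(n_risk, 0.2, 0.8)
    r1 <- matrix(stats::rbinom(n * n_risk, 2L, rep(p_risk, each = n)), n)
    r2 <- matrix(stats::rbinom(n * n_risk, 2L, rep(p_risk, each = n)), n)
  }

  dos <- rbind(g1$dosages, g2$dosages)
  ids_bg <- paste0("snp", seq_len(m_bg))
  colnames(dos) <- ids_bg
  if (n_risk) {
    risk_dos <- rbind(r1, r2)
    colnames(risk_dos) <- rt$variant
    dos <- cbind(dos, risk_dos)
  }
  pop <- rep(c("AJ", "EUNW"), each = n)

  hla_aj <- plant_hla_haplotypes(cfg$hla_spec, n, "freq_AJ",
                                 seed = .sub_seed(seed, 5))
  hla_eu <- plant_hla_haplotypes(cfg$hla_spec, n, "freq_EUNW",
                                 seed = .sub_seed(seed, 6))
  hla <- rbind(hla_aj$dosages, hla_eu$dosages)

  status <- assign_case_status(dos, hla, rt, cfg$hla_spec,
                               cfg$baseline_prevalence,
                               seed = .sub_seed(seed, 7))

  # reference panel: a fifth of AJ controls, ethnically well characterized
  set.seed(.sub_seed(seed, 8))
  ref <- rep(FALSE, 2L * n)
  aj_ctrl <- which(pop == "AJ" & status == 0L)
  ref[sample(aj_ctrl, max(1L, length(aj_ctrl) %/% 5L))] <- TRUE

  sample_ids <- sprintf("%s%04d", rep(c("AJ", "EU"), each = n),
                        c(seq_len(n), seq_len(n)))
  variants <- data.frame(
    id = colnames(dos),
    chrom = 1L,
    pos = c(positions,
            if (n_risk) max(positions) + 1e6 * seq_len(n_risk) else NULL),
    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sample_ids, population = pop,
    status = ifelse(status == 1L, "case", "control"),
    reference_panel = ref, stringsAsFactors = FALSE)
  structure(list(geno = geno_matrix(dos, variants, sample_ids),
                 haplotypes = if (!is.null(g1$haplotypes))
                   rbind(g1$haplotypes, g2$haplotypes) else NULL,
                 samples = samples, hla = hla, freqs = fr,
                 trios = if (cfg$n_trios > 0) {
                   # trios carry the risk variants (the markers the family
                   # analyses test); parents of both populations share the
                   # risk-variant frequencies, as in the case-control arms
                   if (n_risk)
                     simulate_trio_cohort(p_risk, p_risk, cfg$n_trios,
                                          cfg$fraction_mixed, rt,
                                          cfg$baseline_prevalence,
                                          variant_ids = rt$variant,
                                          seed = .sub_seed(seed, 9))
                   else
                     simulate_trio_cohort(fr$pops[[1]], fr$pops[[2]],
                                          cfg$n_trios, cfg$fraction_mixed,
                                          NULL, cfg$baseline_prevalence,
                                          variant_ids = ids_bg,
                                          seed = .sub_seed(seed, 9))
                 } else NULL,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$geno$dosages), "samples x",
      ncol(x$geno$dosages), "variants;",
      sum(x$samples$status == "case"), "cases;",
      sum(x$samples$reference_panel), "reference-panel samples\n")
  invisible(x)
}
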