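# Ancestry extraction: genome-wide allele-sharing distance, classical MDS,
# Ward clustering, reference-anchored cluster labelling, trio-member
# classification on PC1, and cohort-level frequency dendrograms.

#' Genome-wide allele-sharing distance
#'
#' d(i, j) = mean over shared non-missing sites of |d_i - d_j| / 2, a
#' deterministic identity-by-state distance in [0, 1] used where the
#' original pipeline consumed haplotype-based IBD sharing: it serves only as
#' the input to MDS and Ward clustering, for which the ordering of distances
#' is what matters.
#'
#' @param G a \code{\link{geno_matrix}} with at least 2 samples and 1 variant.
#' @return Symmetric n x n matrix with zero diagonal and sample-id dimnames.
#' @export
allele_sharing_distance <- function(G) {
  X <- G$dosages
  n <- nrow(X); m <- ncol(X)
  if (n < 2 || m < 1) stop("need >= 2 samples and >= 1 variant")
  if (!anyNA(X)) {
    D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * m)
  } else {
    # pairwise-complete mean |di - dj| / 2 via indicator algebra
    M <- !is.na(X)
    X0 <- X; X0[!M] <- 0
    shared <- M %*% t(M)
    if (any(shared == 0))
      stop("sample pair(s) share zero non-missing sites; distance undefined")
    # |a-b| for dosages in 0..2: sum over the two thresholds t=1,2 of
    # |1[a>=t] - 1[b>=t]| since dosage differences are monotone
    S <- matrix(0, n, n)
    for (t in 1:2) {
      A <- (X0 >= t) & M
      # count of sites where exactly one of the pair exceeds t (both present)
      A1 <- A + 0
      S <- S + A1 %*% t(M - A1) + (M - A1) %*% t(A1)
    }
    D <- S / (2 * shared)
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering plus eigendecomposition of the squared-distance matrix.
#' For a Euclidean-embeddable distance matrix the pairwise distances among
#' the returned coordinates reproduce the input exactly. The sign of each
#' axis is arbitrary; see \code{\link{classify_trio_members}} for the
#' reference-anchored orientation of PC1.
#'
#' @param D symmetric distance matrix.
#' @param k number of dimensions requested (default 50); silently reduced
#'   (with a warning) to the number of positive eigenvalues.
#' @return List with \code{points} (n x k' coordinates, columns ordered by
#'   decreasing eigenvalue), \code{eig} (all eigenvalues) and \code{k}.
#' @export
classical_mds <- function(D, k = 50L) {
  if (k < 1) stop("k must be >= 1")
  n <- nrow(D)
  k_try <- min(k, n - 1L)
  fit <- stats::cmdscale(stats::as.dist(D), k = k_try, eig = TRUE)
  npos <- sum(fit$eig > 1e-9)
  if (npos < k)
    warning("only ", npos, " positive eigenvalues; returning ",
            min(k_try, npos), " dimensions instead of ", k)
  kk <- max(1L, min(k_try, npos))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) == 0)
    pts <- matrix(0, n, 1, dimnames = list(rownames(D), NULL))
  pts <- pts[, seq_len(min(kk, ncol(pts))), drop = FALSE]
  rownames(pts) <- rownames(D)
  list(points = pts, eig = fit$eig, k = ncol(pts))
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative Ward linkage in the Ward.D2 convention (Lance-Williams
#' update on squared distances), as used to resolve population clusters from
#' genome-wide sharing distances.
#'
#' @param D symmetric distance matrix (n >= 2).
#' @return An \code{hclust} tree.
#' @export
ward_tree <- function(D) {
  if (nrow(D) < 2) stop("need at least 2 samples to cluster")
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Label clusters from a reference panel
#'
#' Cuts the tree into K clusters; the cluster holding the largest fraction
#' of the reference-panel AJ samples is labelled AJ, the largest remaining
#' cluster EUNW, and all others OTHER. Reference samples keep their known
#' label.
#'
#' @param tree an \code{hclust} tree over samples.
#' @param K number of clusters to cut (default 3).
#' @param reference named character vector: sample id -> known label for the
#'   reference-panel samples (must contain at least one "AJ").
#' @return Data frame with \code{sample_id}, \code{cluster}, \code{label}.
#' @export
label_clusters <- function(tree, K = 3L, reference) {
  if (is.null(reference) || !length(reference) || !any(reference == "AJ"))
    stop("reference panel with at least one AJ sample required")
  cl <- stats::cutree(tree, k = K)
  ids <- names(cl)
  ref_aj <- names(reference)[reference == "AJ"]
  ref_aj <- intersect(ref_aj, ids)
  if (!length(ref_aj)) stop("no reference AJ sample present in the tree")
  frac <- tapply(ids %in% ref_aj, cl, mean)
  top <- sort(frac, decreasing = TRUE)
  if (length(top) > 1 && top[1] > 0 && isTRUE(all.equal(top[1], top[2])))
    stop("reference panel split evenly across clusters; ",
         "enlarge the panel or change K")
  aj_cluster <- as.integer(names(which.max(frac)))
  sizes <- table(cl)
  rest <- setdiff(as.integer(names(sizes)), aj_cluster)
  eunw_cluster <- if (length(rest))
    rest[which.max(sizes[as.character(rest)])] else integer(0)
  label <- rep("OTHER", length(cl))
  label[cl == aj_cluster] <- "AJ"
  label[cl %in% eunw_cluster] <- "EUNW"
  ref_known <- intersect(names(reference), ids)
  label[match(ref_known, ids)] <- unname(reference[ref_known])
  data.frame(sample_id = ids, cluster = unname(cl), label = label,
             stringsAsFactors = FALSE)
}

#' Classify trio members on the first MDS axis
#'
#' PC1 is first oriented so the reference-AJ mean is positive. A member is
#' called AJ iff its oriented PC1 exceeds the threshold (default: midpoint
#' of the reference AJ and reference EUNW PC1 means). A trio is flagged AJ
#' iff at least one parent is AJ; trios with a missing parent are skipped.
#'
#' @param coords MDS result from \code{\link{classical_mds}} (or a matrix
#'   whose first column is PC1) over all trio members.
#' @param reference named character vector sample id -> "AJ"/"EUNW" for the
#'   anchoring samples.
#' @param trios data frame with columns \code{father}, \code{mother},
#'   \code{proband} (sample ids).
#' @param threshold optional PC1 cutoff overriding the midpoint default.
#' @return List with \code{members} (sample_id, pc1, label) and \code{trios}
#'   (the input plus \code{aj_trio}; skipped trios carry NA).
#' @export
classify_trio_members <- function(coords, reference, trios,
                                  threshold = NULL) {
  pts <- if (is.list(coords) && !is.null(coords$points)) coords$points
         else as.matrix(coords)
  pc1 <- pts[, 1]
  names(pc1) <- rownames(pts)
  ref_aj <- intersect(names(reference)[reference == "AJ"], names(pc1))
  ref_eu <- intersect(names(reference)[reference == "EUNW"], names(pc1))
  if (!length(ref_aj)) stop("need reference AJ samples to orient PC1")
  if (mean(pc1[ref_aj]) < 0) pc1 <- -pc1
  if (is.null(threshold)) {
    if (!length(ref_eu))
      stop("need reference EUNW samples (or an explicit threshold)")
    threshold <- (mean(pc1[ref_aj]) + mean(pc1[ref_eu])) / 2
  }
  members <- data.frame(sample_id = names(pc1), pc1 = unname(pc1),
                        label = ifelse(pc1 > threshold, "AJ", "EUNW"),
                        stringsAsFactors = FALSE)
  lab <- function(id) members$label[match(id, members$sample_id)]
  aj_trio <- logical(nrow(trios))
  for (i in seq_len(nrow(trios))) {
    lf <- lab(trios$father[i]); lm <- lab(trios$mother[i])
    if (is.na(lf) || is.na(lm)) {
      aj_trio[i] <- NA
      message("trio ", i, " skipped: missing parent coordinates")
    } else aj_trio[i] <- lf == "AJ" || lm == "AJ"
  }
  trios$aj_trio <- aj_trio
  list(members = members, trios = trios, threshold = threshold)
}

#' Ward dendrogram of cohorts from genome-wide allele frequencies
#'
#' Computes the Euclidean distance between per-cohort allele-frequency
#' vectors over a shared variant set, scaled by 1/sqrt(m) so the height is
#' a per-SNP root-mean-square frequency difference, and clusters cohorts by
#' Ward linkage.
#'
#' @param freq_matrix cohorts x variants matrix of allele frequencies
#'   (rownames are cohort labels).
#' @return An \code{hclust} tree over cohorts.
#' @export
cohort_frequency_dendrogram <- function(freq_matrix) {
  freq_matrix <- as.matrix(freq_matrix)
  if (nrow(freq_matrix) < 2) stop("need >= 2 cohorts")
  if (anyNA(freq_matrix))
    stop("cohorts must share the variant set (no missing frequencies)")
  m <- ncol(freq_matrix)
  D <- stats::dist(freq_matrix) / sqrt(m)
  stats::hclust(D, method = "ward.D2")
}
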