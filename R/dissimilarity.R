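# Intra- vs inter-cluster structural similarity: Euclidean, Gaussian and
# Wasserstein dissimilarities on the per-structure pairwise-distance
# vectors, and their log2 inter/intra ratios.

# Upper-triangle center-distance vectors, one column per structure.
pair_distance_vectors <- function(structures) {
  mats <- lapply(structures, function(s) {
    m <- center_distance_matrix(coords_of(s))
    m[upper.tri(m)]
  })
  do.call(cbind, mats)
}

sample_cols <- function(n, size, seed) {
  if (n <= size) return(seq_len(n))
  set.seed(seed)
  sort(sample.int(n, size))
}

new_dissimilarity_report <- function(measure, inter, intra) {
  structure(list(measure = measure, inter = inter, intra = intra,
                 log2_ratio = log2(inter / intra)),
            class = "dissimilarity_report")
}

#' @export
print.dissimilarity_report <- function(x, ...) {
  cat(sprintf("<%s dissimilarity: inter %.4g, intra %.4g, log2 ratio %.3f>\n",
              x$measure, x$inter, x$intra, x$log2_ratio))
  invisible(x)
}

#' Euclidean distance dissimilarity between two clusters
#'
#' For structures `a`, `b` the dissimilarity is the Euclidean norm of the
#' difference of their flattened pairwise-distance vectors; the cluster
#' value averages over all cross pairs of (up to `sample`) structures drawn
#' from each cluster. Intra-cluster values average over distinct pairs
#' within the sampled cluster. The report includes
#' `log2(s(A,B) / s(A,A))`.
#'
#' @param A,B Lists of structures ([chrom_structure()] or coordinate
#'   matrices) with a common bead count.
#' @param sample Structures sampled per cluster (200 in the reference
#'   analysis).
#' @param seed Sampling seed.
#' @return A `dissimilarity_report`.
#' @export
euclidean_dissimilarity <- function(A, B, sample = 200, seed = 1L) {
  RA <- pair_distance_vectors(A)
  RB <- pair_distance_vectors(B)
  if (nrow(RA) != nrow(RB)) stop("structures must share bead count")
  same <- identical(A, B)
  RA <- RA[, sample_cols(ncol(RA), sample, seed), drop = FALSE]
  RB <- RB[, sample_cols(ncol(RB), sample, seed + 1L), drop = FALSE]
  # when A and B are one set, the "inter" value uses distinct pairs only,
  # mirroring the intra computation (so the log2 ratio is 0 by construction)
  inter <- if (same) intra_mean_euclid(RA) else mean(cross_euclid(RA, RB))
  new_dissimilarity_report("euclidean", inter = inter,
                           intra = intra_mean_euclid(RA))
}

# ||R_a - R_b|| for all column pairs via the Gram-matrix identity.
cross_euclid <- function(RA, RB) {
  sa <- colSums(RA^2); sb <- colSums(RB^2)
  g2 <- outer(sa, sb, "+") - 2 * crossprod(RA, RB)
  sqrt(pmax(g2, 0))
}

intra_mean_euclid <- function(R) {
  E <- cross_euclid(R, R)
  mean(E[upper.tri(E)])
}

#' Gaussian dissimilarity between two clusters
#'
#' `s_g(a, b) = 1 - mean_{i<j} exp(-(d_ij(a) - d_ij(b))^2 / (2 sigma^2))`
#' with `sigma = 8 R_bead` by default: 0 for identical structures,
#' approaching 1 when all pair distances differ grossly. Cluster averaging,
#' sampling and the log2 ratio as in [euclidean_dissimilarity()].
#'
#' @inheritParams euclidean_dissimilarity
#' @param sigma Distance-difference scale in nm (default `8 * 118`).
#' @return A `dissimilarity_report`.
#' @export
gaussian_dissimilarity <- function(A, B, sigma = 8 * 118, sample = 200,
                                   seed = 1L) {
  if (sigma <= 0) stop("sigma must be positive")
  RA <- pair_distance_vectors(A)
  RB <- pair_distance_vectors(B)
  if (nrow(RA) != nrow(RB)) stop("structures must share bead count")
  RA <- RA[, sample_cols(ncol(RA), sample, seed), drop = FALSE]
  RB <- RB[, sample_cols(ncol(RB), sample, seed + 1L), drop = FALSE]
  same <- identical(A, B)
  intra_vals <- c()
  for (a in seq_len(ncol(RA) - 1)) {
    rest <- RA[, (a + 1):ncol(RA), drop = FALSE]
    intra_vals <- c(intra_vals,
                    1 - colMeans(exp(-(rest - RA[, a])^2 / (2 * sigma^2))))
  }
  intra <- if (length(intra_vals)) mean(intra_vals) else NA_real_
  inter <- if (same) intra else mean(vapply(seq_len(ncol(RA)), function(a) {
    mean(1 - colMeans(exp(-(RB - RA[, a])^2 / (2 * sigma^2))))
  }, 0))
  new_dissimilarity_report("gaussian", inter = inter, intra = intra)
}

# 1-Wasserstein distance between two equal-size empirical samples per row:
# mean absolute difference of the row-sorted matrices.
row_wasserstein <- function(DA, DB) {
  if (ncol(DA) == ncol(DB)) {
    SA <- t(apply(DA, 1, sort))
    SB <- t(apply(DB, 1, sort))
    rowMeans(abs(SA - SB))
  } else {
    vapply(seq_len(nrow(DA)),
           function(i) wasserstein1(DA[i, ], DB[i, ]), 0)
  }
}

#' 1-Wasserstein distance between two empirical distributions
#'
#' Integral of the absolute difference of the two empirical CDFs.
#'
#' @param u,v Numeric samples.
#' @return The distance (same units as the samples).
#' @export
wasserstein1 <- function(u, v) {
  all_s <- sort(c(u, v))
  deltas <- diff(all_s)
  cu <- stats::ecdf(u)(all_s[-length(all_s)])
  cv <- stats::ecdf(v)(all_s[-length(all_s)])
  sum(abs(cu - cv) * deltas)
}

#' Wasserstein distance dissimilarity between two clusters
#'
#' For every bead pair `(i, j)` the 1-Wasserstein distance between the
#' distribution of `d_ij` over cluster A and over cluster B, averaged over
#' pairs. The intra-cluster value splits cluster A into a random half
#' (indices `i`) and the reversed complementary half (indices `M - i - 1`).
#'
#' @inheritParams euclidean_dissimilarity
#' @param seed Seed for the intra-cluster split.
#' @return A `dissimilarity_report`.
#' @export
wasserstein_dissimilarity <- function(A, B, seed = 1L) {
  if (length(A) < 2) stop("intra-cluster split needs at least 2 structures")
  DA <- pair_distance_vectors(A)
  DB <- pair_distance_vectors(B)
  if (nrow(DA) != nrow(DB)) stop("structures must share bead count")
  inter <- mean(row_wasserstein(DA, DB))
  M <- ncol(DA)
  set.seed(seed)
  half <- sample.int(M, M %/% 2) - 1L           # 0-based indices i
  other <- M - half - 1L                        # reversed complement M-i-1
  intra <- mean(row_wasserstein(DA[, half + 1L, drop = FALSE],
                                DA[, other + 1L, drop = FALSE]))
  new_dissimilarity_report("wasserstein", inter = inter, intra = intra)
}

#' Pairwise log2 inter/intra dissimilarity matrix
#'
#' Entry `(A, B)` is `log2(s(A, B) / s(A, A))` -- the inter-cluster
#' dissimilarity normalized row-wise by cluster A's intra value. The
#' diagonal is 0 by construction; positive off-diagonal values indicate
#' structures are more similar within than between clusters.
#'
#' @param clusters Named list of structure sets.
#' @param measure `"wasserstein"`, `"euclidean"` or `"gaussian"`.
#' @param ... Passed to the measure function (`sample`, `seed`, `sigma`).
#' @return K x K numeric matrix.
#' @export
dissimilarity_matrix <- function(clusters,
                                 measure = c("wasserstein", "euclidean",
                                             "gaussian"), ...) {
  measure <- match.arg(measure)
  if (length(clusters) < 2) stop("need at least 2 clusters")
  fn <- switch(measure, wasserstein = wasserstein_dissimilarity,
               euclidean = euclidean_dissimilarity,
               gaussian = gaussian_dissimilarity)
  K <- length(clusters)
  out <- matrix(0, K, K, dimnames = list(names(clusters), names(clusters)))
  intra <- vapply(clusters, function(cl) fn(cl, cl, ...)$intra, 0)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    rep_ <- fn(clusters[[a]], clusters[[b]], ...)
    out[a, b] <- log2(rep_$inter / intra[a])
  }
  out
}
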