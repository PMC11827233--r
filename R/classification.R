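# Classification of external single-cell observations against detected
# clusters: sci-Hi-C imputation (convolution + random walk with restart),
# mask-based contact scoring with randomized controls, and correlation
# scoring of chromatin-tracing structures.

# (2w+1) x (2w+1) box convolution with zero padding, separable.
box_convolve <- function(M, w) {
  if (w == 0) return(M)
  n <- nrow(M)
  pass <- function(X) {
    cs <- rbind(0, apply(X, 2, cumsum))
    hi <- pmin(seq_len(n) + w, n) + 1L
    lo <- pmax(seq_len(n) - w, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  t(pass(t(pass(M))))
}

#' Impute a sparse single-cell Hi-C matrix
#'
#' Three-stage imputation of a raw single-cell contact matrix:
#' (1) convolution with a `(2w+1) x (2w+1)` box filter (w = 5 for 200-kb
#' matrices), integrating contacts from genomic neighbours; (2) row
#' normalization into a transition matrix and a random walk with restart,
#' `R_t = (1-p) R_{t-1} M + p I` from `R_0 = I`, iterated until the
#' Frobenius norm of the update is at most `tol`; (3) per-row binarization
#' keeping entries above the row's 75th percentile.
#'
#' @param raw Square matrix of raw contact counts.
#' @param w Convolution half-width.
#' @param restart_p Restart probability.
#' @param tol Convergence tolerance on `||R_t - R_(t-1)||_F`.
#' @param percentile Row binarization quantile.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param return_stages Also return the intermediate matrices.
#' @return Binary matrix (list of stages when `return_stages`).
#' @export
impute_scihic <- function(raw, w = 5, restart_p = 0.5, tol = 1e-6,
                          percentile = 0.75, max_iter = 10000,
                          return_stages = FALSE) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  if (n != ncol(raw)) stop("matrix must be square")
  conv <- box_convolve(raw, w)
  rs <- rowSums(conv)
  zero <- rs == 0
  if (any(zero)) warning(sum(zero), " all-zero row(s) left zero")
  rs[zero] <- 1
  trans <- conv / rs
  R <- diag(n)
  p <- restart_p
  pI <- p * diag(n)
  for (it in seq_len(max_iter)) {
    Rn <- (1 - p) * (R %*% trans) + pI
    res <- sqrt(sum((Rn - R)^2))
    R <- Rn
    if (res <= tol) break
    if (it == max_iter)
      stop("random walk did not converge: residual ", format(res))
  }
  bin <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    q <- quantile(R[i, ], percentile, names = FALSE)
    bin[i, ] <- as.integer(R[i, ] > q)
  }
  if (return_stages)
    list(conv = conv, trans = trans, rwr = R, binarized = bin)
  else bin
}

#' Superiority / inferiority contact masks of a cluster
#'
#' From the size-normalized difference matrix
#' `d_ij = log2(S_A m^Pop_ij / (S_Pop m^A_ij))`: the superiority mask marks
#' entries with `d >= 5` (contacts strongly depleted in the cluster relative
#' to the population), the inferiority mask entries with `d <= -1` (contacts
#' enriched in the cluster). Entries where either matrix is zero are
#' undefined and belong to neither mask.
#'
#' @param cm_cluster,cm_pop Contact frequency matrices of the cluster and
#'   the whole population (same shape).
#' @param S_A,S_pop Numbers of structures behind each matrix.
#' @param sup_threshold,inf_threshold Mask thresholds on `d`.
#' @return List of class `cluster_masks`: `sup`, `inf` (binary matrices),
#'   `d` (difference matrix, `NA` where undefined).
#' @export
build_masks <- function(cm_cluster, cm_pop, S_A, S_pop, sup_threshold = 5,
                        inf_threshold = -1) {
  if (!all(dim(cm_cluster) == dim(cm_pop))) stop("matrices must share shape")
  d <- log2((S_A * cm_pop) / (S_pop * cm_cluster))
  d[cm_pop == 0 | cm_cluster == 0] <- NA_real_
  sup <- (!is.na(d) & d >= sup_threshold) * 1L
  inf <- (!is.na(d) & d <= inf_threshold) * 1L
  structure(list(sup = sup, inf = inf, d = d), class = "cluster_masks")
}

#' Score a binarized single-cell matrix against cluster masks
#'
#' `s^(A) = exp(<M, M_inf>/<E, M_inf> - <M, M_sup>/<E, M_sup>)` (Frobenius
#' inner products; an empty mask contributes 0 with a warning). The cell is
#' assigned to the top-scoring cluster only when the top-two score margin is
#' at least `margin`; matching probabilities normalize the scores over
#' clusters.
#'
#' @param cell Binarized contact matrix (from [impute_scihic()]).
#' @param masks Named list of [build_masks()] results, one per cluster.
#' @param margin Minimum top-two score difference for assignment.
#' @return List of class `assignment_result`: `scores`, `probabilities`,
#'   `assigned` (cluster name or `NA`), `margin`.
#' @export
score_scihic <- function(cell, masks, margin = 0.01) {
  frac <- function(M, mask) {
    tot <- sum(mask)
    if (tot == 0) {
      warning("empty mask: term set to 0")
      return(0)
    }
    sum(M * mask) / tot
  }
  s <- vapply(masks, function(mk)
    exp(frac(cell, mk$inf) - frac(cell, mk$sup)), 0)
  ord <- order(s, decreasing = TRUE)
  top_margin <- if (length(s) > 1) s[ord[1]] - s[ord[2]] else Inf
  assigned <- if (top_margin >= margin) names(s)[ord[1]] else NA_character_
  structure(list(scores = s, probabilities = s / sum(s),
                 assigned = assigned, margin = top_margin),
            class = "assignment_result")
}

#' Randomized control for a single-cell contact matrix
#'
#' Permutes the off-diagonal upper-triangle entries uniformly at random and
#' mirrors them, keeping the diagonal and the total contact count intact.
#'
#' @param raw Symmetric raw contact matrix.
#' @param seed Permutation seed.
#' @return Shuffled symmetric matrix.
#' @export
randomize_control <- function(raw, seed = 1L) {
  set.seed(seed)
  ut <- upper.tri(raw)
  v <- raw[ut]
  out <- raw
  out[ut] <- sample(v)
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Symmetrize a contact matrix by the pairwise minimum
#' @param CM Square matrix.
#' @return `min(CM, t(CM))` elementwise.
#' @export
symmetrize_min <- function(CM) pmin(CM, t(CM))

#' Classify a single structure against cluster average distance matrices
#'
#' The structure's distance matrix and each cluster's average distance
#' matrix (downsampled to the structure's loci beforehand) are flattened to
#' their upper triangles, min-max normalized, and compared by Pearson
#' correlation; the score is `exp(r)`. Assignment requires a top-two margin
#' of at least `margin` (0.05 for tracing data). The score is invariant to
#' global scaling of the input coordinates.
#'
#' @param x Structure coordinates (n x 3) or a precomputed distance matrix.
#' @param cluster_dms Named list of cluster average distance matrices at the
#'   structure's loci.
#' @param margin Minimum top-two score difference.
#' @return An `assignment_result` (see [score_scihic()]).
#' @export
classify_structure <- function(x, cluster_dms, margin = 0.05) {
  DM <- if (is.matrix(x) && nrow(x) == ncol(x) && ncol(x) != 3) x
        else center_distance_matrix(coords_of(x))
  if (nrow(DM) < 3) stop("need at least 3 loci")
  flatnorm <- function(m) {
    v <- m[upper.tri(m)]
    (v - min(v)) / (max(v) - min(v))
  }
  R <- flatnorm(DM)
  s <- vapply(cluster_dms, function(dm) {
    if (!all(dim(dm) == dim(DM)))
      stop("cluster matrix shape does not match the structure's loci")
    exp(cor(R, flatnorm(dm)))
  }, 0)
  ord <- order(s, decreasing = TRUE)
  top_margin <- if (length(s) > 1) s[ord[1]] - s[ord[2]] else Inf
  assigned <- if (top_margin >= margin) names(s)[ord[1]] else NA_character_
  structure(list(scores = s, probabilities = s / sum(s),
                 assigned = assigned, margin = top_margin),
            class = "assignment_result")
}

#' Per-cluster transcription log-ratio at a locus
#'
#' `log2` of the mean transcription-on count in the cluster's copies at the
#' locus over the mean across all clustered copies.
#'
#' @param trans_counts Numeric vector of transcription-on counts at the
#'   locus, one per copy.
#' @param labels Cluster labels per copy (`NA` = unclustered).
#' @return Named numeric vector of log2 ratios per cluster.
#' @export
transcription_ratio <- function(trans_counts, labels) {
  keep <- !is.na(labels)
  overall <- mean(trans_counts[keep])
  if (!is.finite(overall) || overall == 0) {
    warning("zero overall transcription mean")
    return(setNames(rep(NA_real_, length(unique(labels[keep]))),
                    sort(unique(labels[keep]))))
  }
  cl <- sort(unique(labels[keep]))
  vapply(setNames(cl, cl), function(k)
    log2(mean(trans_counts[keep][labels[keep] == k]) / overall), 0)
}
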