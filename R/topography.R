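# Nuclear-topography features: speckle prediction by Markov clustering of
# the A1 interaction network, speckle distance / SON TSA-seq / SAF tracks,
# and inter-chromosomal proximity maps and profiles.

#' Markov clustering of a graph
#'
#' Native Markov Cluster Algorithm: the column-stochastic adjacency matrix
#' (with self loops) is alternately expanded (matrix power 2) and inflated
#' (elementwise power, then re-normalized), with small entries pruned, until
#' the matrix is (numerically) idempotent. Clusters are read off the
#' attractor structure.
#'
#' @param adjacency Symmetric (weighted) adjacency matrix.
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @return Integer membership vector (cluster id per node).
#' @export
mcl_cluster <- function(adjacency, inflation = 2, expansion = 2,
                        prune = 1e-5, max_iter = 100) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (n == 0) return(integer(0))
  diag(A) <- pmax(diag(A), 1)           # self loops
  normalize <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    Minf <- normalize(Minf)
    if (max(abs(Minf - M)) < 1e-8) { M <- Minf; break }
    M <- Minf
  }
  # connected components of the limit support define the clusters
  supp <- (M > 0) | (t(M) > 0)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[u] > 0L) next
      comp[u] <- cur
      stack <- c(stack, which(supp[u, ] & comp == 0L))
    }
  }
  comp
}

#' Predict nuclear speckle locations in a single cell
#'
#' A chromatin interaction network is built over the beads annotated as A1
#' subcompartment (edges where the center distance is at most
#' `edge_threshold`, default `4 R_bead`); Markov clustering partitions the
#' network, and every subgraph with more than 3 nodes yields a speckle at
#' the geometric center of its member beads.
#'
#' @param coords N x 3 coordinate matrix of one genome structure (nm).
#' @param a1 Logical or integer index of A1 beads.
#' @param R_bead Bead radius in nm.
#' @param edge_threshold Edge distance threshold in nm.
#' @param inflation MCL inflation.
#' @param min_nodes Minimum subgraph size (exclusive; default keeps > 3).
#' @return Object of class `speckle_set`: `centers` (k x 3 matrix),
#'   `sizes`, `members` (list of bead indices).
#' @export
predict_speckles <- function(coords, a1, R_bead = 118,
                             edge_threshold = 4 * R_bead, inflation = 2,
                             min_nodes = 3) {
  idx <- if (is.logical(a1)) which(a1) else as.integer(a1)
  if (!length(idx))
    return(structure(list(centers = matrix(0, 0, 3), sizes = integer(0),
                          members = list()), class = "speckle_set"))
  X <- coords[idx, , drop = FALSE]
  D <- as.matrix(dist(X))
  A <- (D <= edge_threshold) * 1
  diag(A) <- 0
  memb <- mcl_cluster(A, inflation = inflation)
  centers <- NULL; sizes <- integer(0); members <- list()
  for (k in sort(unique(memb))) {
    sel <- which(memb == k)
    if (length(sel) <= min_nodes) next
    centers <- rbind(centers, colMeans(X[sel, , drop = FALSE]))
    sizes <- c(sizes, length(sel))
    members[[length(members) + 1L]] <- idx[sel]
  }
  if (is.null(centers)) centers <- matrix(0, 0, 3)
  structure(list(centers = centers, sizes = sizes, members = members),
            class = "speckle_set")
}

# Surface-to-center distances of every bead to its nearest speckle (nm);
# NA when the structure has no speckle.
nearest_speckle_distance <- function(coords, speckles, R_bead = 118,
                                     convention = c("surface", "center")) {
  convention <- match.arg(convention)
  if (nrow(speckles$centers) == 0) return(rep(NA_real_, nrow(coords)))
  d <- vapply(seq_len(nrow(speckles$centers)), function(l)
    sqrt(rowSums(sweep(coords, 2, speckles$centers[l, ])^2)),
    numeric(nrow(coords)))
  dmin <- if (is.matrix(d)) apply(d, 1, min) else d
  if (convention == "surface") dmin - R_bead else dmin
}

#' Mean speckle-distance track of a cluster (SpD)
#'
#' Distance from the surface of each chromatin region to its nearest
#' predicted speckle, averaged over the cluster's structures. Structures
#' without any predicted speckle are excluded with a warning.
#'
#' @param structures List of per-structure bead coordinate matrices for the
#'   target chromosome (nm).
#' @param speckles List of `speckle_set` objects, parallel to `structures`.
#' @param R_bead Bead radius in nm.
#' @param convention `"surface"` (default) or `"center"`.
#' @return Numeric per-bin track in nm.
#' @export
speckle_distance_track <- function(structures, speckles, R_bead = 118,
                                   convention = "surface") {
  n <- nrow(coords_of(structures[[1]]))
  D <- matrix(vapply(seq_along(structures), function(a)
    nearest_speckle_distance(coords_of(structures[[a]]), speckles[[a]],
                             R_bead, convention), numeric(n)), nrow = n)
  if (anyNA(D)) warning("structures without speckles excluded from SpD")
  rowMeans(D, na.rm = TRUE)
}

#' Predicted SON TSA-seq track
#'
#' Per-structure signal of region `i` is `sum_l exp(-k d_il)` over all
#' predicted speckles `l`, with distances in micrometers and decay constant
#' `k = 4` per micrometer; the cluster signal averages over structures and
#' is reported as `log2(sg_i / mean(sg))` against the genome-wide mean.
#'
#' @inheritParams speckle_distance_track
#' @param k Exponential decay constant per micrometer.
#' @return List: `signal` (mean raw signal per bin), `track`
#'   (log2-normalized TSA-seq).
#' @export
son_tsaseq_track <- function(structures, speckles, k = 4, R_bead = 118) {
  n <- nrow(coords_of(structures[[1]]))
  sg <- rowMeans(matrix(vapply(seq_along(structures), function(a) {
    X <- coords_of(structures[[a]])
    ctr <- speckles[[a]]$centers
    if (nrow(ctr) == 0) return(rep(0, n))
    rowSums(matrix(vapply(seq_len(nrow(ctr)), function(l) {
      d <- (sqrt(rowSums(sweep(X, 2, ctr[l, ])^2)) - R_bead) / 1000  # um
      exp(-k * d)
    }, numeric(n)), nrow = n))
  }, numeric(n)), nrow = n))
  list(signal = sg, track = log2(sg / mean(sg)))
}

#' Speckle association frequency track (SAF)
#'
#' Fraction of structures in which a region's surface lies within `d_t` of
#' the nearest speckle center (1000 nm for model structures, 500 nm for
#' tracing data).
#'
#' @inheritParams speckle_distance_track
#' @param d_t Association threshold in nm.
#' @return Numeric per-bin track in `[0, 1]`.
#' @export
saf_track <- function(structures, speckles, d_t = 1000, R_bead = 118) {
  n <- nrow(coords_of(structures[[1]]))
  counts <- rowSums(matrix(vapply(seq_along(structures), function(a) {
    d <- nearest_speckle_distance(coords_of(structures[[a]]), speckles[[a]],
                                  R_bead, "surface")
    !is.na(d) & d < d_t
  }, logical(n)), nrow = n))
  counts / length(structures)
}

# Bead selectors on a genome bead table.
beads_of <- function(bead_table, chrom, copy = NULL) {
  sel <- bead_table$chrom == chrom
  if (!is.null(copy)) sel <- sel & bead_table$copy == copy
  which(sel)
}

#' Proximity frequency map of a target chromosome
#'
#' Fraction of structures in which a target-chromosome bead lies within
#' `R_soft` (2000 nm) of each genome bin. The intra-chromosomal part is
#' computed from the same homolog copy only; inter-chromosomal parts are
#' averaged over both homolog copies of target and partner.
#'
#' @param structures List of whole-genome N x 3 coordinate matrices.
#' @param bead_table Bead table (`chrom`, `copy`, `start`) matching the
#'   coordinate rows.
#' @param target_chrom Target chromosome identifier.
#' @param R_soft Proximity range in nm.
#' @return Matrix (target bins x genome bins) of proximity frequencies in
#'   `[0, 1]`, with column names `chrom:bin`.
#' @export
proximity_map <- function(structures, bead_table, target_chrom,
                          R_soft = 2000) {
  chroms <- unique(bead_table$chrom)
  tgt0 <- beads_of(bead_table, target_chrom, 0)
  tgt1 <- beads_of(bead_table, target_chrom, 1)
  nt <- length(tgt0)
  bins_by_chrom <- lapply(chroms, function(ch)
    list(c0 = beads_of(bead_table, ch, 0), c1 = beads_of(bead_table, ch, 1)))
  names(bins_by_chrom) <- chroms
  nbins_total <- sum(vapply(bins_by_chrom, function(b) length(b$c0), 0L))
  acc <- matrix(0, nt, nbins_total)
  for (X in structures) {
    per_copy <- lapply(list(tgt0, tgt1), function(tsel) {
      Xi <- X[tsel, , drop = FALSE]
      row_blocks <- lapply(chroms, function(ch) {
        b <- bins_by_chrom[[ch]]
        if (ch == target_chrom) {
          # intra: same copy as the target rows
          same <- if (identical(tsel, tgt0)) b$c0 else b$c1
          prox_block(Xi, X[same, , drop = FALSE], R_soft)
        } else {
          (prox_block(Xi, X[b$c0, , drop = FALSE], R_soft) +
             prox_block(Xi, X[b$c1, , drop = FALSE], R_soft)) / 2
        }
      })
      do.call(cbind, row_blocks)
    })
    acc <- acc + (per_copy[[1]] + per_copy[[2]]) / 2
  }
  pm <- acc / length(structures)
  colnames(pm) <- unlist(lapply(chroms, function(ch)
    paste0(ch, ":", seq_along(bins_by_chrom[[ch]]$c0))))
  attr(pm, "chrom") <- rep(chroms,
                           vapply(bins_by_chrom, function(b) length(b$c0), 0L))
  pm
}

prox_block <- function(A, B, R_soft) {
  sa <- rowSums(A^2); sb <- rowSums(B^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(A, B)
  (d2 <= R_soft^2) * 1
}

#' Inter-chromosomal proximity profile (IPP)
#'
#' Per-bin count of inter-chromosomal proximities within `R_soft`, divided
#' by the number of structures, averaged over both homolog copies of the
#' target chromosome.
#'
#' @inheritParams proximity_map
#' @param partners Partner chromosomes (`"genome"` scope: all chromosomes
#'   except the target, the default).
#' @return Numeric per-bin track.
#' @export
ipp_track <- function(structures, bead_table, target_chrom, partners = NULL,
                      R_soft = 2000) {
  chroms <- setdiff(unique(bead_table$chrom), target_chrom)
  if (!is.null(partners)) chroms <- intersect(chroms, partners)
  tgt <- list(beads_of(bead_table, target_chrom, 0),
              beads_of(bead_table, target_chrom, 1))
  part <- which(bead_table$chrom %in% chroms)
  nt <- length(tgt[[1]])
  acc <- numeric(nt)
  for (X in structures) {
    Xp <- X[part, , drop = FALSE]
    cnt <- (rowSums(prox_block(X[tgt[[1]], , drop = FALSE], Xp, R_soft)) +
              rowSums(prox_block(X[tgt[[2]], , drop = FALSE], Xp, R_soft))) / 2
    acc <- acc + cnt
  }
  acc / length(structures)
}

#' Rank partner chromosomes by mean IppRatio
#'
#' For every partner chromosome: `log2(IPP_cluster / IPP_ensemble)` per bin
#' (computed chromosome-wide against that partner), averaged over the
#' target's bins (zero-ensemble bins excluded), sorted descending.
#'
#' @param cluster_structures,ensemble_structures Lists of whole-genome
#'   coordinate matrices.
#' @inheritParams proximity_map
#' @return Named numeric vector (partner chromosome -> mean IppRatio),
#'   sorted descending.
#' @export
ipp_ranking <- function(cluster_structures, ensemble_structures, bead_table,
                        target_chrom, R_soft = 2000) {
  chroms <- setdiff(unique(bead_table$chrom), target_chrom)
  vals <- vapply(chroms, function(ch) {
    ic <- ipp_track(cluster_structures, bead_table, target_chrom, ch, R_soft)
    ie <- ipp_track(ensemble_structures, bead_table, target_chrom, ch, R_soft)
    r <- log2(ic / ie)
    r[!is.finite(r)] <- NA_real_
    mean(r, na.rm = TRUE)
  }, 0)
  sort(setNames(vals, chroms), decreasing = TRUE)
}
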