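# From 2D embedding to clusters: 3-sigma outlier removal, KDE on a grid,
# maximum-filter peak detection, watershed-like basin assignment, occupancy
# and silhouette.

#' Remove embedding outliers by the 3-sigma rule
#'
#' For each point the row sum of the pairwise distance matrix is computed;
#' points whose row sum falls outside `mean +/- 3 sd` are removed.
#'
#' @param points n x 2 embedding matrix.
#' @return List with `points` (retained), `kept` and `removed` (indices into
#'   the input).
#' @export
remove_outliers <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3) stop("need at least 3 points")
  rs <- rowSums(as.matrix(dist(pts)))
  m <- mean(rs); s <- sd(rs)
  keep <- rs >= m - 3 * s & rs <= m + 3 * s
  list(points = pts[keep, , drop = FALSE], kept = unname(which(keep)),
       removed = unname(which(!keep)))
}

#' Bivariate kernel density on a grid
#'
#' Gaussian-kernel density estimate with Scott's-rule bandwidth
#' (`sd_j * n^(-1/6)` per axis), evaluated on a `gridsize x gridsize` grid
#' spanning the axis-wise minima and maxima of the points. Degenerate inputs
#' (an axis with zero spread) are jittered by `1e-9` of the overall span.
#'
#' @param points n x 2 matrix.
#' @param gridsize Grid side (1000 reproduces the reference analysis; 500 is
#'   the desk-scale default of the pipeline).
#' @param seed Seed for the degenerate-input jitter.
#' @return Object of class `density_grid`: `x`, `y` (grid coordinates), `P`
#'   (`gridsize x gridsize`, `P[i, j]` is the density at `(x[i], y[j])`),
#'   `bandwidth`.
#' @export
kde_density <- function(points, gridsize = 1000, seed = 1L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points")
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  if (span == 0 || any(apply(pts, 2, sd) == 0)) {
    warning("degenerate point configuration; adding tiny jitter")
    set.seed(seed)
    pts <- pts + rnorm(length(pts), sd = max(span, 1) * 1e-9)
  }
  h <- apply(pts, 2, sd) * n^(-1 / 6)
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = gridsize)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = gridsize)
  # separable Gaussian product kernel -> one GEMM
  Kx <- dnorm(outer(gx, pts[, 1], "-") / h[1])
  Ky <- dnorm(outer(gy, pts[, 2], "-") / h[2])
  P <- (Kx %*% t(Ky)) / (n * h[1] * h[2])
  structure(list(x = gx, y = gy, P = P, bandwidth = h, n = n),
            class = "density_grid")
}

# 5x5 maximum filter via shifted maxima (out-of-range neighbours ignored,
# which for the equality test below is equivalent to reflecting the border).
max_filter <- function(P, size = 5) {
  r <- (size - 1) %/% 2
  n1 <- nrow(P); n2 <- ncol(P)
  out <- P
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(n1, n1 + di)
    ti <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 + dj):min(n2, n2 + dj)
    tj <- max(1, 1 - dj):min(n2, n2 - dj)
    out[ti, tj] <- pmax(out[ti, tj], P[si, sj])
  }
  out
}

#' Detect density peaks with a maximum filter
#'
#' A 5 x 5 maximum filter is applied to the density matrix `P`; the peak
#' indicator is `I(p == maxfilter(p)) XOR I(p == 0)`, i.e. nonzero cells that
#' equal their neighbourhood maximum. Plateau ties are collapsed to the
#' lexicographically smallest index.
#'
#' @param grid A [kde_density()] result (or a bare density matrix).
#' @param size Maximum-filter window.
#' @return Integer k x 2 matrix of peak grid indices (row, col).
#' @export
detect_peaks <- function(grid, size = 5) {
  P <- if (inherits(grid, "density_grid")) grid$P else as.matrix(grid)
  q <- (P == max_filter(P, size)) & (P != 0)
  idx <- which(q, arr.ind = TRUE)
  if (nrow(idx) > 1) {
    # collapse plateaus: among equal-valued candidates within each other's
    # window, keep the lexicographically smallest (row, col)
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(idx))
    vals <- P[idx]
    r <- (size - 1) %/% 2
    for (a in seq_len(nrow(idx))) {
      if (!keep[a]) next
      for (b in seq_len(a - 1)) {
        if (keep[b] && vals[a] == vals[b] &&
            max(abs(idx[a, ] - idx[b, ])) <= 2 * r) {
          keep[a] <- FALSE
          break
        }
      }
    }
    idx <- idx[keep, , drop = FALSE]
  }
  colnames(idx) <- c("row", "col")
  unname(idx)
}

#' Assign points to density basins (watershed-like)
#'
#' For each peak the density level is raised through `nlevels` evenly spaced
#' levels from 0 to the grid maximum until the enclosing super-level region
#' contains only that peak; points whose grid cell falls inside that region
#' get the peak's label. Clusters with fewer than `min_size` members are
#' discarded (their points become unclustered).
#'
#' @param grid A [kde_density()] result.
#' @param peaks Peak index matrix from [detect_peaks()].
#' @param points The n x 2 points the grid was computed from.
#' @param min_size Minimum cluster size (100 at full scale).
#' @param nlevels Number of density levels.
#' @return Object of class `cluster_assignment`: `labels` (integer or `NA`
#'   per point), `peaks` (retained peak indices), `sizes`, `occupancy`,
#'   `region` (grid labeling).
#' @export
watershed_assign <- function(grid, peaks, points, min_size = 100,
                             nlevels = 100) {
  stopifnot(inherits(grid, "density_grid"))
  pts <- as.matrix(points)
  if (nrow(peaks) < 1) stop("need at least one peak")
  region <- .watershed_regions(grid$P, peaks, as.integer(nlevels))
  G <- length(grid$x)
  ix <- round((pts[, 1] - grid$x[1]) / (grid$x[G] - grid$x[1]) * (G - 1)) + 1
  iy <- round((pts[, 2] - grid$y[1]) / (grid$y[G] - grid$y[1]) * (G - 1)) + 1
  ix <- pmin(pmax(ix, 1), G); iy <- pmin(pmax(iy, 1), G)
  lab <- region[cbind(ix, iy)]
  lab[lab == 0] <- NA_integer_
  sizes <- tabulate(lab, nbins = nrow(peaks))
  small <- which(sizes > 0 & sizes < min_size)
  if (length(small)) lab[lab %in% small] <- NA_integer_
  keep <- which(tabulate(lab, nbins = nrow(peaks)) >= min_size)
  if (!length(keep)) {
    warning("no cluster of at least ", min_size, " members")
    return(structure(list(labels = rep(NA_integer_, length(lab)),
                          peaks = peaks[0, , drop = FALSE],
                          sizes = integer(0), occupancy = numeric(0),
                          region = region),
                     class = "cluster_assignment"))
  }
  relab <- match(lab, keep)
  sizes <- tabulate(relab, nbins = length(keep))
  structure(list(labels = relab, peaks = peaks[keep, , drop = FALSE],
                 sizes = sizes, occupancy = sizes / sum(sizes),
                 region = region),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d clusters, %d/%d points clustered>\n",
              length(x$sizes), sum(x$sizes), length(x$labels)))
  invisible(x)
}

#' Silhouette coefficients of a clustering
#'
#' Per-point silhouette `s = (b - a) / max(a, b)` with `a` the mean distance
#' to the own cluster and `b` the smallest mean distance to another cluster;
#' unclustered points (label `NA`) are excluded. The summary coefficient is
#' the mean over all clustered points.
#'
#' @param points n x 2 (or n x d) matrix.
#' @param labels Integer cluster labels with `NA` for unclustered points.
#' @return List: `values` (per clustered point), `mean`, `by_cluster` (mean
#'   silhouette per cluster).
#' @export
silhouette_score <- function(points, labels) {
  keep <- !is.na(labels)
  pts <- as.matrix(points)[keep, , drop = FALSE]
  lab <- labels[keep]
  cl <- sort(unique(lab))
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters")
  D <- as.matrix(dist(pts))
  n <- nrow(D)
  sums <- vapply(cl, function(k) rowSums(D[, lab == k, drop = FALSE]), numeric(n))
  cnt <- vapply(cl, function(k) sum(lab == k), 0L)
  li <- match(lab, cl)
  a <- sums[cbind(seq_len(n), li)] / pmax(cnt[li] - 1, 1)
  meanother <- sweep(sums, 2, cnt, "/")
  meanother[cbind(seq_len(n), li)] <- Inf
  b <- apply(meanother, 1, min)
  s <- ifelse(cnt[li] > 1, (b - a) / pmax(a, b), 0)
  list(values = s, mean = mean(s),
       by_cluster = vapply(seq_along(cl), function(k) mean(s[li == k]), 0))
}

#' Cluster occupancy
#'
#' Fraction of clustered structures in each cluster: cluster size divided by
#' the total number of structures in all clusters (unclustered points are
#' excluded from the denominator).
#'
#' @param assignment A [watershed_assign()] result (or an integer/NA label
#'   vector).
#' @return Named numeric vector summing to 1.
#' @export
occupancy <- function(assignment) {
  sizes <- if (inherits(assignment, "cluster_assignment")) assignment$sizes
           else as.vector(table(assignment))
  if (!length(sizes) || sum(sizes) == 0) stop("no clustered structures")
  setNames(sizes / sum(sizes), seq_along(sizes))
}

#' Select structures midway between two cluster centers
#'
#' Returns the unclustered points lying within a radius (default 5% of the
#' embedding span) of the midpoint between two peaks -- candidate
#' intermediate conformations on the transition path between two states.
#'
#' @param points n x 2 embedding matrix.
#' @param assignment A [watershed_assign()] result.
#' @param grid The [kde_density()] grid (to convert peak indices to data
#'   coordinates).
#' @param peak_pair Length-2 integer vector of cluster ids.
#' @param radius_frac Radius as a fraction of the embedding span.
#' @return Integer indices of the selected points.
#' @export
select_intermediates <- function(points, assignment, grid, peak_pair,
                                 radius_frac = 0.05) {
  stopifnot(length(peak_pair) == 2)
  if (any(peak_pair > nrow(assignment$peaks)))
    stop("unknown cluster in peak_pair")
  pts <- as.matrix(points)
  pk <- assignment$peaks[peak_pair, , drop = FALSE]
  ctr <- cbind(grid$x[pk[, 1]], grid$y[pk[, 2]])
  mid <- colMeans(ctr)
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  r <- radius_frac * span
  d <- sqrt((pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2)
  which(is.na(assignment$labels) & d <= r)
}
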