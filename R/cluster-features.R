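# Per-cluster averaged matrices and per-bin structural tracks: contact and
# distance matrices, insulation scores and territory-domain boundaries,
# P(s) curves, radius of gyration, radial statistics, A/B compartments and
# generic log2 cluster-vs-ensemble ratio tracks.

#' Binary contact matrix of one structure
#'
#' Beads `i`, `j` are in contact iff `||x_i - x_j|| <= threshold`
#' (inclusive), with the conventional threshold `3 R_bead`.
#'
#' @param s A [chrom_structure()] or coordinate matrix.
#' @param threshold Contact range in nm; defaults to `3 R_bead` of the
#'   structure (or of the 118-nm model bead for a bare matrix).
#' @return Binary integer matrix (diagonal 1).
#' @export
contact_matrix <- function(s, threshold = NULL) {
  if (is.null(threshold))
    threshold <- 3 * if (inherits(s, "chrom_structure")) s$R_bead else 118
  m <- as.matrix(dist(coords_of(s)))
  out <- (m <= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Summed contact frequency matrix of a set of structures
#'
#' @param structures List of structures.
#' @param threshold Contact range in nm (default `3 R_bead`).
#' @return Integer matrix of contact counts. The display transform
#'   `log2(cm + 1)` is left to rendering.
#' @export
cluster_contact_matrix <- function(structures, threshold = NULL) {
  Reduce(`+`, lapply(structures, function(s)
    contact_matrix(s, threshold)))
}

#' Average min-max-normalized distance matrix of a cluster
#'
#' @param structures List of structures.
#' @return Matrix in `[0, 1]`: the mean of per-structure min-max-normalized
#'   center-distance matrices.
#' @export
average_distance_matrix <- function(structures) {
  if (!length(structures)) stop("need at least 1 structure")
  Reduce(`+`, lapply(structures, function(s)
    normalize_minmax(center_distance_matrix(coords_of(s))))) /
    length(structures)
}

# Summed-area table block sums and diagonal cumsums for the insulation
# windows.
sat_block <- function(S, r1, r2, c1, c2) {
  S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
}

#' Insulation-score profile along the diagonal
#'
#' Sliding windows of `l` bins on each side of bin `i` (the right window
#' includes `i`). With `LM`/`RM` the within-side upper-triangle sums and `M`
#' the cross-block sum, the contact variant scores `LM + RM - M` on a
#' contact matrix; the distance variant first binarizes the average distance
#' matrix at `binarize_threshold` (1 where larger) and scores `M - LM - RM`.
#' Either way a territory-domain boundary appears as a profile maximum. Bins
#' within `l` of the chromosome ends are `NA`.
#'
#' @param M Square matrix (contact counts or normalized average distances).
#' @param variant `"contact"` or `"distance"`.
#' @param window Window size `l` in bins.
#' @param binarize_threshold Distance-variant threshold (0.4--0.5).
#' @return Numeric per-bin profile.
#' @export
insulation_profile <- function(M, variant = c("distance", "contact"),
                               window = 30, binarize_threshold = 0.45) {
  variant <- match.arg(variant)
  n <- nrow(M)
  if (window > n / 2) stop("window must be at most half the matrix side")
  B <- if (variant == "distance") (M > binarize_threshold) * 1 else M
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- t(apply(apply(B, 2, cumsum), 1, cumsum))   # summed-area table
  dcs <- c(0, cumsum(diag(B)))
  tri <- function(r1, r2) {
    (sat_block(S, r1, r2, r1, r2) - (dcs[r2 + 1] - dcs[r1])) / 2
  }
  out <- rep(NA_real_, n)
  l <- window
  for (i in seq_len(n)) {
    if (i - l < 1 || i + l - 1 > n) next
    lm <- tri(i - l, i - 1)
    rm_ <- tri(i, i + l - 1)
    cross <- sat_block(S, i - l, i - 1, i, i + l - 1)
    out[i] <- if (variant == "contact") lm + rm_ - cross else cross - lm - rm_
  }
  out
}

# Local maxima of a profile with a minimum prominence; NA treated as -Inf.
find_local_maxima <- function(x, min_prominence = 0) {
  v <- ifelse(is.na(x), -Inf, x)
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[is.finite(v[cand])]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- v[i]; j <- i
    while (j > 1 && v[j - 1] <= v[i]) { j <- j - 1; lmin <- min(lmin, v[j]) }
    rmin <- v[i]; j <- i
    while (j < n && v[j + 1] <= v[i]) { j <- j + 1; rmin <- min(rmin, v[j]) }
    v[i] - max(lmin, rmin, -.Machine$double.xmax)
  }, 0)
  cand[prom >= min_prominence]
}

#' Call territory-domain boundaries from an average distance matrix
#'
#' Two-pass procedure on the distance-variant insulation profile: a coarse
#' window (40 Mb = 200 bins at 200 kb) locates candidate boundary regions as
#' local maxima with prominence at least one profile standard deviation; a
#' fine window (6 Mb = 30 bins) then pinpoints the boundary bin as the local
#' profile maximum inside each candidate region.
#'
#' @param DM Average min-max-normalized distance matrix.
#' @param coarse_window,fine_window Window sizes in bins.
#' @param binarize_threshold Distance binarization threshold.
#' @param prominence_sd Required prominence in units of the coarse profile's
#'   standard deviation.
#' @return Sorted integer vector of boundary bin indices.
#' @export
call_boundaries <- function(DM, coarse_window = 200, fine_window = 30,
                            binarize_threshold = 0.45, prominence_sd = 1) {
  n <- nrow(DM)
  if (n < 2 * coarse_window)
    stop("chromosome must span at least twice the coarse window")
  coarse <- insulation_profile(DM, "distance", coarse_window,
                               binarize_threshold)
  s <- sd(coarse, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(integer(0))
  cand <- find_local_maxima(coarse, min_prominence = prominence_sd * s)
  if (!length(cand)) return(integer(0))
  fine <- insulation_profile(DM, "distance", fine_window, binarize_threshold)
  hw <- coarse_window %/% 2
  b <- vapply(cand, function(i) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    w <- fine[lo:hi]
    if (all(is.na(w))) return(NA_integer_)
    as.integer(lo + which.max(w) - 1L)
  }, 0L)
  sort(unique(b[!is.na(b)]))
}

#' Contact probability versus sequence separation
#'
#' Mean contact frequency per genomic-separation band, normalized by the
#' number of structures and by the number of bead pairs in the band.
#'
#' @param CM Summed contact matrix of the cluster.
#' @param n_structures Number of structures summed into `CM`.
#' @param breaks Band edges in bins (bands are `[breaks[k], breaks[k+1])`);
#'   the diagonal (`s = 0`) is excluded.
#' @return `data.frame` with `s_min`, `s_max`, `prob`.
#' @export
contact_probability_curve <- function(CM, n_structures,
                                      breaks = NULL) {
  n <- nrow(CM)
  if (is.null(breaks))
    breaks <- unique(pmin(c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, n), n))
  sep <- abs(row(CM) - col(CM))
  out <- data.frame(s_min = head(breaks, -1), s_max = breaks[-1], prob = NA_real_)
  for (k in seq_len(nrow(out))) {
    sel <- sep >= out$s_min[k] & sep < out$s_max[k] & upper.tri(CM)
    if (any(sel)) out$prob[k] <- mean(CM[sel]) / n_structures
  }
  out[!is.na(out$prob), ]
}

#' Local radius of gyration profile
#'
#' Radius of gyration of the 1-Mb (5-bin) region centered on each bin:
#' `rg_i = sqrt(mean of squared distances to the region's center of mass)`.
#' Bins too close to the ends are `NA`.
#'
#' @param s A [chrom_structure()] or coordinate matrix.
#' @param window Region size in bins (odd; 5 bins = 1 Mb at 200 kb).
#' @return Numeric per-bin profile in nm.
#' @export
rg_profile <- function(s, window = 5) {
  x <- coords_of(s)
  n <- nrow(x)
  hw <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - hw < 1 || i + hw > n) next
    w <- x[(i - hw):(i + hw), , drop = FALSE]
    com <- colMeans(w)
    out[i] <- sqrt(mean(rowSums(sweep(w, 2, com)^2)))
  }
  out
}

#' Whole-structure radius of gyration
#' @param s A [chrom_structure()] or coordinate matrix.
#' @return Scalar radius of gyration in nm.
#' @export
structure_rg <- function(s) {
  x <- coords_of(s)
  com <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, com)^2)))
}

#' Mean radial-position track of a cluster
#'
#' Radial position of a bead is `||x|| / R_nuc` in a spherical nucleus (0 =
#' center, 1 = envelope) and the scaled elliptic radius
#' `sqrt((x/a)^2 + (y/b)^2 + (z/c)^2)` in an ellipsoid. The track is the
#' per-bin mean over structures.
#'
#' @param structures List of structures (equal bead count).
#' @param geometry A [nucleus_geometry()].
#' @return Numeric per-bin track.
#' @export
radial_track <- function(structures, geometry) {
  n <- nrow(coords_of(structures[[1]]))
  R <- matrix(vapply(structures, function(s)
    radial_positions(coords_of(s), geometry), numeric(n)), nrow = n)
  rowMeans(R)
}

#' Structural-variability track (delta-RAD)
#'
#' `log2(sigma_i / mean(sigma))` where `sigma_i` is the standard deviation
#' of the radial position of bin `i` across structures and the denominator
#' averages over all bins of the chromosome. Bins with zero variability are
#' `NA`.
#'
#' @inheritParams radial_track
#' @return Numeric per-bin track.
#' @export
variability_track <- function(structures, geometry) {
  n <- nrow(coords_of(structures[[1]]))
  R <- matrix(vapply(structures, function(s)
    radial_positions(coords_of(s), geometry), numeric(n)), nrow = n)
  sig <- apply(R, 1, sd)
  sig[sig == 0] <- NA_real_
  log2(sig / mean(sig, na.rm = TRUE))
}

#' Log2 cluster-versus-ensemble ratio track
#'
#' `log2(cluster_i / ensemble_i)`; bins with a non-positive or missing
#' ensemble value are `NA`. This is the form of RadRatio, RgRatio,
#' SpdRatio, SafRatio, IppRatio and the TSA-seq ratio.
#'
#' @param cluster_track,ensemble_track Equal-length numeric tracks.
#' @return Numeric track.
#' @export
log2_ratio_track <- function(cluster_track, ensemble_track) {
  if (length(cluster_track) != length(ensemble_track))
    stop("tracks must have equal length")
  out <- log2(cluster_track / ensemble_track)
  out[is.na(ensemble_track) | ensemble_track <= 0] <- NA_real_
  out
}

#' A/B compartments by eigenvector decomposition
#'
#' Observed/expected normalization of the contact matrix (expected = mean
#' per separation band), Pearson correlation matrix, leading eigenvectors.
#' Both PC1 and PC2 are returned -- the compartment signal can surface in
#' either -- and signs are oriented by correlation with a reference track
#' (e.g. gene density or an A1/A2 indicator) when given.
#'
#' @param CM Contact frequency matrix.
#' @param reference Optional per-bin reference track for sign orientation
#'   and for choosing the compartment-carrying component.
#' @return List: `PC1`, `PC2` (per-bin, `NA` at masked bins), `compartment`
#'   (+1/-1/NA), `component` (1 or 2), `masked` (bins without contacts).
#' @export
ab_compartments <- function(CM, reference = NULL) {
  n <- nrow(CM)
  off <- CM; diag(off) <- 0
  mask <- rowSums(off) == 0
  keep <- which(!mask)
  M <- CM[keep, keep, drop = FALSE]
  sep <- abs(row(M) - col(M))
  expctd <- vapply(0:(nrow(M) - 1), function(s) mean(M[sep == s]), 0)
  OE <- M / expctd[sep + 1]
  OE[!is.finite(OE)] <- 0
  sds <- apply(OE, 2, sd)
  if (all(sds == 0)) {
    warning("uniform matrix: no compartment signal")
    z <- rep(NA_real_, n); z[keep] <- 0
    return(list(PC1 = z, PC2 = z, compartment = rep(NA_real_, n),
                component = 1L, masked = which(mask)))
  }
  keep2 <- keep[sds > 0]
  OE <- OE[sds > 0, sds > 0, drop = FALSE]
  C <- cor(OE)
  ev <- eigen(C, symmetric = TRUE)
  pc <- function(k) {
    v <- rep(NA_real_, n)
    v[keep2] <- ev$vectors[, k]
    v
  }
  PC1 <- pc(1); PC2 <- pc(2)
  comp_idx <- 1L
  if (!is.null(reference)) {
    r1 <- suppressWarnings(cor(PC1, reference, use = "complete.obs"))
    r2 <- suppressWarnings(cor(PC2, reference, use = "complete.obs"))
    if (!is.na(r2) && (is.na(r1) || abs(r2) > abs(r1))) comp_idx <- 2L
    if (comp_idx == 1L && !is.na(r1) && r1 < 0) PC1 <- -PC1
    if (comp_idx == 2L && !is.na(r2) && r2 < 0) PC2 <- -PC2
  }
  chosen <- if (comp_idx == 1L) PC1 else PC2
  list(PC1 = PC1, PC2 = PC2, compartment = sign(chosen),
       component = comp_idx, masked = which(mask))
}

#' Partition a chromosome into territory domains
#'
#' Intervals between consecutive boundaries (including the chromosome ends),
#' labeled `a`, `b`, `c`, ...
#'
#' @param boundaries Sorted boundary bin indices (a boundary bin starts a
#'   new domain).
#' @param n_bins Chromosome length in bins.
#' @return `data.frame` with `label`, `start_bin`, `end_bin` (inclusive).
#' @export
territory_domains <- function(boundaries, n_bins) {
  b <- sort(unique(boundaries))
  starts <- c(1L, as.integer(b))
  ends <- c(as.integer(b) - 1L, n_bins)
  data.frame(label = letters[seq_along(starts)], start_bin = starts,
             end_bin = ends, stringsAsFactors = FALSE)
}

#' Z-scores of an insulation profile at given positions
#'
#' Used for the negative control: a called boundary only counts as a
#' territory-domain boundary when its insulation score stands out from the
#' chromosome-wide profile. The denominator is floored at `floor_sd` so
#' that spikes on an essentially flat profile (where the empirical sd is
#' dominated by counting noise) are not declared significant.
#'
#' @param profile Insulation profile.
#' @param positions Bin indices.
#' @param floor_sd Lower bound for the profile standard deviation.
#' @return Numeric z-scores.
#' @export
insulation_zscore <- function(profile, positions, floor_sd = 0) {
  m <- mean(profile, na.rm = TRUE)
  s <- max(sd(profile, na.rm = TRUE), floor_sd, .Machine$double.eps)
  (profile[positions] - m) / s
}

#' Significance of called boundaries on an average distance matrix
#'
#' Z-score of each called boundary's distance-variant insulation score
#' against the chromosome-wide profile, with the denominator floored at the
#' counting-noise level of the binarized window sums: under an independent
#' Bernoulli null with the matrix's overall binarized density `p`, the
#' score's standard deviation is about `sqrt(2 p (1 - p)) * window`.
#'
#' @param DM Average min-max-normalized distance matrix.
#' @param boundaries Boundary bins (from [call_boundaries()]).
#' @param window Insulation window in bins.
#' @param binarize_threshold Distance binarization threshold.
#' @return Numeric z-score per boundary.
#' @export
boundary_significance <- function(DM, boundaries, window = 30,
                                  binarize_threshold = 0.45) {
  if (!length(boundaries)) return(numeric(0))
  prof <- insulation_profile(DM, "distance", window, binarize_threshold)
  p <- mean(DM > binarize_threshold)
  floor_sd <- sqrt(2 * p * (1 - p)) * window
  insulation_zscore(prof, boundaries, floor_sd = floor_sd)
}
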