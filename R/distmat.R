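# Per-structure distance matrices: the embedding input (surface-to-surface,
# max-normalized, resized) and the profiling input (center-to-center,
# min-max-normalized).

#' Remove unrestrained beads from a structure
#'
#' Drops beads annotated `"cen"` (centromeric/telomeric, unrestrained in the
#' models); only `"domain"` beads enter the distance matrices. The original
#' indices of the retained beads are attached as attribute `retained_index`
#' so per-bin profiles can be re-expanded to genome coordinates.
#'
#' @param s A [chrom_structure()].
#' @param ann A [bin_annotation()] covering the structure's chromosome, in
#'   bead order.
#' @return The filtered [chrom_structure()] with attribute `retained_index`.
#' @export
filter_beads <- function(s, ann) {
  cat_ <- ann$category[ann$chrom == s$chrom]
  if (length(cat_) != n_beads(s))
    stop("annotation does not cover all beads (", length(cat_), " vs ",
         n_beads(s), ")")
  keep <- which(cat_ == "domain")
  if (!length(keep)) warning("all beads removed: no 'domain' beads")
  out <- chrom_structure(s$structure_id, s$chrom, s$copy,
                         s$coords[keep, , drop = FALSE], s$R_bead)
  attr(out, "retained_index") <- keep
  out
}

coords_of <- function(s) if (inherits(s, "chrom_structure")) s$coords else as.matrix(s)

#' Surface-to-surface distance matrix
#'
#' `d_ij = ||x_i - x_j|| - 2 R_bead` for `i != j` (0 on the diagonal): the
#' gap between bead surfaces, negative when beads overlap. This is the input
#' convention of the embedding.
#'
#' @param s A [chrom_structure()] (or an n x 3 coordinate matrix, with
#'   `R_bead` taken from the `R_bead` argument).
#' @param R_bead Bead radius in nm, used when `s` is a bare matrix.
#' @return Square symmetric matrix with attribute `convention = "surface"`.
#' @export
surface_distance_matrix <- function(s, R_bead = 118) {
  if (inherits(s, "chrom_structure")) R_bead <- s$R_bead
  x <- coords_of(s)
  if (nrow(x) < 2) stop("need at least 2 beads")
  m <- as.matrix(dist(x)) - 2 * R_bead
  diag(m) <- 0
  attr(m, "convention") <- "surface"
  m
}

#' Center-to-center distance matrix
#'
#' Plain Euclidean distances between bead centers; used for cluster-average
#' distance matrices and dissimilarity measures.
#'
#' @inheritParams surface_distance_matrix
#' @return Square symmetric matrix with attribute `convention = "center"`.
#' @export
center_distance_matrix <- function(s) {
  x <- coords_of(s)
  m <- as.matrix(dist(x))
  attr(m, "convention") <- "center"
  m
}

#' Normalize a distance matrix so its maximum entry is 1
#'
#' Surface-convention matrices may contain small negative entries for
#' overlapping beads; these are clipped to 0 first (`clip_negative`), keeping
#' the normalized matrix in `[0, 1]`.
#'
#' @param m Square matrix with non-negative maximum.
#' @param clip_negative Clip negative entries to 0 before scaling.
#' @return The scaled matrix (max entry exactly 1).
#' @export
normalize_max <- function(m, clip_negative = TRUE) {
  if (clip_negative) m[m < 0] <- 0
  mx <- max(m)
  if (mx <= 0) stop("cannot max-normalize an all-zero matrix")
  out <- m / mx
  attr(out, "normalized") <- "max"
  out
}

#' Min-max normalize a distance matrix
#'
#' Affinely maps off-diagonal entries to `[0, 1]`; the diagonal stays 0.
#'
#' @param m Square symmetric matrix.
#' @return Normalized matrix.
#' @export
normalize_minmax <- function(m) {
  off <- m[row(m) != col(m)]
  lo <- min(off); hi <- max(off)
  if (hi <= lo) stop("cannot min-max normalize: constant off-diagonal")
  out <- (m - lo) / (hi - lo)
  diag(out) <- 0
  attr(out, "normalized") <- "minmax"
  out
}

# Bilinear interpolation weights mapping n source samples to m targets with
# endpoints fixed (target i sits at source position (i-1)(n-1)/(m-1)+1).
bilinear_weights <- function(n, m) {
  W <- matrix(0, m, n)
  if (m == 1) { W[1, 1] <- 1; return(W) }
  p <- (seq_len(m) - 1) * (n - 1) / (m - 1) + 1
  lo <- pmin(floor(p), n - 1)
  fr <- p - lo
  for (i in seq_len(m)) {
    W[i, lo[i]] <- 1 - fr[i]
    W[i, lo[i] + 1] <- fr[i]
  }
  W
}

#' Resize a square matrix to a multiple of 50 by bilinear interpolation
#'
#' The autoencoder pools by 5 x 5 x 2, so its input side must be divisible
#' by 50. The matrix is treated as an image and resampled bilinearly with
#' endpoints fixed (corner values are preserved exactly; constant and
#' row/column-affine matrices are resized exactly).
#'
#' @param m Square matrix with side >= 50.
#' @param side Target side; default the nearest multiple of 50 (ties round
#'   down). Must itself be a multiple of 50.
#' @return The resized matrix.
#' @export
resize_to_multiple_of_50 <- function(m, side = NULL) {
  n <- nrow(m)
  if (n != ncol(m)) stop("matrix must be square")
  if (n < 50) stop("matrix side must be at least 50")
  if (is.null(side)) {
    t <- n / 50
    side <- 50 * (floor(t) + (t - floor(t) > 0.5))
  }
  if (side %% 50 != 0 || side < 50) stop("target side must be a multiple of 50")
  if (side == n) return(m)
  W <- bilinear_weights(n, side)
  W %*% m %*% t(W)
}

#' Downsample a structure or matrix to a coarser genomic step
#'
#' Retains one bead per window of `step` bp (the window's central bin), or
#' beads at explicitly given indices (e.g. positions imaged in a tracing
#' experiment). Distance matrices recomputed from the retained beads equal
#' the corresponding submatrix of the full matrix.
#'
#' @param x A [chrom_structure()] or a square matrix.
#' @param step Window size in bp (a multiple of `bin_width`).
#' @param bin_width Bin width in bp.
#' @param at Optional integer vector of bin indices to retain, overriding
#'   `step`.
#' @return The reduced structure or matrix, with attribute `retained_index`.
#' @export
downsample_coverage <- function(x, step = 3e6, bin_width = 2e5, at = NULL) {
  n <- if (inherits(x, "chrom_structure")) n_beads(x) else nrow(x)
  if (is.null(at)) {
    if (step < bin_width) stop("step must be at least the bin width")
    if (step %% bin_width != 0) stop("step must be a multiple of the bin width")
    w <- step / bin_width
    at <- seq.int(ceiling(w / 2), n, by = w)
  }
  if (any(at < 1 | at > n)) stop("retained indices out of range")
  out <- if (inherits(x, "chrom_structure")) {
    chrom_structure(x$structure_id, x$chrom, x$copy,
                    x$coords[at, , drop = FALSE], x$R_bead)
  } else {
    x[at, at, drop = FALSE]
  }
  attr(out, "retained_index") <- at
  out
}

#' Embedding input matrix for one structure
#'
#' Convenience composition used by the pipeline: surface distances, negative
#' gaps clipped, max-normalized, then resized for the autoencoder.
#'
#' @param s A [chrom_structure()].
#' @param side Target side passed to [resize_to_multiple_of_50()].
#' @return Matrix with values in `[0, 1]` and side a multiple of 50.
#' @export
embedding_input_matrix <- function(s, side = NULL) {
  resize_to_multiple_of_50(normalize_max(surface_distance_matrix(s)),
                           side = side)
}
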