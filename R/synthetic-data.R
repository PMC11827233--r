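# Seeded generators for every input class the pipeline consumes: planted
# conformational clusters (positive control), confined self-avoiding
# homopolymers (negative control), genomes with planted A1/speckle
# architecture, and sparse single-cell contact maps. All generators are
# deterministic given the configuration seed.

#' Simulation configuration
#'
#' Conditions of the synthetic studies. Defaults follow the positive-control
#' setup used throughout: 4 reference conformations of 200 beads with
#' distinct planted territory-domain patterns, 500 structures per cluster,
#' Gaussian coordinate noise with relative standard deviations 0.1, 0.4 and
#' 0.8 (of the reference radius of gyration), in a spherical 5000-nm
#' nucleus with 118-nm beads.
#'
#' @param n_clusters Number of planted clusters.
#' @param n_beads Beads per chromosome structure.
#' @param structures_per_cluster Structures sampled per cluster.
#' @param sigmas Relative noise levels in (0, 1]; cycled over structures.
#' @param boundaries List (length `n_clusters`) of planted territory-domain
#'   boundary bins, strictly inside the chromosome. The default plants
#'   distinct patterns, including one boundary-free cluster.
#' @param geometry A [nucleus_geometry()].
#' @param R_bead Bead radius in nm.
#' @param seed Master seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_clusters = 4, n_beads = 200,
                              structures_per_cluster = 500,
                              sigmas = c(0.1, 0.4, 0.8),
                              boundaries = NULL,
                              geometry = nucleus_geometry("sphere",
                                                          R_nuc = 5000),
                              R_bead = 118, seed = 1L) {
  if (any(sigmas <= 0 | sigmas > 1)) stop("sigmas must lie in (0, 1]")
  if (is.null(boundaries)) {
    half <- round(n_beads / 2); third <- round(n_beads / 3)
    pats <- list(half, c(third, 2 * third),
                 round(n_beads * c(0.25, 0.5, 0.75)), integer(0),
                 round(n_beads * 0.7), round(n_beads * c(0.2, 0.55, 0.85)))
    boundaries <- rep(pats, length.out = n_clusters)
  }
  for (b in boundaries)
    if (length(b) && any(b <= 1 | b >= n_beads))
      stop("boundaries must be strictly inside the chromosome")
  structure(list(n_clusters = n_clusters, n_beads = n_beads,
                 structures_per_cluster = structures_per_cluster,
                 sigmas = sigmas, boundaries = boundaries,
                 geometry = geometry, R_bead = R_bead,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Confined random-walk blob: beads around `center` within radius `r`.
blob_walk <- function(n, center, r, bond) {
  X <- matrix(0, n, 3)
  X[1, ] <- center
  for (i in seq_len(n - 1)) {
    repeat {
      dir <- rnorm(3)
      cand <- X[i, ] + bond * dir / sqrt(sum(dir^2))
      if (sum((cand - center)^2) <= r^2) break
    }
    X[i + 1, ] <- cand
  }
  X
}

#' Reference conformations with planted territory domains
#'
#' Per cluster, a confined random-walk backbone in which each planted
#' territory domain is collapsed around its own displaced center, yielding
#' block-structured distance matrices with boundaries at the planted
#' positions. Distinct clusters get distinct domain layouts.
#'
#' @param cfg A [simulation_config()].
#' @return List of [chrom_structure()] reference conformations (one per
#'   cluster), with the planted boundaries attached as attribute
#'   `boundaries`.
#' @export
make_reference_conformations <- function(cfg) {
  set.seed(cfg$seed)
  refs <- vector("list", cfg$n_clusters)
  for (k in seq_len(cfg$n_clusters)) {
    b <- cfg$boundaries[[k]]
    starts <- c(1L, as.integer(b))
    ends <- c(as.integer(b) - 1L, cfg$n_beads)
    sizes <- ends - starts + 1L
    radii <- cfg$R_bead * pmax(2, 1.3 * sizes^(1 / 3))
    centers <- matrix(0, length(sizes), 3)
    for (d in seq_along(sizes)[-1]) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      centers[d, ] <- centers[d - 1, ] + dir * 1.6 * (radii[d - 1] + radii[d])
    }
    coords <- do.call(rbind, lapply(seq_along(sizes), function(d)
      blob_walk(sizes[d], centers[d, ], radii[d], 2 * cfg$R_bead)))
    coords <- sweep(coords, 2, colMeans(coords))   # center in the nucleus
    ref <- chrom_structure(paste0("ref", k), "chrS", 0, coords, cfg$R_bead)
    attr(ref, "boundaries") <- b
    refs[[k]] <- ref
  }
  refs
}

#' Positive-control population with planted cluster identity
#'
#' Per cluster, replicate inputs are derived from the reference
#' conformation with Gaussian noise at relative standard deviation `sigma`;
#' true labels are retained. Two noise spaces are supported:
#'
#' * `"matrix"` (default): Gaussian noise with standard deviation `sigma`
#'   micrometers is added to the entries of the reference's surface
#'   distance matrix (in nm; symmetrized, negatives clipped, zero
#'   diagonal), and each noisy matrix is then max-normalized exactly like a
#'   real structure's input. Distance noise leaves the expected pattern at
#'   the reference morphology, so replicates scatter around their
#'   reference at every noise level. A 3D realization of each replicate is
#'   available via [control_structures()].
#' * `"coordinate"`: the reference matrix is embedded to 3D by classical
#'   multidimensional scaling (exact for a Euclidean matrix) and isotropic
#'   Gaussian noise with standard deviation `sigma x` (reference radius of
#'   gyration) is added to the coordinates. Coordinate noise at large
#'   `sigma` systematically inflates all distances, so replicates drift
#'   away from the reference pattern rather than scattering around it.
#'
#' The sigma cycles through `cfg$sigmas` across a cluster's structures;
#' pass a scalar `sigma` to build a single-noise-level dataset.
#'
#' @param cfg A [simulation_config()].
#' @param references Optional precomputed [make_reference_conformations()].
#' @param sigma Optional scalar overriding `cfg$sigmas`.
#' @param noise_space `"matrix"` or `"coordinate"`.
#' @return List: `matrices` (noisy max-normalized input matrices with a
#'   `scales` attribute holding the nm value mapped to 1; `NULL` in
#'   coordinate mode), `structures` (list of [chrom_structure()]; `NULL` in
#'   matrix mode, see [control_structures()]), `labels`, `sigmas` (per
#'   structure), `references`, `noise_space`.
#' @export
positive_control <- function(cfg, references = NULL, sigma = NULL,
                             noise_space = c("matrix", "coordinate")) {
  noise_space <- match.arg(noise_space)
  if (is.null(references)) references <- make_reference_conformations(cfg)
  set.seed(cfg$seed + 1L)
  sig_list <- if (is.null(sigma)) cfg$sigmas else sigma
  n <- cfg$structures_per_cluster
  labels <- integer(0); sigmas <- numeric(0)
  matrices <- NULL; structures <- NULL
  if (noise_space == "matrix") {
    matrices <- list(); scales <- numeric(0)
    ref_mats <- lapply(references, function(r) {
      m <- surface_distance_matrix(r)
      m[m < 0] <- 0
      m
    })
    for (k in seq_along(references)) {
      sig <- rep(sig_list, length.out = n)
      for (s in seq_len(n)) {
        nb <- nrow(ref_mats[[k]])
        noise <- matrix(rnorm(nb * nb, sd = sig[s] * 1000), nb)  # um -> nm
        noise <- (noise + t(noise)) / sqrt(2)
        m <- ref_mats[[k]] + noise
        m[m < 0] <- 0; diag(m) <- 0
        mx <- max(m)
        matrices[[length(matrices) + 1L]] <- m / mx
        scales <- c(scales, mx)
        labels <- c(labels, k); sigmas <- c(sigmas, sig[s])
      }
    }
    attr(matrices, "scales") <- scales
  } else {
    structures <- list()
    for (k in seq_along(references)) {
      D <- center_distance_matrix(references[[k]])
      Y <- cmdscale(stats::as.dist(D), k = 3)
      rg <- structure_rg(Y)
      sig <- rep(sig_list, length.out = n)
      for (s in seq_len(n)) {
        noise <- matrix(rnorm(length(Y), sd = sig[s] * rg), ncol = 3)
        structures[[length(structures) + 1L]] <- chrom_structure(
          sprintf("c%d_s%03d", k, s), "chrS", 0, Y + noise, cfg$R_bead)
        labels <- c(labels, k); sigmas <- c(sigmas, sig[s])
      }
    }
  }
  list(matrices = matrices, structures = structures, labels = labels,
       sigmas = sigmas, references = references, noise_space = noise_space)
}

#' 3D structure realizations of matrix-noise positive controls
#'
#' Embeds each noisy input matrix to 3D by classical multidimensional
#' scaling (on the matrix rescaled back to nm by the reference's original
#' maximum), giving coordinate structures whose distance matrices carry the
#' large-scale part of the planted noise.
#'
#' @param pos A matrix-mode [positive_control()] result.
#' @param cfg The [simulation_config()] used to build it.
#' @return List of [chrom_structure()] objects.
#' @export
control_structures <- function(pos, cfg) {
  if (pos$noise_space != "matrix")
    return(pos$structures)
  scales <- attr(pos$matrices, "scales")
  lapply(seq_along(pos$matrices), function(i) {
    k <- pos$labels[i]
    D <- pos$matrices[[i]] * scales[i] + 2 * cfg$R_bead
    diag(D) <- 0
    Y <- cmdscale(stats::as.dist(D), k = 3)
    chrom_structure(sprintf("c%d_s%03d", k, i), "chrS", 0, Y, cfg$R_bead)
  })
}

#' Negative-control homopolymer population
#'
#' Random self-avoiding chromosome homopolymers constrained only by the
#' nuclear volume: consecutive beads at bond length `2 R_bead`, non-bonded
#' beads rejected below `2 R_bead` center distance, all beads inside the
#' nucleus.
#'
#' @param cfg A [simulation_config()].
#' @param n_structures Number of walks.
#' @return List of [chrom_structure()] objects.
#' @export
negative_control <- function(cfg, n_structures = 1000) {
  R_max <- if (cfg$geometry$shape == "sphere") cfg$geometry$R_nuc - cfg$R_bead
           else min(cfg$geometry$semiaxes) - cfg$R_bead
  lapply(seq_len(n_structures), function(i) {
    X <- .saw_walk(cfg$n_beads, 2 * cfg$R_bead, 2 * cfg$R_bead * 0.999,
                   R_max, cfg$seed + 7L * i)
    chrom_structure(sprintf("neg_%04d", i), "chrS", 0, X, cfg$R_bead)
  })
}

#' Synthetic genome population with planted speckle architecture
#'
#' Diploid two-chromosome genomes whose A1-annotated beads are placed in
#' `k_blobs` tight spatial blobs per cell (pairwise bead distances within a
#' blob below the speckle-network edge threshold, blob centers far apart).
#' Ground-truth blob centers are recorded for every structure.
#'
#' @param cfg A [simulation_config()] (only `geometry`, `R_bead`, `seed`
#'   used).
#' @param n_cells Number of cells.
#' @param beads_per_chrom Beads per chromosome copy.
#' @param n_a1 A1 bins per chromosome (taken at fixed positions).
#' @param k_blobs Speckle blobs per cell.
#' @param bin_width Bin width in bp.
#' @return List: `population` (a [genome_population()]), `a1` (logical per
#'   bead), `truth` (list of k x 3 blob-center matrices per cell).
#' @export
synthetic_genome_with_speckles <- function(cfg, n_cells = 5,
                                           beads_per_chrom = 60, n_a1 = 10,
                                           k_blobs = 3, bin_width = 2e5) {
  set.seed(cfg$seed + 2L)
  chroms <- c("chr1", "chr2")
  bead_table <- do.call(rbind, lapply(chroms, function(ch)
    do.call(rbind, lapply(0:1, function(cp)
      data.frame(chrom = ch, copy = cp,
                 start = (seq_len(beads_per_chrom) - 1) * bin_width,
                 end = seq_len(beads_per_chrom) * bin_width,
                 stringsAsFactors = FALSE)))))
  a1_bins <- round(seq(5, beads_per_chrom - 5, length.out = n_a1))
  a1 <- rep(FALSE, nrow(bead_table))
  for (ch in chroms) for (cp in 0:1)
    a1[which(bead_table$chrom == ch & bead_table$copy == cp)[a1_bins]] <- TRUE
  R_max <- cfg$geometry$R_nuc - cfg$R_bead
  structures <- list(); truth <- list()
  for (cell in seq_len(n_cells)) {
    X <- do.call(rbind, lapply(seq_len(4), function(i)
      blob_walk(beads_per_chrom, rnorm(3, sd = R_max / 4),
                R_max / 2, 2 * cfg$R_bead)))
    # blob centers mutually distant (>= 10x the 4 R_bead edge threshold)
    repeat {
      ctr <- matrix(stats::runif(k_blobs * 3, -R_max / 2, R_max / 2), k_blobs)
      if (k_blobs == 1 || min(dist(ctr)) > 10 * 4 * cfg$R_bead) break
    }
    memb <- rep(seq_len(k_blobs), length.out = sum(a1))
    X[a1, ] <- ctr[memb, ] + matrix(rnorm(sum(a1) * 3, sd = cfg$R_bead / 2),
                                    ncol = 3)
    structures[[cell]] <- X
    truth[[cell]] <- ctr
  }
  names(structures) <- sprintf("cell%02d", seq_len(n_cells))
  pop <- suppressWarnings(genome_population(structures, bead_table,
                                            cfg$geometry, R_bead = cfg$R_bead))
  list(population = pop, a1 = a1, truth = truth)
}

#' Sample sparse single-cell contact maps from cluster contact probabilities
#'
#' Bernoulli sampling of the upper triangle of a contact-probability matrix,
#' thinned so the expected number of sampled contacts matches `depth`
#' (~3879 contacts per cell emulates the observed sci-Hi-C coverage at
#' 200-kb resolution); the result is mirrored into a symmetric count matrix.
#'
#' @param prob Square matrix of contact probabilities in `[0, 1]`.
#' @param n_cells Number of cells to sample.
#' @param depth Target expected contacts per cell.
#' @param seed Sampling seed.
#' @return List of symmetric binary count matrices.
#' @export
sample_scihic_cells <- function(prob, n_cells, depth = 3879, seed = 1L) {
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  n <- nrow(prob)
  ut <- which(upper.tri(prob))
  p <- prob[ut]
  tot <- sum(p)
  if (depth > length(ut)) {
    warning("depth exceeds available pairs; capped")
    depth <- length(ut)
  }
  q <- pmin(p * depth / tot, 1)
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    m <- matrix(0L, n, n)
    m[ut] <- stats::rbinom(length(ut), 1L, q)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
}
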