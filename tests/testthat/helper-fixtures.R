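# Small in-code fixtures shared across the test files.

# Deterministic toy chromosome structure: n beads on a noisy helix.
toy_structure <- function(n = 10, seed = 1, id = "s1", copy = 0L,
                          R_bead = 118) {
  set.seed(seed)
  t <- seq(0, 4 * pi, length.out = n)
  coords <- cbind(500 * cos(t), 500 * sin(t), 80 * t) +
    matrix(rnorm(3 * n, sd = 20), ncol = 3)
  chrom_structure(id, "chrT", copy, coords, R_bead)
}

# Tiny diploid two-chromosome population.
toy_population <- function(n_cells = 2, beads = 5, seed = 1) {
  set.seed(seed)
  bead_table <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch)
    do.call(rbind, lapply(0:1, function(cp)
      data.frame(chrom = ch, copy = cp, start = (seq_len(beads) - 1) * 2e5,
                 end = seq_len(beads) * 2e5, stringsAsFactors = FALSE)))))
  structures <- lapply(seq_len(n_cells), function(i)
    matrix(rnorm(nrow(bead_table) * 3, sd = 800), ncol = 3))
  names(structures) <- paste0("cell", seq_len(n_cells))
  genome_population(structures, bead_table,
                    nucleus_geometry("sphere", R_nuc = 5000))
}

# Two well-separated planted 2-D clouds.
two_clouds <- function(n_per = 500, gap = 50, sd = 1, seed = 1) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, gap, sd), rnorm(n_per, 0, sd)))
  list(points = pts, labels = rep(1:2, each = n_per))
}

# Block-structured average distance matrix with a boundary after bin `b`:
# small distances within blocks, large across.
planted_boundary_dm <- function(n = 40, b = 20, lo = 0.2, hi = 0.9,
                                seed = 1) {
  set.seed(seed)
  m <- matrix(hi, n, n) + matrix(rnorm(n * n, sd = 0.01), n)
  m <- (m + t(m)) / 2
  blocks <- list(1:b, (b + 1):n)
  for (bl in blocks) m[bl, bl] <- lo + abs(matrix(rnorm(length(bl)^2, sd = 0.01),
                                                  length(bl)))
  m[m > 1] <- 1; m[m < 0] <- 0
  diag(m) <- 0
  (m + t(m)) / 2
}
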