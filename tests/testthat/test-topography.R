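test_that("speckle prediction recovers planted A1 blobs and honors the size cutoff", {
  cfg <- simulation_config(seed = 5)
  syn <- synthetic_genome_with_speckles(cfg, n_cells = 3, k_blobs = 3)
  pop <- syn$population
  for (cell in seq_along(pop$structures)) {
    sp <- predict_speckles(pop$structures[[cell]], syn$a1, R_bead = cfg$R_bead)
    expect_equal(nrow(sp$centers), 3)
    # centroid error below one bead radius
    truth <- syn$truth[[cell]]
    for (k in seq_len(3)) {
      err <- min(sqrt(rowSums(sweep(sp$centers, 2, truth[k, ])^2)))
      expect_lt(err, cfg$R_bead)
    }
  }
  # a 3-bead clique yields no speckle (subgraphs must exceed 3 nodes)
  tight3 <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0),
                  c(1e5, 1e5, 1e5))
  sp3 <- predict_speckles(tight3, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(sp3$centers), 0)
  # five mutually close beads -> one speckle at their centroid
  set.seed(6)
  blob <- matrix(rnorm(15, sd = 50), 5)
  far <- matrix(3e4 + rnorm(30, sd = 5000), 10)
  sp5 <- predict_speckles(rbind(blob, far), c(rep(TRUE, 5), rep(FALSE, 10)))
  expect_equal(nrow(sp5$centers), 1)
  expect_equal(sp5$centers[1, ], colMeans(blob), tolerance = 1e-9)
  # two cliques of five, widely separated -> two speckles
  sp2 <- predict_speckles(rbind(blob, blob + 2e4),
                          rep(TRUE, 10))
  expect_equal(nrow(sp2$centers), 2)
  expect_equal(nrow(predict_speckles(blob, rep(FALSE, 5))$centers), 0)
})

test_that("markov clustering separates disconnected cliques", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  memb <- mcl_cluster(A)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:3])), 1)
  expect_equal(length(unique(memb[4:6])), 1)
})

test_that("speckle distance tracks use the surface convention and min over speckles", {
  coords <- rbind(c(0, 0, 0), c(1000, 0, 0))
  sp1 <- list(centers = rbind(c(0, 0, 0)), sizes = 5L)
  sp2 <- list(centers = rbind(c(0, 0, 0), c(1000, 0, 0)), sizes = c(5L, 5L))
  t1 <- speckle_distance_track(list(coords), list(sp1), R_bead = 118)
  expect_equal(t1, c(-118, 1000 - 118))       # bead at center: -R_bead surface
  t1c <- speckle_distance_track(list(coords), list(sp1), convention = "center")
  expect_equal(t1c, c(0, 1000))
  # more speckles never increase the distance
  t2 <- speckle_distance_track(list(coords), list(sp2))
  expect_true(all(t2 <= t1 + 1e-12))
  # structures without speckles drop out of the mean with a warning
  none <- list(centers = matrix(0, 0, 3), sizes = integer(0))
  expect_warning(
    t3 <- speckle_distance_track(list(coords, coords), list(sp1, none)),
    "excluded")
  expect_equal(t3, t1)
})

test_that("SON TSA-seq decays exponentially and normalizes to the genome mean", {
  coords <- rbind(c(118, 0, 0), c(1118, 0, 0), c(2118, 0, 0))
  sp <- list(centers = rbind(c(0, 0, 0)), sizes = 5L)
  ts <- son_tsaseq_track(list(coords), list(sp), k = 4)
  # surface distances 0, 1, 2 um -> signals 1, e^-4, e^-8
  expect_equal(ts$signal, exp(-4 * c(0, 1, 2)), tolerance = 1e-9)
  # two-speckle toy value matches the hand sum
  sp2 <- list(centers = rbind(c(0, 0, 0), c(2236, 0, 0)))
  ts2 <- son_tsaseq_track(list(coords[1, , drop = FALSE]), list(sp2), k = 4)
  expect_equal(ts2$signal, exp(0) + exp(-4 * 2), tolerance = 1e-9)
  # genome-mean normalization: the linearized track averages to exactly 1
  expect_equal(mean(2^ts$track), 1, tolerance = 1e-9)
  # doubling all distances strictly decreases every signal
  ts3 <- son_tsaseq_track(list(coords * 2), list(sp), k = 4)
  expect_true(all(ts3$signal < ts$signal))
})

test_that("SAF counts structures within the association threshold", {
  sp <- list(centers = rbind(c(0, 0, 0)), sizes = 5L)
  near <- rbind(c(500, 0, 0)); far <- rbind(c(5000, 0, 0))
  structs <- c(replicate(3, near, simplify = FALSE),
               replicate(7, far, simplify = FALSE))
  saf <- saf_track(structs, replicate(10, sp, simplify = FALSE), d_t = 1000)
  expect_equal(saf, 0.3)
  expect_equal(saf_track(structs, replicate(10, sp, simplify = FALSE),
                         d_t = 1e9), 1)
  expect_equal(saf_track(structs, replicate(10, sp, simplify = FALSE),
                         d_t = 1e-9), 0)
})

test_that("proximity maps and IPP match a brute-force pair scan", {
  cfg <- simulation_config(seed = 7)
  syn <- synthetic_genome_with_speckles(cfg, n_cells = 3,
                                        beads_per_chrom = 10)
  pop <- syn$population
  bt <- pop$bead_table
  pm <- proximity_map(pop$structures, bt, "chr1", R_soft = 2000)
  expect_true(all(pm >= 0 & pm <= 1))
  # brute force for one target bin x partner bin, averaged over copies
  X <- pop$structures
  tgt <- list(which(bt$chrom == "chr1" & bt$copy == 0),
              which(bt$chrom == "chr1" & bt$copy == 1))
  prt <- list(which(bt$chrom == "chr2" & bt$copy == 0),
              which(bt$chrom == "chr2" & bt$copy == 1))
  i <- 3; j <- 5
  manual <- mean(vapply(X, function(x) {
    mean(vapply(1:2, function(tc) mean(vapply(1:2, function(pc)
      as.numeric(sqrt(sum((x[tgt[[tc]][i], ] - x[prt[[pc]][j], ])^2)) <= 2000),
      0)), 0))
  }, 0))
  expect_equal(unname(pm[i, 10 + j]), manual, tolerance = 1e-12)
  # IPP: brute-force inter-chromosomal count for bin i
  ipp <- ipp_track(X, bt, "chr1", R_soft = 2000)
  part_all <- which(bt$chrom == "chr2")
  manual_ipp <- mean(vapply(X, function(x) {
    mean(vapply(1:2, function(tc)
      sum(sqrt(colSums((t(x[part_all, , drop = FALSE]) -
                          x[tgt[[tc]][i], ])^2)) <= 2000), 0))
  }, 0))
  expect_equal(ipp[i], manual_ipp, tolerance = 1e-12)
  # isolated chromosome: IPP = 0
  iso <- lapply(X, function(x) { x[part_all, ] <- x[part_all, ] + 5e4; x })
  expect_equal(ipp_track(iso, bt, "chr1"), rep(0, 10))
})

test_that("IPP ranking puts a planted partner enrichment first", {
  set.seed(8)
  beads <- 8
  bt <- do.call(rbind, lapply(c("chr1", "chr2", "chr3"), function(ch)
    do.call(rbind, lapply(0:1, function(cp)
      data.frame(chrom = ch, copy = cp, start = (seq_len(beads) - 1) * 2e5,
                 end = seq_len(beads) * 2e5, stringsAsFactors = FALSE)))))
  gen_struct <- function(pull2 = FALSE) {
    x <- matrix(rnorm(nrow(bt) * 3, sd = 3000), ncol = 3)
    base <- x[bt$chrom == "chr1" & bt$copy == 0, ]
    if (pull2) {
      sel <- bt$chrom == "chr2"
      x[sel, ] <- base[rep(1:beads, 2), ] + matrix(rnorm(sum(sel) * 3,
                                                         sd = 500), ncol = 3)
      x[bt$chrom == "chr1" & bt$copy == 1, ] <- base +
        matrix(rnorm(beads * 3, sd = 500), ncol = 3)
    }
    x
  }
  ens <- lapply(1:12, function(i) gen_struct(i %% 2 == 0))
  clu <- lapply(1:6, function(i) gen_struct(TRUE))    # chr2 hugs chr1
  rk <- ipp_ranking(clu, ens, bt, "chr1")
  expect_equal(names(rk)[1], "chr2")
  expect_gt(rk[["chr2"]], rk[["chr3"]])
})
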