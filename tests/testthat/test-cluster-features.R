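test_that("contact matrices use an inclusive 3 R_bead threshold and sum over clusters", {
  s <- rbind(c(0, 0, 0), c(354, 0, 0), c(708, 0, 0))
  cm <- contact_matrix(s)                       # default 3 * 118 = 354
  expect_equal(cm[1, 2], 1L)                    # boundary case inclusive
  expect_equal(cm[2, 3], 1L)
  expect_equal(contact_matrix(rbind(c(0, 0, 0), c(355, 0, 0)))[1, 2], 0L)
  expect_equal(cm[1, 3], 0L)
  ten <- replicate(10, s, simplify = FALSE)
  expect_equal(cluster_contact_matrix(ten), 10L * cm)
})

test_that("ensemble contact counts are conserved across clusters", {
  set.seed(1)
  structs <- lapply(1:9, function(i) toy_structure(15, seed = i))
  labels <- c(1, 1, 1, 2, 2, NA, NA, 2, 1)
  ens <- cluster_contact_matrix(structs)
  parts <- lapply(list(which(labels %in% 1), which(labels %in% 2),
                       which(is.na(labels))),
                  function(ix) cluster_contact_matrix(structs[ix]))
  expect_identical(Reduce(`+`, parts), ens)
})

test_that("average distance matrices are means of min-max normalized matrices", {
  a <- toy_structure(10, seed = 1); b <- toy_structure(10, seed = 2)
  expect_equal(average_distance_matrix(list(a)),
               normalize_minmax(center_distance_matrix(a)),
               ignore_attr = TRUE)
  two <- average_distance_matrix(list(a, b))
  expect_equal(two, (normalize_minmax(center_distance_matrix(a)) +
                       normalize_minmax(center_distance_matrix(b))) / 2,
               ignore_attr = TRUE)
  expect_true(all(two >= 0 & two <= 1))
})

test_that("insulation profiles match the naive window-sum oracle", {
  naive <- function(M, variant, l, thr = 0.45) {
    n <- nrow(M)
    B <- if (variant == "distance") (M > thr) * 1 else M
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - l < 1 || i + l - 1 > n) next
      L <- (i - l):(i - 1); R <- i:(i + l - 1)
      lm <- 0; for (a in L) for (b in L) if (a < b) lm <- lm + B[a, b]
      rm_ <- 0; for (a in R) for (b in R) if (a < b) rm_ <- rm_ + B[a, b]
      cross <- sum(B[L, R])
      out[i] <- if (variant == "contact") lm + rm_ - cross
                else cross - lm - rm_
    }
    out
  }
  set.seed(2)
  for (rep in 1:3) {
    DM <- planted_boundary_dm(30, b = 10 + rep * 3, seed = rep)
    expect_equal(insulation_profile(DM, "distance", 6),
                 naive(DM, "distance", 6), tolerance = 1e-9)
    CM <- matrix(rpois(900, 3), 30); CM <- CM + t(CM)
    expect_equal(insulation_profile(CM, "contact", 5),
                 naive(CM, "contact", 5), tolerance = 1e-9)
  }
  # block-diagonal binary distance matrix: global max at the junction
  DM <- planted_boundary_dm(40, b = 20)
  prof <- insulation_profile(DM, "distance", 8)
  expect_equal(which.max(prof), 21, tolerance = 1)
  # uniform matrix: flat profile
  flat <- insulation_profile(matrix(1, 30, 30), "contact", 5)
  expect_equal(sd(flat, na.rm = TRUE), 0)
  expect_error(insulation_profile(DM, "distance", 25), "half")
})

test_that("boundary calling recovers planted junctions and stays silent on homogeneous input", {
  for (b in c(15, 20, 25)) {
    DM <- planted_boundary_dm(60, b = b, seed = b)
    bd <- call_boundaries(DM, coarse_window = 14, fine_window = 5)
    expect_length(bd, 1)
    expect_lte(abs(bd - (b + 1)), 1)
  }
  # three domains -> two boundaries
  dm3 <- planted_boundary_dm(60, b = 20)
  dm3[41:60, 41:60] <- planted_boundary_dm(60, b = 20)[1:20, 1:20]
  dm3[41:60, 1:40] <- 0.9; dm3[1:40, 41:60] <- 0.9; diag(dm3) <- 0
  bd3 <- call_boundaries(dm3, coarse_window = 12, fine_window = 5)
  expect_length(bd3, 2)
  expect_true(all(abs(bd3 - c(21, 41)) <= 1))
  # homogeneous matrix: nothing called
  hom <- matrix(0.2, 60, 60); diag(hom) <- 0
  expect_length(call_boundaries(hom, 14, 5), 0)
})

test_that("radius of gyration matches closed forms and scales linearly", {
  # five coincident beads
  expect_equal(rg_profile(matrix(1, 5, 3))[3], 0)
  # collinear beads at spacing a: rg = a sqrt(2)
  a <- 37.5
  line <- cbind(a * (1:5), 0, 0)
  expect_equal(rg_profile(line)[3], a * sqrt(2), tolerance = 1e-12)
  expect_equal(structure_rg(line), a * sqrt(2), tolerance = 1e-12)
  s <- toy_structure(11)
  expect_equal(rg_profile(s$coords * 3), 3 * rg_profile(s$coords))
  expect_true(all(is.na(rg_profile(s)[c(1, 2, 10, 11)])))
})

test_that("radial tracks and variability follow the geometry conventions", {
  sph <- nucleus_geometry("sphere", R_nuc = 5000)
  structs <- list(rbind(c(0, 0, 0), c(3000, 0, 0)),
                  rbind(c(0, 0, 0), c(0, 4000, 0)))
  expect_equal(radial_track(structs, sph), c(0, 0.7))
  ell <- nucleus_geometry("ellipsoid", semiaxes = c(7840, 6470, 2450))
  expect_equal(radial_track(list(rbind(c(7840, 0, 0))), ell), 1)
  # sigma = 0 bins are NA
  v <- variability_track(structs, sph)
  expect_true(is.na(v[1]))
  expect_false(is.na(v[2]))
})

test_that("log2 ratio tracks handle equality, doubling and inversion", {
  ens <- c(1, 2, 4, 0, NA)
  expect_equal(log2_ratio_track(ens, ens), c(0, 0, 0, NA, NA))
  expect_equal(log2_ratio_track(2 * ens, ens)[1:3], c(1, 1, 1))
  r <- log2_ratio_track(c(1, 8), c(2, 2))
  expect_equal(log2_ratio_track(c(2, 2), c(1, 8)), -r)
})

test_that("A/B compartments from a checkerboard match the eigen oracle", {
  n <- 40
  blocks <- rep(c(1, 2), each = n / 2)
  CM <- outer(blocks, blocks, function(a, b) ifelse(a == b, 60, 10)) +
    40 * diag(n)
  ref <- as.numeric(blocks == 1)
  ab <- ab_compartments(CM, reference = ref)
  # the chosen component separates the two blocks with the reference sign
  chosen <- if (ab$component == 1) ab$PC1 else ab$PC2
  expect_true(all(chosen[1:20] > 0) && all(chosen[21:40] < 0))
  expect_equal(ab$compartment[1:20], rep(1, 20))
  # sign orientation flips deterministically with the reference
  ab2 <- ab_compartments(CM, reference = 1 - ref)
  chosen2 <- if (ab2$component == 1) ab2$PC1 else ab2$PC2
  expect_equal(chosen2, -chosen, tolerance = 1e-9)
  expect_warning(ab_compartments(matrix(1, 20, 20)), "uniform")
})

test_that("P(s) curves decay for polymers and separate planted long-range blocks", {
  cfg <- simulation_config(n_beads = 60, seed = 2)
  neg <- negative_control(cfg, n_structures = 20)
  CM <- cluster_contact_matrix(neg)
  ps <- contact_probability_curve(CM, 20)
  expect_gt(ps$prob[1], ps$prob[nrow(ps)])            # decreasing at large s
  expect_true(all(ps$s_min >= 1))                     # diagonal excluded
  # planted long-range contact block elevates the tail
  CM2 <- CM; CM2[1:5, 56:60] <- CM2[1:5, 56:60] + 20
  CM2[56:60, 1:5] <- t(CM2[1:5, 56:60])
  ps2 <- contact_probability_curve(CM2, 20)
  expect_gt(ps2$prob[nrow(ps2)], ps$prob[nrow(ps)])
})

test_that("territory domains partition the chromosome between boundaries", {
  expect_equal(territory_domains(integer(0), 50)$end_bin, 50)
  d1 <- territory_domains(21, 50)
  expect_equal(d1$start_bin, c(1, 21))
  expect_equal(d1$end_bin, c(20, 50))
  expect_equal(d1$label, c("a", "b"))
  # boundary at 155 Mb on a 171-Mb chromosome (200-kb bins)
  d2 <- territory_domains(776, 855)
  expect_equal(d2$start_bin[2] - 1, 775)   # domains split at 155 Mb
  expect_equal(nrow(d2), 2)
})
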