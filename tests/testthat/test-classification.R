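test_that("random-walk imputation satisfies its fixed point and the linear-solve oracle", {
  set.seed(1)
  raw <- matrix(rpois(400, 1), 20); raw <- raw + t(raw)
  st <- impute_scihic(raw, w = 2, return_stages = TRUE)
  # fixed point: R = (1-p) R M + p I to within the tolerance
  res <- st$rwr - (0.5 * st$rwr %*% st$trans + 0.5 * diag(20))
  expect_lte(sqrt(sum(res^2)), 1e-6 + 1e-9)
  # w = 0 on a 10x10: converged R equals the closed form p (I - (1-p) M)^-1
  raw10 <- matrix(rpois(100, 2), 10); raw10 <- raw10 + t(raw10) + diag(10)
  st10 <- impute_scihic(raw10, w = 0, tol = 1e-12, return_stages = TRUE)
  closed <- 0.5 * solve(diag(10) - 0.5 * st10$trans)
  expect_equal(st10$rwr, closed, tolerance = 1e-6)
  # per-row retained fraction <= 25%
  expect_true(all(rowMeans(st$binarized) <= 0.25 + 1e-9))
  # all-zero row stays zero with a warning
  raw0 <- raw; raw0[3, ] <- 0; raw0[, 3] <- 0
  raw0[abs(row(raw0) - col(raw0)) > 1] <- 0   # isolate row 3 from the filter
  expect_warning(impute_scihic(raw0, w = 0), "all-zero")
})

test_that("difference-matrix masks follow the printed thresholds", {
  # hand 3x3 case
  cmA <- matrix(c(4, 1, 0, 1, 2, 8, 0, 8, 2), 3)
  cmP <- matrix(c(128, 64, 3, 64, 64, 4, 3, 4, 64), 3)
  mk <- build_masks(cmA, cmP, S_A = 1, S_pop = 1)
  d <- log2(cmP / cmA)
  expect_equal(mk$d[2, 2], d[2, 2])
  expect_equal(mk$sup, (is.finite(d) & d >= 5 & cmA > 0) * 1L,
               ignore_attr = TRUE)
  expect_equal(mk$inf[2, 3], 1L)               # log2(4/8) = -1 (inclusive)
  # zero entries belong to neither mask
  expect_equal(mk$sup[1, 3] + mk$inf[1, 3], 0)
  # cluster = scaled population: both masks empty
  mk0 <- build_masks(2 * cmP, cmP, S_A = 2, S_pop = 1)
  expect_equal(sum(mk0$sup) + sum(mk0$inf), 0)
  # masks are disjoint
  expect_true(all(mk$sup + mk$inf <= 1))
})

test_that("mask scoring assigns by margin and normalizes probabilities", {
  n <- 10
  mkA <- list(sup = matrix(0L, n, n), inf = matrix(0L, n, n))
  mkB <- list(sup = matrix(0L, n, n), inf = matrix(0L, n, n))
  mkA$inf[1, 2] <- mkA$inf[2, 1] <- 1L
  mkB$sup[1, 2] <- mkB$sup[2, 1] <- 1L
  cell <- matrix(0L, n, n); cell[1, 2] <- cell[2, 1] <- 1L
  r <- suppressWarnings(score_scihic(cell, list(A = mkA, B = mkB)))
  expect_equal(r$assigned, "A")                  # hits A's enrichment cells
  expect_equal(unname(r$scores), c(exp(1), exp(-1)))
  expect_equal(sum(r$probabilities), 1)
  # all-ones cell scores exp(1-1) = 1 for every mask -> unassigned
  ones <- matrix(1L, n, n)
  mkC <- list(sup = mkA$inf, inf = mkB$sup)
  r2 <- score_scihic(ones, list(A = list(sup = mkA$inf, inf = mkB$sup),
                                B = list(sup = mkB$sup, inf = mkA$inf)))
  expect_true(is.na(r2$assigned))
  expect_equal(unname(r2$scores), c(1, 1))
  # empty mask contributes 0 with a warning
  expect_warning(
    r3 <- score_scihic(cell, list(A = list(sup = matrix(0L, n, n),
                                           inf = mkA$inf))),
    "empty mask")
  expect_equal(unname(r3$scores), exp(1))
})

test_that("randomized controls preserve diagonal and total counts", {
  set.seed(2)
  raw <- matrix(rpois(225, 2), 15); raw <- raw + t(raw)
  shuf <- randomize_control(raw, seed = 3)
  expect_equal(diag(shuf), diag(raw))
  expect_equal(sum(shuf), sum(raw))
  expect_equal(shuf, t(shuf))
  expect_equal(sort(shuf[upper.tri(shuf)]), sort(raw[upper.tri(raw)]))
  # symmetrize_min
  m <- matrix(c(0, 5, 3, 0), 2)
  expect_equal(symmetrize_min(m), matrix(c(0, 3, 3, 0), 2))
  expect_equal(symmetrize_min(symmetrize_min(m)), symmetrize_min(m))
})

test_that("structure classification is correlation-based and scale invariant", {
  set.seed(4)
  # two references with genuinely distinct territory-domain layouts
  refs <- make_reference_conformations(
    simulation_config(n_clusters = 2, n_beads = 40, seed = 6,
                      boundaries = list(20, integer(0))))
  refA <- refs[[1]]$coords
  refB <- refs[[2]]$coords * 0.4
  dms <- list(A = center_distance_matrix(refA),
              B = center_distance_matrix(refB))
  # a structure equal to a cluster mean gets r = 1, s = e
  r <- classify_structure(refA, dms)
  expect_equal(unname(r$scores["A"]), exp(1), tolerance = 1e-9)
  expect_equal(r$assigned, "A")
  # global scaling of the input changes nothing
  r2 <- classify_structure(refA * 7.3, dms)
  expect_equal(r2$scores, r$scores, tolerance = 1e-9)
  # noisy replicates are assigned to their generating reference
  ok <- vapply(1:20, function(i) {
    x <- refB + matrix(rnorm(length(refB), sd = 20), ncol = 3)
    identical(classify_structure(x, dms)$assigned, "B")
  }, TRUE)
  expect_gte(mean(ok), 0.99)
  expect_error(classify_structure(refA[1:2, ], lapply(dms, function(m)
    m[1:2, 1:2])), "at least 3")
})

test_that("transcription ratios compare cluster means to the clustered mean", {
  counts <- c(2, 2, 2, 2, 4, 4, 100)
  labels <- c(1, 1, 1, 1, 2, 2, NA)   # unclustered copy excluded
  r <- transcription_ratio(counts, labels)
  overall <- mean(c(2, 2, 2, 2, 4, 4))
  expect_equal(r[["1"]], log2(2 / overall))
  expect_equal(r[["2"]], log2(4 / overall))
  # uniform transcription -> 0 everywhere
  expect_equal(unname(transcription_ratio(rep(3, 6), labels[1:6])), c(0, 0))
  expect_warning(transcription_ratio(rep(0, 4), rep(1:2, 2)), "zero overall")
})
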