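test_that("3-sigma outlier removal keeps tight clouds and drops extremes", {
  # all points identical: nothing removed
  same <- matrix(1, 10, 2)
  expect_length(remove_outliers(same)$removed, 0)
  # one point at 100x the spread is removed
  set.seed(1)
  pts <- rbind(matrix(rnorm(2000), ncol = 2), c(100, 100))
  out <- remove_outliers(pts)
  expect_equal(out$removed, 1001L)
  # isotropic Gaussian: the 3-sigma rule retains almost everything
  frac <- vapply(2:4, function(sd_) {
    set.seed(sd_)
    g <- matrix(rnorm(4000), ncol = 2)
    length(remove_outliers(g)$kept) / 2000
  }, 0)
  expect_gte(mean(frac), 0.985)
  expect_gte(min(frac), 0.97)
})

test_that("KDE grid integrates to ~1 and peaks at the sample mean", {
  set.seed(3)
  pts <- cbind(rnorm(2000, 5, 0.5), rnorm(2000, -2, 0.5))
  grid <- kde_density(pts, gridsize = 200)
  # argmax within one bandwidth of the sample mean
  am <- which(grid$P == max(grid$P), arr.ind = TRUE)[1, ]
  expect_lt(abs(grid$x[am[1]] - mean(pts[, 1])), grid$bandwidth[1])
  expect_lt(abs(grid$y[am[2]] - mean(pts[, 2])), grid$bandwidth[2])
  # mass on an enlarged grid (pad so tails are covered)
  pad <- rbind(pts, c(2, -8), c(8, 4))  # corners widen the bounding box
  g2 <- kde_density(pad, gridsize = 400)
  cell <- diff(g2$x[1:2]) * diff(g2$y[1:2])
  expect_equal(sum(g2$P) * cell, 1, tolerance = 0.02)
  # two clouds 10 sigma apart give two local maxima
  two <- two_clouds(400, gap = 10, sd = 1, seed = 4)
  g3 <- kde_density(two$points, gridsize = 200)
  expect_equal(nrow(detect_peaks(g3)), 2)
  expect_warning(kde_density(matrix(c(1, 1, 1, 2, 1, 3), ncol = 2,
                                    byrow = TRUE)), "degenerate")
})

test_that("maximum-filter peak detection matches the brute-force oracle", {
  brute <- function(P, r = 2) {
    idx <- NULL
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
      if (P[i, j] == 0) next
      nb <- P[max(1, i - r):min(nrow(P), i + r),
              max(1, j - r):min(ncol(P), j + r)]
      if (P[i, j] >= max(nb) && sum(nb == max(nb)) == 1)
        idx <- rbind(idx, c(i, j))
    }
    idx
  }
  canon <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  set.seed(5)
  for (rep in 1:5) {
    P <- matrix(runif(30 * 30), 30)
    P[P < 0.2] <- 0   # some exact zeros
    expect_equal(canon(detect_peaks(P)), canon(brute(P)), ignore_attr = TRUE)
  }
  # degenerate grids
  expect_equal(nrow(detect_peaks(matrix(0, 20, 20))), 0)
  uni <- outer(1:30, 1:30, function(i, j) dnorm(i, 15, 5) * dnorm(j, 15, 5))
  expect_equal(nrow(detect_peaks(uni)), 1)
  # a smaller maximum within the 5x5 window of a larger one is absorbed
  close2 <- matrix(0, 20, 20); close2[10, 10] <- 1; close2[10, 12] <- 0.8
  expect_equal(nrow(detect_peaks(close2)), 1)
  far2 <- matrix(0, 20, 20); far2[5, 5] <- 1; far2[15, 15] <- 0.8
  expect_equal(nrow(detect_peaks(far2)), 2)
  # exact plateau ties collapse to the lexicographically smallest index
  tie <- matrix(0, 20, 20); tie[10, 10] <- 1; tie[10, 12] <- 1
  expect_equal(detect_peaks(tie), rbind(c(10L, 10L)), ignore_attr = TRUE)
})

test_that("watershed assignment recovers planted clouds and filters small clusters", {
  two <- two_clouds(500, gap = 40, sd = 1, seed = 6)
  grid <- kde_density(two$points, gridsize = 300)
  peaks <- detect_peaks(grid)
  expect_gte(nrow(peaks), 2)  # spurious shoulder peaks die in the size filter
  asg <- watershed_assign(grid, peaks, two$points, min_size = 100)
  expect_equal(length(asg$sizes), 2)
  # label recovery: no mixing between the planted clouds
  tab <- table(two$labels, asg$labels, useNA = "no")
  expect_equal(sum(tab) - sum(apply(tab, 2, max)), 0)
  expect_gte(min(asg$sizes), 450)
  expect_equal(sum(asg$occupancy), 1)
  # a 50-point cloud is discarded by the size filter
  small <- rbind(two$points, cbind(rnorm(50, 20, 0.5), rnorm(50, 30, 0.5)))
  g2 <- kde_density(small, gridsize = 300)
  p2 <- detect_peaks(g2)
  asg2 <- watershed_assign(g2, p2, small, min_size = 100)
  expect_equal(length(asg2$sizes), 2)
  expect_true(all(is.na(asg2$labels[1001:1050])))
  # single cloud: one cluster holding everything dense enough
  one <- matrix(rnorm(600), ncol = 2)
  g3 <- kde_density(one, gridsize = 200)
  asg3 <- watershed_assign(g3, detect_peaks(g3), one, min_size = 100)
  expect_equal(length(asg3$sizes), 1)
})

test_that("silhouette matches the per-point formula and its closed forms", {
  # brute-force oracle on a 20-point fixture
  set.seed(7)
  pts <- rbind(matrix(rnorm(20, 0, 1), ncol = 2),
               matrix(rnorm(20, 6, 1), ncol = 2))
  lab <- rep(1:2, each = 10)
  sil <- silhouette_score(pts, lab)
  D <- as.matrix(dist(pts))
  for (i in seq_len(20)) {
    a <- mean(D[i, setdiff(which(lab == lab[i]), i)])
    b <- mean(D[i, lab != lab[i]])
    expect_equal(sil$values[i], (b - a) / max(a, b), tolerance = 1e-12)
  }
  # two near-point-masses far apart: mean ~ 1
  eps <- two_clouds(20, gap = 1000, sd = 1e-3, seed = 8)
  expect_gt(silhouette_score(eps$points, eps$labels)$mean, 0.999)
  # random labels on one cloud: mean ~ 0
  set.seed(9)
  cloud <- matrix(rnorm(400), ncol = 2)
  rl <- sample(1:2, 200, replace = TRUE)
  expect_lt(abs(silhouette_score(cloud, rl)$mean), 0.1)
  expect_error(silhouette_score(cloud, rep(1, 200)), "at least 2")
  # NA labels are excluded
  lab_na <- lab; lab_na[1:3] <- NA
  expect_length(silhouette_score(pts, lab_na)$values, 17)
})

test_that("occupancy and intermediate selection behave as defined", {
  expect_equal(unname(occupancy(c(rep(1, 300), rep(2, 100)))), c(0.75, 0.25))
  expect_equal(unname(occupancy(rep(1, 10))), 1)
  # unclustered points are excluded from the denominator
  expect_equal(unname(occupancy(c(rep(1, 30), rep(2, 10), rep(NA, 60)))),
               c(0.75, 0.25))
  two <- two_clouds(300, gap = 40, sd = 1, seed = 10)
  mid <- cbind(rnorm(5, 20, 0.3), rnorm(5, 0, 0.3))   # planted midway points
  pts <- rbind(two$points, mid)
  grid <- kde_density(pts, gridsize = 300)
  asg <- watershed_assign(grid, detect_peaks(grid), pts, min_size = 100)
  sel <- select_intermediates(pts, asg, grid, c(1, 2))
  expect_true(all(601:605 %in% sel))
  expect_length(select_intermediates(pts, asg, grid, c(1, 2),
                                     radius_frac = 0), 0)
})
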