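# Training sets for the autoencoder tests: small planted-cluster distance
# matrices at the minimum meaningful side (100).
ae_fixture <- function(n_per = 12, seed = 1) {
  cfg <- simulation_config(n_beads = 120, structures_per_cluster = n_per,
                           sigmas = c(0.2, 0.4), n_clusters = 2, seed = seed)
  pos <- positive_control(cfg)
  mats <- lapply(pos$matrices, resize_to_multiple_of_50, side = 100)
  list(mats = mats, labels = pos$labels)
}

test_that("autoencoder training reduces the reconstruction loss and bounds outputs", {
  fx <- ae_fixture()
  spec <- autoencoder_spec(epochs = 6, batch = 8)
  model <- train_autoencoder(fx$mats, spec, seed = 2)
  expect_length(model$loss, 6)
  expect_lt(tail(model$loss, 1), model$loss[1])
  rec <- reconstruct(model, fx$mats[1:2])
  expect_true(all(rec[[1]] >= 0 & rec[[1]] <= 1))     # sigmoid range
  # latent dimensionality: (side/50)^2 x last encoder filter count,
  # about 700x smaller than the input entries
  lat <- encode(model, fx$mats)
  expect_equal(ncol(lat), (100 / 50)^2 * 4)
  expect_equal(100^2 / ncol(lat), 625)
  expect_equal(nrow(lat), length(fx$mats))
  # identical inputs give identical latents
  lat2 <- encode(model, list(fx$mats[[1]], fx$mats[[1]]))
  expect_equal(lat2[1, ], lat2[2, ])
  # held-out reconstruction error is within 2x the training error
  idx <- seq(1, length(fx$mats), by = 5)
  m_tr <- train_autoencoder(fx$mats[-idx], spec, seed = 2)
  expect_lt(reconstruction_mse(m_tr, fx$mats[idx]),
            2 * reconstruction_mse(m_tr, fx$mats[-idx]) + 1e-4)
  # shape guards
  expect_error(train_autoencoder(list(matrix(0.5, 60, 60)), spec),
               "divisible")
  expect_error(train_autoencoder(list(matrix(2, 100, 100)), spec), "0, 1")
  expect_error(encode(model, list(matrix(0.5, 150, 150))), "side")
})

test_that("training is deterministic given seed and data order", {
  fx <- ae_fixture(n_per = 6)
  spec <- autoencoder_spec(epochs = 2, batch = 6)
  m1 <- train_autoencoder(fx$mats, spec, seed = 9)
  m2 <- train_autoencoder(fx$mats, spec, seed = 9)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_autoencoder(fx$mats, spec, seed = 10)
  expect_false(identical(m3$weights, m1$weights))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  mats <- lapply(1:2, function(i) {
    m <- matrix(runif(1e4), 100); (m + t(m)) / 2
  })
  spec <- autoencoder_spec(epochs = 1, batch = 2)
  model <- train_autoencoder(mats, spec, seed = 4)
  dat <- matrix(unlist(mats), nrow = 1e4)
  g <- chromomorph:::.cae_gradient(dat, 100L, unclass(spec), model$weights,
                                   model$biases)
  loss_of <- function(W) chromomorph:::.cae_gradient(dat, 100L, unclass(spec),
                                                     W, model$biases)$loss
  # check the largest-magnitude weight gradients (small ones drown in the
  # single-precision quantization of the loss)
  for (li in c(1, 4, 7)) {
    top <- order(abs(g$gW[[li]]), decreasing = TRUE)[1:3]
    for (j in top) {
      eps <- 2e-3
      Wp <- model$weights; Wp[[li]][j] <- Wp[[li]][j] + eps
      Wm <- model$weights; Wm[[li]][j] <- Wm[[li]][j] - eps
      num <- (loss_of(Wp) - loss_of(Wm)) / (2 * eps)
      expect_equal(g$gW[[li]][j], num,
                   tolerance = max(0.05, 2e-6 / abs(num)))
    }
  }
})

test_that("latent standardization z-scores dimensions and zeroes constant ones", {
  set.seed(5)
  lat <- cbind(rnorm(30, 10, 3), rnorm(30, -5, 0.1), rep(7, 30))
  z <- standardize_latents(lat)
  expect_equal(colMeans(z), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd)[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(z[, 3], rep(0, 30))
  expect_true(attr(z, "standardized"))
  expect_error(standardize_latents(lat[1, , drop = FALSE]), "at least 2")
})

test_that("t-SNE separates planted latent clusters and keeps duplicates together", {
  set.seed(6)
  lat <- rbind(matrix(rnorm(50 * 8), ncol = 8),
               matrix(rnorm(50 * 8, mean = 12), ncol = 8))
  labels <- rep(1:2, each = 50)
  expect_warning(emb <- tsne_embed(lat, seed = 7), "perplexity shrunk")
  expect_equal(ncol(emb), 2)
  expect_true(all(is.finite(emb)))
  expect_gt(silhouette_score(emb, labels)$mean, 0.5)
  # duplicate rows land closer than the typical pair
  lat_dup <- rbind(lat, lat[1, ], lat[1, ])
  expect_warning(emb2 <- tsne_embed(lat_dup, seed = 7))
  d_dup <- sqrt(sum((emb2[101, ] - emb2[102, ])^2))
  expect_lt(d_dup, quantile(dist(emb2), 0.05))
  expect_error(tsne_embed(lat[1:4, ]), "at least 5")
  # determinism given the seed
  expect_warning(emb3 <- tsne_embed(lat, seed = 7))
  expect_identical(unclass(emb3)[, ], unclass(emb)[, ])
})

test_that("alternative embeddings cover PCA/MDS/Isomap/Spectral and reject the rest", {
  set.seed(8)
  lat <- rbind(matrix(rnorm(30 * 5), ncol = 5),
               matrix(rnorm(30 * 5, mean = 8), ncol = 5))
  for (m in c("PCA", "MDS", "SpectralEmbedding")) {
    e <- alternative_embed(lat, m, seed = 1)
    expect_equal(dim(e), c(60, 2))
    expect_equal(attr(e, "method"), m)
  }
  # PCA axes are variance-ordered
  p <- alternative_embed(lat, "PCA")
  expect_gte(var(p[, 1]), var(p[, 2]))
  # MDS on exact 2D point distances recovers the configuration up to a
  # rigid motion (Procrustes oracle)
  pts <- cbind(rnorm(40), rnorm(40))
  rec <- alternative_embed(pts, "MDS")
  pc <- function(x) sweep(as.matrix(x), 2, colMeans(as.matrix(x)))
  A <- pc(pts); B <- pc(rec)
  sv <- svd(crossprod(B, A))
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(B %*% rot - A)), 1e-6)
  expect_error(alternative_embed(lat, "UMAP"), "no backend")
  expect_error(alternative_embed(lat, "nonsense"))
})
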