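# Two-step dimension reduction: convolutional autoencoder to latent vectors,
# then t-SNE to 2D.

#' Autoencoder architecture specification
#'
#' Defaults follow the reference architecture: three encoder convolutions
#' (16, 8, 4 filters, 10 x 10 kernels, stride 1, same padding, ReLU) each
#' followed by max pooling (5, 5, 2); the decoder mirrors them (4, 8, 16
#' filters with nearest-neighbour upsampling 2, 5, 5) and ends in a single
#' sigmoid filter so outputs lie in `[0, 1]`. Training: 15 epochs, batch
#' 200, MSE loss, Adadelta. The input side must be divisible by
#' `prod(pools)` (50 by default); the latent matrix is then
#' `(side/50) x (side/50) x 4`, roughly 700 times smaller than the input.
#'
#' @param enc_filters,dec_filters Integer vectors of filter counts.
#' @param pools,ups Pooling windows / upsampling factors.
#' @param kernel Convolution kernel side.
#' @param epochs,batch Training schedule.
#' @return List of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(enc_filters = c(16L, 8L, 4L),
                             pools = c(5L, 5L, 2L),
                             dec_filters = c(4L, 8L, 16L),
                             ups = c(2L, 5L, 5L),
                             kernel = 10L, epochs = 15L, batch = 200L) {
  stopifnot(length(enc_filters) == length(pools),
            length(dec_filters) == length(ups),
            prod(pools) == prod(ups))
  structure(list(enc_filters = as.integer(enc_filters),
                 pools = as.integer(pools),
                 dec_filters = as.integer(dec_filters),
                 ups = as.integer(ups), kernel = as.integer(kernel),
                 epochs = as.integer(epochs), batch = as.integer(batch)),
            class = "autoencoder_spec")
}

# Stack a list of matrices into the (side^2 x n) column layout the C++ side
# expects; validates a common side and the [0, 1] value range.
stack_matrices <- function(matrices, spec) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  side <- nrow(matrices[[1]])
  block <- prod(spec$pools)
  if (side %% block != 0)
    stop("matrix side ", side, " is not divisible by ", block,
         " (pooling factor); resize the inputs first")
  for (m in matrices) {
    if (nrow(m) != side || ncol(m) != side)
      stop("all matrices must share side ", side)
  }
  rng <- range(vapply(matrices, range, numeric(2)))
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("matrix values must lie in [0, 1]; normalize the inputs first")
  matrix(unlist(matrices, use.names = FALSE), nrow = side * side)
}

#' Train the convolutional autoencoder
#'
#' @param matrices List of square normalized distance matrices (equal side, a
#'   multiple of the pooling factor, values in `[0, 1]`).
#' @param spec An [autoencoder_spec()].
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch shuffling of the training set.
#' @return Object of class `conv_autoencoder` with elements `weights`,
#'   `biases`, `loss` (per-epoch training MSE), `side`, `spec`, `seed`.
#' @export
train_autoencoder <- function(matrices, spec = autoencoder_spec(), seed = 1L) {
  dat <- stack_matrices(matrices, spec)
  side <- as.integer(sqrt(nrow(dat)))
  fit <- .cae_train(dat, side, unclass(spec), spec$epochs, spec$batch,
                    as.integer(seed))
  structure(list(weights = fit$W, biases = fit$b,
                 loss = as.numeric(fit$loss), side = side, spec = spec,
                 seed = as.integer(seed)),
            class = "conv_autoencoder")
}

#' @export
print.conv_autoencoder <- function(x, ...) {
  cat(sprintf("<conv_autoencoder side %d, %d epochs, final MSE %.3g>\n",
              x$side, length(x$loss), tail(x$loss, 1)))
  invisible(x)
}

#' Encode matrices to latent vectors
#'
#' Each latent matrix is flattened in a fixed order (column-major over the
#' spatial dimensions, then channels), giving one vector per structure of
#' length `(side/50)^2 x` last encoder filter count.
#'
#' @param model A trained [train_autoencoder()] model.
#' @param matrices List of matrices with the model's input side.
#' @return Numeric n x d matrix with attribute `standardized = FALSE`.
#' @export
encode <- function(model, matrices) {
  dat <- stack_matrices(matrices, model$spec)
  if (nrow(dat) != model$side^2)
    stop("matrix side does not match the trained model (", model$side, ")")
  out <- .cae_forward(dat, model$side, unclass(model$spec), model$weights,
                      model$biases, TRUE)
  lat <- out$latent
  attr(lat, "standardized") <- FALSE
  lat
}

#' Reconstruct matrices through the autoencoder
#' @inheritParams encode
#' @return List of reconstructed matrices (values in `[0, 1]`).
#' @export
reconstruct <- function(model, matrices) {
  dat <- stack_matrices(matrices, model$spec)
  out <- .cae_forward(dat, model$side, unclass(model$spec), model$weights,
                      model$biases, FALSE)
  lapply(seq_len(ncol(out$recon)),
         function(i) matrix(out$recon[, i], model$side, model$side))
}

#' Mean reconstruction error of a model on a set of matrices
#' @inheritParams encode
#' @return Mean squared error per pixel, averaged over matrices.
#' @export
reconstruction_mse <- function(model, matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  rec <- reconstruct(model, matrices)
  mean(vapply(seq_along(matrices),
              function(i) mean((rec[[i]] - matrices[[i]])^2), 0))
}

#' Standardize latent vectors
#'
#' Per-dimension z-scoring over the set: each latent dimension gets mean 0
#' and standard deviation 1. Zero-variance dimensions are set to 0.
#'
#' @param latents n x d latent matrix.
#' @return Standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_latents <- function(latents) {
  if (nrow(latents) < 2) stop("need at least 2 vectors")
  mu <- colMeans(latents)
  sdv <- apply(latents, 2, sd)
  out <- sweep(latents, 2, mu)
  pos <- sdv > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, sdv[pos], "/")
  out[, !pos] <- 0
  attr(out, "standardized") <- TRUE
  out
}

# Perplexity calibration: per-point binary search for the Gaussian precision
# whose conditional distribution has the requested perplexity, then
# symmetrization P = (P + t(P)) / (2n). The search itself runs in C++.
tsne_affinities <- function(X, perplexity) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  .tsne_affinities(D2, perplexity)
}

#' t-SNE embedding of latent vectors
#'
#' Exact t-SNE to two dimensions with the defaults used throughout the
#' package: perplexity 200, learning rate 1000, 1000 iterations (early
#' exaggeration 12 for the first 250, momentum 0.5 then 0.8). When fewer
#' than `3 * perplexity + 1` points are given the perplexity is shrunk with
#' a warning.
#'
#' @param latents n x d matrix (standardized latent vectors).
#' @param perplexity Target perplexity of the conditional distributions.
#' @param learning_rate Gradient-descent learning rate.
#' @param seed Integer seed for the random initialization.
#' @param n_iter Number of gradient iterations.
#' @return n x 2 matrix of class `embedding2d` with attributes `method` and
#'   `seed`.
#' @export
tsne_embed <- function(latents, perplexity = 200, learning_rate = 1000,
                       seed = 1L, n_iter = 1000L) {
  n <- nrow(latents)
  if (n < 5) stop("need at least 5 points")
  if (n < 3 * perplexity + 1) {
    perplexity <- max(5, floor((n - 1) / 3))
    warning("perplexity shrunk to ", perplexity, " for ", n, " points")
  }
  P <- tsne_affinities(as.matrix(latents), perplexity)
  Y <- .tsne_optimize(P, as.integer(seed), as.integer(n_iter),
                      learning_rate, 12, 250L, 250L)
  structure(Y, method = "tsne", seed = as.integer(seed),
            perplexity = perplexity, class = c("embedding2d", class(Y)))
}

# Nearest-neighbour graph Laplacian eigenmap (spectral embedding).
spectral_embed <- function(X, k = 10) {
  n <- nrow(X)
  k <- min(k, n - 1)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[2:(k + 1)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))
  d <- rowSums(A)
  d[d == 0] <- 1
  L <- diag(n) - diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  e <- eigen(L, symmetric = TRUE)
  e$vectors[, c(n - 1, n - 2)]
}

#' Alternative 2D embeddings of latent vectors
#'
#' A generic hook for comparing the t-SNE step against other reductions.
#' Supported here: `PCA`, `MDS` (classical, Euclidean dissimilarities),
#' `Isomap` (via \pkg{vegan} when available) and `SpectralEmbedding`.
#' `LLE` and `UMAP` are recognised method names but have no backend in this
#' build and raise an informative error.
#'
#' @param latents n x d matrix.
#' @param method One of `"PCA"`, `"MDS"`, `"LLE"`, `"Isomap"`,
#'   `"SpectralEmbedding"`, `"UMAP"`.
#' @param seed Integer seed (recorded; the supported methods are
#'   deterministic).
#' @param k Neighbourhood size for the graph-based methods.
#' @return n x 2 `embedding2d` matrix with the method recorded.
#' @export
alternative_embed <- function(latents, method = c("PCA", "MDS", "LLE",
                                                  "Isomap",
                                                  "SpectralEmbedding",
                                                  "UMAP"),
                              seed = 1L, k = 10) {
  method <- match.arg(method)
  X <- as.matrix(latents)
  Y <- switch(method,
    PCA = prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2],
    MDS = cmdscale(dist(X), k = 2),
    Isomap = {
      if (!requireNamespace("vegan", quietly = TRUE))
        stop("Isomap requires the vegan package")
      as.matrix(vegan::scores(vegan::isomap(dist(X), ndim = 2, k = k)))[, 1:2]
    },
    SpectralEmbedding = spectral_embed(X, k = k),
    stop("no backend for method '", method, "' in this build"))
  structure(unname(as.matrix(Y)), method = method, seed = as.integer(seed),
            class = c("embedding2d", "matrix", "array"))
}
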