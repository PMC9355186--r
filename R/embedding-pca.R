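## Image embeddings behind a provider interface, and their PCA reduction.
##
## A provider wraps any function mapping an 84 x 84 image to a fixed-length
## finite feature vector. The contract mirrors deep embedding networks
## (a ResNet-12 trained episodically emits 12,800-d vectors); the default
## provider is a seeded random projection of the raw pixels — deterministic,
## dependency-free, and sufficient to exercise PCA, feature fusion and
## classification. Nothing downstream assumes any particular dimension.

EMBED_INPUT_SIZE <- 84L

#' Wrap an embedding function as a provider
#'
#' @param embed_fn `function(image)` taking an 84 x 84 image (grayscale
#'   matrix or RGB array, 0-255) and returning a numeric vector of length
#'   `output_dim`.
#' @param name Identifier for the provider.
#' @param output_dim Declared output length.
#' @param deterministic Does the provider return identical vectors for
#'   identical inputs?
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(embed_fn, name, output_dim,
                               deterministic = TRUE) {
  stopifnot(is.function(embed_fn), output_dim >= 1)
  structure(list(embed_fn = embed_fn, name = name,
                 output_dim = as.integer(output_dim),
                 deterministic = isTRUE(deterministic)),
            class = "embedding_provider")
}

#' Seeded random-projection embedding provider
#'
#' Projects the 7,056 grayscale pixels of an 84 x 84 image onto
#' `output_dim` fixed random directions (Gaussian entries scaled by
#' `1/sqrt(n_pixels)`), drawn once from `seed`. Byte-identical across
#' processes for the same seed.
#'
#' @param output_dim Embedding length (default 128).
#' @param seed Seed for the projection matrix.
#' @return An `embedding_provider`.
#' @export
random_projection_provider <- function(output_dim = 128L, seed = 42L) {
  d_in <- EMBED_INPUT_SIZE^2
  P <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(output_dim * d_in), nrow = output_dim) / sqrt(d_in)
  })
  embedding_provider(
    embed_fn = function(image) as.numeric(P %*% as.vector(as_gray(image))),
    name = sprintf("random_projection_%d_seed%d", output_dim, as.integer(seed)),
    output_dim = output_dim
  )
}

#' Embed an 84 x 84 image
#'
#' @param image Grayscale matrix or RGB array of exactly 84 x 84 pixels.
#' @param provider An [embedding_provider()].
#' @return Numeric vector of length `provider$output_dim`.
#' @export
embed_image <- function(image, provider) {
  stopifnot(inherits(provider, "embedding_provider"))
  d <- dim(image)
  if (!all(d[1:2] == EMBED_INPUT_SIZE)) {
    stop(sprintf("embedding input must be %d x %d, got %d x %d",
                 EMBED_INPUT_SIZE, EMBED_INPUT_SIZE, d[1], d[2]),
         call. = FALSE)
  }
  v <- provider$embed_fn(image)
  if (length(v) != provider$output_dim || !all(is.finite(v))) {
    stop("provider returned a malformed embedding", call. = FALSE)
  }
  v
}

#' Fit a principal component analysis
#'
#' Mean-centred PCA by singular value decomposition, keeping the top `k`
#' components by eigenvalue. The sign of each component is fixed so its
#' largest-magnitude entry is non-negative, making the fit fully
#' deterministic.
#'
#' @param features An n x d numeric matrix (or list of equal-length
#'   vectors), n >= k + 1.
#' @param k Number of components to keep.
#' @return An object of class `pca_model`: `mean` (length d), `rotation`
#'   (k x d, orthonormal rows), `eigenvalues` (length k, non-increasing),
#'   `k`, `total_variance` (sum of all d eigenvalues).
#' @export
fit_pca <- function(features, k = 5L) {
  X <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  n <- nrow(X)
  if (n < k + 1) stop("need at least k + 1 samples to fit PCA", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > rank) {
    stop(sprintf("k = %d exceeds the data rank (%d)", k, rank), call. = FALSE)
  }
  rot <- t(sv$v[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(rot[i, ]))
    if (rot[i, j] < 0) rot[i, ] <- -rot[i, ]
  }
  structure(
    list(mean = unname(mu), rotation = unname(rot),
         eigenvalues = ev[seq_len(k)], k = as.integer(k),
         total_variance = sum(ev)),
    class = "pca_model"
  )
}

#' Project a feature vector onto fitted components
#'
#' Computes `(feature - mean) %*% t(rotation)`.
#'
#' @param model A `pca_model`.
#' @param feature A numeric vector of the model's input dimension, or an
#'   n x d matrix.
#' @return A length-`k` vector (or n x k matrix).
#' @export
project_pca <- function(model, feature) {
  if (is.null(dim(feature))) {
    if (length(feature) != length(model$mean)) {
      stop("feature dimension does not match the PCA model", call. = FALSE)
    }
    return(as.numeric(model$rotation %*% (feature - model$mean)))
  }
  if (ncol(feature) != length(model$mean)) {
    stop("feature dimension does not match the PCA model", call. = FALSE)
  }
  sweep(feature, 2, model$mean) %*% t(model$rotation)
}

#' Kaiser-rule component count
#'
#' Standardises every feature to unit variance (correlation-matrix PCA) and
#' returns how many of the leading `k_max` eigenvalues exceed 1 — the
#' number of components each explaining more than one variable's worth of
#' variability.
#'
#' @param features n x d matrix (or list of vectors), n >= 2.
#' @param k_max Maximum number of components examined (default 20).
#' @return Integer count in `[0, k_max]`.
#' @export
choose_k_by_eigenvalue <- function(features, k_max = 20L) {
  X <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  if (k_max == 0) return(0L)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) {
    stop("degenerate feature set: every dimension has zero variance",
         call. = FALSE)
  }
  Z <- scale(X[, sds > 0, drop = FALSE])
  ev <- svd(Z, nu = 0, nv = 0)$d^2 / (nrow(Z) - 1)
  sum(head(ev, k_max) > 1)
}
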