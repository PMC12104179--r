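# Exact (O(n^2)) t-SNE on a precomputed distance matrix.
#
# Standard algorithm: per-point Gaussian bandwidths calibrated to the target
# perplexity by bisection on log-scale precision beta; symmetrized joint
# probabilities; gradient descent on the Student-t low-dimensional
# similarities with early exaggeration and momentum. Deterministic given the
# seed (initial coordinates are the only stochastic ingredient).

tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { # entropy too high -> sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    sw <- sum(w)
    P[i, -i] <- if (sw > 0) w / sw else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

tsne_embed <- function(D, perplexity = 30, learning_rate = 500, seed = 1L,
                       n_iter = 1000L, momentum = 0.5, final_momentum = 0.8,
                       mom_switch = 250L, exaggeration = 4, stop_lying = 100L) {
  n <- nrow(D)
  P <- tsne_affinities(D^2, perplexity)
  P_ex <- P * exaggeration
  withr::with_seed(as.integer(seed), {
    Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  })
  dY <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  for (iter in seq_len(n_iter)) {
    Pi <- if (iter <= stop_lying) P_ex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.eps)
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= mom_switch) momentum else final_momentum
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Pairwise Hamming distances
#'
#' Proportion of coordinates at which two vectors differ (any integer
#' entries, not only 0-1), the distance used for embedding binary and count
#' feature vectors.
#'
#' @param X Numeric matrix, one vector per row.
#' @return Symmetric n x n matrix of proportions in [0, 1].
#' @export
hamming_distances <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- matrix(0, n, n)
  tX <- t(X)
  for (i in seq_len(n)) {
    D[i, ] <- colMeans(tX != X[i, ])
  }
  (D + t(D)) / 2
}

#' Embed high-dimensional formula vectors in 2-D with t-SNE
#'
#' Exact t-SNE on a precomputed distance matrix, used to inspect whether real
#' formulas separate from random pseudo-formulas and how syndrome classes
#' distribute. Deterministic under `seed`; rows of the output correspond to
#' rows of the input in order.
#'
#' @param vectors Numeric matrix, one vector per row (formula vectors or
#'   weighted triplet-set vectors), or a precomputed `dist`/square distance
#'   matrix when `metric = "precomputed"`.
#' @param metric `"hamming"` (default), `"euclidean"`, `"manhattan"`, or
#'   `"precomputed"`.
#' @param perplexity t-SNE perplexity; needs at least `3 * perplexity + 1`
#'   points.
#' @param learning_rate Gradient-descent learning rate.
#' @param seed Integer seed for the random initial layout (required).
#' @param n_iter Gradient-descent iterations.
#' @return An n x 2 numeric matrix of coordinates.
#' @export
embed_2d <- function(vectors, metric = c("hamming", "euclidean", "manhattan", "precomputed"),
                     perplexity = 30, learning_rate = 500, seed, n_iter = 1000L) {
  metric <- match.arg(metric)
  if (missing(seed)) stop("an explicit seed is required for embedding", call. = FALSE)
  D <- switch(metric,
    hamming = hamming_distances(vectors),
    euclidean = as.matrix(stats::dist(vectors, method = "euclidean")),
    manhattan = as.matrix(stats::dist(vectors, method = "manhattan")),
    precomputed = as.matrix(vectors)
  )
  n <- nrow(D)
  if (n < 3 * perplexity + 1) {
    stop(
      "too few points (", n, ") for perplexity ", perplexity,
      "; need at least ", 3 * perplexity + 1,
      call. = FALSE
    )
  }
  Y <- tsne_embed(D,
    perplexity = perplexity, learning_rate = learning_rate,
    seed = seed, n_iter = n_iter
  )
  if (!all(is.finite(Y))) stop("embedding diverged to non-finite coordinates", call. = FALSE)
  dimnames(Y) <- list(rownames(vectors), c("dim1", "dim2"))
  Y
}
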