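# Exact (dense-gradient) t-SNE. Datasets here are small (hundreds of
# neurons), so the O(n^2) gradient is the simplest reliable choice and
# keeps the embedding fully deterministic under a seed.

# row-wise conditional probabilities at a target perplexity via binary
# search on the Gaussian bandwidth
tsne_p_matrix <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { beta <- beta / 2; next }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - log_u) < 1e-6) break
      if (h > log_u) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

#' 2-D embedding of principal-component scores
#'
#' Exact t-SNE (perplexity-calibrated Gaussian affinities, Student-t
#' low-dimensional kernel, momentum gradient descent with early
#' exaggeration). Deterministic for a fixed seed. With fewer than four
#' points (or a single point) the first two input columns are returned
#' instead, with a warning. The perplexity is reduced automatically when
#' the sample is too small to support it.
#'
#' @param x numeric matrix (points x dims), typically 4 PC scores.
#' @param perplexity target perplexity.
#' @param seed integer seed for the random initialisation.
#' @param n_iter gradient-descent iterations.
#' @return points x 2 coordinate matrix.
#' @export
embed_2d <- function(x, perplexity = 30, seed = 1, n_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) {
    warning("too few points for t-SNE; returning first two input columns")
    return(cbind(x[, 1], if (ncol(x) > 1) x[, 2] else 0))
  }
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning("perplexity reduced to ", max_perp, " for n = ", n)
    perplexity <- max_perp
  }
  P <- tsne_p_matrix(x, perplexity)
  with_seed(seed, {
    y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    eta <- 100
    for (it in seq_len(n_iter)) {
      ex <- if (it <= 100) 4 else 1
      d2 <- as.matrix(dist(y))^2
      Qnum <- 1 / (1 + d2); diag(Qnum) <- 0
      Q <- pmax(Qnum / sum(Qnum), .Machine$double.eps)
      W <- (ex * P - Q) * Qnum
      grad <- 4 * (diag(rowSums(W)) - W) %*% y
      momentum <- if (it > 250) 0.8 else 0.5
      inc <- momentum * inc - eta * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    colnames(y) <- c("tsne1", "tsne2")
    y
  })
}
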