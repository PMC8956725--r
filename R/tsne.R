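# Exact (dense) t-SNE, adequate and fully deterministic for the tens of
# points a primitive set contains. Conditional probabilities use the usual
# per-point precision search to match the target perplexity; the embedding
# is optimised by gradient descent with momentum, adaptive gains and early
# exaggeration.

tsne_probabilities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf; beta_max <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

tsne_embed <- function(X, perplexity = 5, seed = 42L, max_iter = 500,
                       eta = 100, momentum_start = 0.5, momentum_final = 0.8,
                       exaggeration = 4, exaggeration_iter = 100) {
  n <- nrow(X)
  if (n < 3) stop("t-SNE needs >= 3 points", call. = FALSE)
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be smaller than the number of points (",
         n, ")", call. = FALSE)
  }
  P <- tsne_probabilities(X, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  })
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= exaggeration_iter) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) momentum_start else momentum_final
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
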