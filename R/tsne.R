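# Exact (O(n^2)) t-distributed stochastic neighbour embedding. Adequate for
# the desk-scale map sizes this package draws (hundreds to a few thousand
# points); seeded and fully deterministic.

tsne_exact <- function(X, perplexity = 30, n_iter = 400, seed = 1,
                       learning_rate = 200, exaggeration = 12,
                       exaggeration_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 5)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    Pm <- if (it <= exaggeration_iter) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pm - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  Y
}
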