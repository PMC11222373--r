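# Exact t-SNE (van der Maaten & Hinton's original algorithm without the
# Barnes-Hut approximation): adequate and fast for the ~120-row token
# embedding tables projected here. Perplexity calibration by per-row
# binary search on the Gaussian bandwidth; optimization by gradient
# descent with momentum and early exaggeration.

tsne_exact <- function(X, perplexity = 30, max_iter = 400L, eta = 100,
                       exaggeration = 4, exag_iter = 100L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { p <- rep(1 / length(di), length(di)); sumP <- 1 }
      H <- log(sumP) + beta * sum(di * p) / sumP
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
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= exag_iter) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
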