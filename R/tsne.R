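# Exact (dense) t-SNE, suitable for the few dozen animals a behavioral
# cohort contains. Conditional probabilities use the standard per-point
# binary search for the bandwidth matching the target perplexity; the
# embedding is optimized by gradient descent with momentum and early
# exaggeration. Deterministic given the RNG state at entry.

tsne_exact <- function(X, perplexity = 5, dims = 2L, max_iter = 500L,
                       eta = 100, momentum = c(0.5, 0.8),
                       exaggeration = 4, exaggerate_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  P <- tsne_p_matrix(X, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Pe <- P * exaggeration
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  inc <- matrix(0, n, dims)
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= exaggerate_iter) Pe else P
    D2 <- as.matrix(stats::dist(Y))^2
    Wq <- 1 / (1 + D2); diag(Wq) <- 0
    Q <- pmax(Wq / sum(Wq), 1e-12)
    L <- (Puse - Q) * Wq
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250L) momentum[1L] else momentum[2L]
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), "-")
  }
  Y
}

tsne_p_matrix <- function(X, perplexity, tol = 1e-5) {
  D2 <- as.matrix(stats::dist(X))^2
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) { H <- 0; p[] <- 0 } else {
        p <- p / s
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
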