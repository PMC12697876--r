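# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# BH step-up, computed literally from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest down
  for (i in rev(seq_len(m))) {
    adj[i] <- if (i == m) sorted[i] else min(sorted[i], adj[i + 1L])
  }
  pmin(1, adj)[order(o)]
}

# explicit small-matrix inverse (adjugate form), K <= 3
inv_small <- function(S) {
  K <- nrow(S)
  if (K == 1L) return(matrix(1 / S[1, 1], 1, 1))
  if (K == 2L) {
    d <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    return(matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / d)
  }
  cof <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    minor <- S[-i, -j, drop = FALSE]
    cof[i, j] <- (-1)^(i + j) * (minor[1, 1] * minor[2, 2] - minor[1, 2] * minor[2, 1])
  }
  d <- sum(S[1, ] * cof[1, ])
  t(cof) / d
}

# forward-model pattern computed with scalar loops and the adjugate inverse
haufe_oracle <- function(W, sigma_x) {
  M <- nrow(W); K <- ncol(W)
  sigma_s <- matrix(0, K, K)
  for (a in 1:K) for (b in 1:K)
    for (i in 1:M) for (j in 1:M)
      sigma_s[a, b] <- sigma_s[a, b] + W[i, a] * sigma_x[i, j] * W[j, b]
  inv <- inv_small(sigma_s)
  A <- matrix(0, M, K)
  for (i in 1:M) for (a in 1:K)
    for (j in 1:M) for (b in 1:K)
      A[i, a] <- A[i, a] + sigma_x[i, j] * W[j, b] * inv[b, a]
  A
}

# random symmetric positive-definite matrix
rand_spd <- function(M) {
  Q <- matrix(rnorm(M * M), M)
  crossprod(Q) / M + diag(M) * 0.1
}

# per-sample state-machine zone scoring: time, entries, distances
zone_oracle <- function(x, y, inside, sample_rate) {
  n <- length(x)
  time_in <- 0; entries <- 0L; dist_in <- 0; dist_tot <- 0
  prev_inside <- FALSE
  for (i in seq_len(n)) {
    if (inside[i]) {
      time_in <- time_in + 1 / sample_rate
      if (!prev_inside) entries <- entries + 1L
    }
    if (i < n) {
      seg <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
      dist_tot <- dist_tot + seg
      if (inside[i]) dist_in <- dist_in + seg
    }
    prev_inside <- inside[i]
  }
  list(time_in_zone_s = time_in, entries = entries,
       distance_in_zone_cm = dist_in, total_distance_cm = dist_tot)
}

# log fold change giving a target count-scale Cohen's d under the negative
# binomial generator (variance = mu + dispersion * mu^2)
log_fold_for_d <- function(d, baseline = 100, dispersion = 0.05) {
  v <- function(mu) mu + dispersion * mu^2
  f <- function(lf) {
    mu2 <- baseline * exp(lf)
    (mu2 - baseline) / sqrt((v(baseline) + v(mu2)) / 2) - d
  }
  stats::uniroot(f, c(1e-6, 5))$root
}

# per-animal action-proportion vectors via normalized gamma draws
rand_props <- function(n, K, alpha = rep(2, K)) {
  m <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  m / rowSums(m)
  }

total_variation_rows <- function(P, Q) apply(abs(P - Q), 1, sum) / 2
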