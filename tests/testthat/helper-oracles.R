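# Independent reference implementations used as oracles. These deliberately
# follow the definitional path (explicit per-sample filtering, explicit lag
# matrices, loops) rather than the package's vectorized code.

# FIR filtering + spatial combination + windowed variance, computed sample by
# sample from the definitions.
oracle_alpha <- function(x, w, h, b, norm = "count") {
  M <- nrow(x); N <- ncol(x); P <- length(h); K <- N - P + 1
  xt <- numeric(K)
  for (n in seq_len(K)) {
    acc <- 0
    for (m in seq_len(M)) {
      for (p in seq_len(P)) acc <- acc + w[m] * h[p] * x[m, n + P - p]
    }
    xt[n] <- acc
  }
  denom <- if (norm == "count") sum(b) else sqrt(sum(b))
  mu <- sum(b * xt) / denom
  sum(b * (xt - mu)^2) / denom
}

# Explicit lag matrix A_n per its defining index map.
oracle_lag_matrix <- function(x, P, n) {
  M <- nrow(x)
  A <- matrix(0, M, P)
  for (m in seq_len(M)) {
    for (p in seq_len(P)) A[m, p] <- x[m, n + P - p]
  }
  A
}

oracle_objective <- function(ts, w, h, b, epsilon, c = 1, norm = "count") {
  a <- vapply(ts$trials, oracle_alpha, numeric(1), w = w, h = h, b = b,
              norm = norm)
  m1 <- mean(a[ts$labels == 1]); m2 <- mean(a[ts$labels == 2])
  jh <- (if (c == 1) m1 else m2) / (m1 + m2)
  jh + epsilon / length(b) * sqrt(sum(b))
}

# Small random two-class trial set.
random_trial_set <- function(M, N, trials_per_class, sd1 = 1, sd2 = 1) {
  n <- 2 * trials_per_class
  trials <- lapply(seq_len(n), function(i) {
    s <- if (i <= trials_per_class) sd1 else sd2
    matrix(rnorm(M * N, sd = s), M, N)
  })
  trial_set(trials, rep(1:2, each = trials_per_class))
}

unit <- function(v) v / sqrt(sum(v^2))
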