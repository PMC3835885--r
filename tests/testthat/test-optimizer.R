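test_that("objective matches the definitional oracle and its reductions", {
  set.seed(51)
  ts <- random_trial_set(2, 8, 2)
  w <- unit(rnorm(2)); h <- unit(rnorm(2)); b <- c(1, 1, 0, 1, 1, 0, 1)

  ob <- cstfp_objective(ts, w, h, b, epsilon = 0.3)
  expect_equal(ob$total, oracle_objective(ts, w, h, b, 0.3), tolerance = 1e-10)
  expect_equal(ob$total, ob$j_hat + ob$penalty)

  # epsilon = 0 removes the window reward
  expect_equal(cstfp_objective(ts, w, h, b, epsilon = 0)$total,
               cstfp_objective(ts, w, h, b, epsilon = 0)$j_hat)

  # classes with identical trials give a ratio of exactly 1/2
  x <- matrix(rnorm(16), 2, 8)
  ts_eq <- trial_set(list(x, x), c(1, 2))
  expect_equal(cstfp_objective(ts_eq, w, h, b, epsilon = 0)$j_hat, 0.5,
               tolerance = 1e-12)

  # complementary target classes sum to one
  j1 <- cstfp_objective(ts, w, h, b, epsilon = 0, c = 1)$j_hat
  j2 <- cstfp_objective(ts, w, h, b, epsilon = 0, c = 2)$j_hat
  expect_equal(j1 + j2, 1, tolerance = 1e-12)
  expect_true(j1 >= 0 && j1 <= 1)

  expect_error(cstfp_objective(trial_set(list(0 * x, 0 * x), c(1, 2)),
                               w, h, b, epsilon = 0),
               class = "cstfp_degenerate_signal")
})

test_that("spatial-weight update solves the constrained maximum", {
  set.seed(53)
  ts <- random_trial_set(3, 20, 5, sd1 = 1, sd2 = 1.7)
  h <- unit(rnorm(4)); b <- c(rep(1, 12), rep(0, 5))
  up <- cstfp_update_w(ts, h, b)

  # no random unit vector beats the eigenvector's objective
  jfun <- function(w) cstfp_objective(ts, w, h, b, epsilon = 0)$j_hat
  best_rand <- max(replicate(10000, jfun(unit(rnorm(3)))))
  expect_gte(jfun(up$w) + 1e-12, best_rand)
  # eigenvalue equals the attained ratio
  expect_equal(jfun(up$w), up$lambda, tolerance = 1e-10)

  # identical classes: lambda = 1/2 exactly
  x <- matrix(rnorm(3 * 20), 3, 20)
  ts_eq <- trial_set(list(x, x), c(1, 2))
  expect_equal(cstfp_update_w(ts_eq, h, b)$lambda, 0.5, tolerance = 1e-10)
})

test_that("deflation subspace construction follows the circular-shift map", {
  # first filter with no extra subspace: empty V
  V0 <- build_deflation_subspace(list(), P = 5)
  expect_equal(dim(V0), c(5, 0))

  # delta filter: its one-sample circular shift is the delta at the last tap
  e1 <- c(1, 0, 0, 0, 0)
  V1 <- build_deflation_subspace(list(e1))
  expect_equal(ncol(V1), 2)
  expect_equal(V1[, 1], e1)
  expect_equal(V1[, 2], c(0, 0, 0, 0, 1))

  # two generic orthogonal filters: V has 4 independent columns
  set.seed(59)
  h1 <- unit(rnorm(6))
  h2 <- unit(rnorm(6)); h2 <- unit(h2 - sum(h2 * h1) * h1)
  V2 <- build_deflation_subspace(list(h1, h2))
  expect_equal(ncol(V2), 4)
  expect_equal(qr(V2)$rank, 4)

  # redundant spanning vectors are pruned with a warning
  expect_warning(V3 <- build_deflation_subspace(list(e1), extra = cbind(e1)),
                 "pruning")
  expect_equal(qr(V3)$rank, ncol(V3))
})

test_that("filter update respects the constraint and matches a random search", {
  set.seed(61)
  ts <- random_trial_set(2, 18, 5, sd1 = 1, sd2 = 1.6)
  w <- unit(rnorm(2)); P <- 4
  b <- c(rep(1, 10), rep(0, 5))

  # unconstrained case agrees with the w/h duality at a fixed point
  V0 <- matrix(0, P, 0)
  uh <- cstfp_update_h(ts, w, b, V0)
  jfun <- function(h) cstfp_objective(ts, w, h, b, epsilon = 0)$j_hat
  expect_equal(jfun(uh$h), uh$zeta, tolerance = 1e-10)
  best_rand <- max(replicate(10000, jfun(unit(rnorm(P)))))
  expect_gte(jfun(uh$h) + 1e-12, best_rand)

  # constrained case: V' h = 0 and no orthogonalized random vector wins
  V <- cbind(unit(rnorm(P)))
  uhc <- cstfp_update_h(ts, w, b, V)
  expect_lt(max(abs(crossprod(V, uhc$h))), 1e-8)
  ortho_rand <- function() {
    v <- rnorm(P); v <- v - V %*% crossprod(V, v) / sum(V^2)
    unit(as.vector(v))
  }
  best_rand_c <- max(replicate(10000, jfun(ortho_rand())))
  expect_gte(jfun(uhc$h) + 1e-12, best_rand_c)

  # P = 1: the only unit filter is +/-1, returned sign-fixed
  u1 <- cstfp_update_h(ts, w, b = c(rep(1, 10), rep(0, 8)),
                       V = matrix(0, 1, 0))
  expect_equal(u1$h, 1)
})

test_that("alternating w/h updates attain the same optimum at a fixed point", {
  set.seed(67)
  ts <- random_trial_set(3, 15, 4, sd1 = 1, sd2 = 1.4)
  b <- rep(1, 12)
  h <- unit(rnorm(4)); V0 <- matrix(0, 4, 0)
  for (i in 1:50) {
    w <- cstfp_update_w(ts, h, b)$w
    h <- cstfp_update_h(ts, w, b, V0)$h
  }
  lam <- cstfp_update_w(ts, h, b)$lambda
  zet <- cstfp_update_h(ts, w, b, V0)$zeta
  expect_equal(lam, zet, tolerance = 1e-8)
})

test_that("window update equals brute-force candidate evaluation", {
  set.seed(71)
  ts <- random_trial_set(2, 12, 4, sd1 = 1, sd2 = 1.5)
  w <- unit(rnorm(2)); h <- unit(rnorm(3)); K <- 10
  cand <- window_block_candidates(K = 10, D = 2, J = 3)

  ub <- cstfp_update_b(ts, w, h, cand, epsilon = 0.2)
  brute <- apply(as.matrix(cand), 1, function(b)
    oracle_objective(ts, w, h, b, 0.2))
  expect_equal(ub$index, which.max(brute))
  expect_equal(ub$j3, max(brute), tolerance = 1e-10)

  # single candidate returned unchanged
  single <- structure(list(candidates = matrix(1L, 1, K), scheme = "contiguous",
                           params = list()), class = "window_candidates")
  expect_equal(cstfp_update_b(ts, w, h, single, epsilon = 0)$b, rep(1, K))

  # overwhelming window reward selects the longest candidate
  ub2 <- cstfp_update_b(ts, w, h, cand, epsilon = 1000)
  expect_equal(sum(ub2$b), max(rowSums(as.matrix(cand))))
})

test_that("each block update does not decrease the objective", {
  set.seed(73)
  cand <- window_block_candidates(K = 10, D = 2, J = 5)
  for (rep_i in 1:10) {
    ts <- random_trial_set(3, 13, 4, sd1 = 1, sd2 = 1 + rep_i / 10)
    w <- unit(rnorm(3)); h <- unit(rnorm(4))
    b <- as.numeric(as.matrix(cand)[sample(nrow(as.matrix(cand)), 1), ])
    V0 <- matrix(0, 4, 0)
    obj <- function() cstfp_objective(ts, w, h, b, epsilon = 0.1)$total
    o0 <- obj()
    w <- cstfp_update_w(ts, h, b)$w;  o1 <- obj()
    h <- cstfp_update_h(ts, w, b, V0)$h; o2 <- obj()
    b <- cstfp_update_b(ts, w, h, cand, epsilon = 0.1)$b; o3 <- obj()
    expect_gte(o1, o0 - 1e-12)
    expect_gte(o2, o1 - 1e-12)
    expect_gte(o3, o2 - 1e-12)
  }
})

test_that("fitted filters are orthonormal with non-decreasing traces", {
  set.seed(79)
  ts <- random_trial_set(4, 30, 8, sd1 = 1, sd2 = 1.5)
  fit <- cstfp(ts, n_filters = 3, r = 1, P = 6, epsilon = 0.1,
               candidates = window_block_candidates(25, 5, 5), seed = 2)
  H <- sapply(fit$h, identity)
  expect_equal(crossprod(H), diag(3), tolerance = 1e-8)
  for (tr in fit$objective_trace) {
    expect_true(all(diff(tr) >= -1e-12))
  }
  # refitting with the same seed reproduces the model exactly
  fit2 <- cstfp(ts, n_filters = 3, r = 1, P = 6, epsilon = 0.1,
                candidates = window_block_candidates(25, 5, 5), seed = 2)
  expect_identical(fit$w, fit2$w)
  expect_identical(fit$h, fit2$h)
  expect_identical(fit$b, fit2$b)
})

test_that("joint spatio-spectral fit dominates identity-filter CSP", {
  # window fixed to all-ones and epsilon 0: the design reduces to a joint
  # spatio-spectral problem whose optimum cannot be worse than CSP with an
  # identity filter (a feasible point of the larger problem)
  set.seed(83)
  cfg <- separable_sim_config(trials_per_class = 15)
  ts <- simulate_trials(cfg, seed = 5)
  K <- 100 - 8 + 1
  allones <- structure(list(candidates = matrix(1L, 1, K), scheme = "contiguous",
                            params = list()), class = "window_candidates")
  fit <- cstfp(ts, n_filters = 1, r = 1, P = 8, epsilon = 0,
               candidates = allones, seed = 3)
  csp_w <- csp_fit(ts)$eigenvectors[, 1]
  j_csp <- cstfp_objective(ts, csp_w, h = c(1, rep(0, 7)), b = rep(1, K),
                           epsilon = 0)$j_hat
  expect_gte(fit$j_hat[1], j_csp - 1e-10)
})

test_that("fit recovers the band and window of a lone late source", {
  # one 12 Hz source active only in the second half of each trial
  bump <- function(p) exp(-(1:6 - p)^2 / (2 * 1.2^2))
  cfg <- sim_config(M = 6, N = 100, trials_per_class = 40, fs = 100,
                    sources = list(
                      source_spec(center_hz = 12, bandwidth_hz = 0.5,
                                  window = c(51, 100),
                                  amp1 = bump(2), amp2 = bump(5))),
                    noise_sd = sqrt(0.1))
  hits_freq <- 0; hits_win <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    ts <- simulate_trials(cfg, seed = 100 + s)
    fit <- cstfp(ts, n_filters = 1, r = 1, P = 41, epsilon = 0.1,
                 candidates = window_block_candidates(60, 6, 10),
                 seed = s)
    pk <- tidy(fit)$peak_hz[1]
    hits_freq <- hits_freq + (abs(pk - 12) <= 2)
    # true active region in filtered coordinates: filtered sample n spans raw
    # samples n..n+P-1, so take samples whose support midpoint n + (P-1)/2
    # falls in the raw active half; require >= 80% coverage
    true_act <- 31:60
    cover <- mean(true_act %in% which(fit$b[[1]] == 1))
    hits_win <- hits_win + (cover >= 0.8)
  }
  expect_gte(hits_freq, n_seeds - 1)
  expect_gte(hits_win, n_seeds - 1)
})

test_that("multi-start fit matches exhaustive search on tiny instances", {
  set.seed(89)
  cand <- window_block_candidates(K = 9, D = 3, J = 3)   # L = 7
  Bm <- as.matrix(cand)
  for (case in 1:2) {
    ts <- random_trial_set(2, 11, 4, sd1 = 1, sd2 = 1 + case / 2)
    P <- 3
    # dense random search over unit spheres x exhaustive windows
    best <- -Inf
    for (l in seq_len(nrow(Bm))) {
      for (draw in 1:4000) {
        w <- unit(rnorm(2)); h <- unit(rnorm(P))
        val <- cstfp_objective(ts, w, h, Bm[l, ], epsilon = 0.1)$total
        if (val > best) best <- val
      }
    }
    # multi-start over 10 seeds, each from both the default (all-ones) and
    # one cycled candidate window initialization
    fits <- sapply(1:10, function(s) {
      f1 <- max(cstfp(ts, n_filters = 1, r = 1, P = P, epsilon = 0.1,
                      candidates = cand, seed = s)$objective_trace[[1]])
      f2 <- max(cstfp(ts, n_filters = 1, r = 1, P = P, epsilon = 0.1,
                      candidates = cand, seed = s,
                      init_window = Bm[(s - 1) %% nrow(Bm) + 1, ]
                      )$objective_trace[[1]])
      max(f1, f2)
    })
    expect_gte(max(fits), best - 1e-3)
  }
})
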