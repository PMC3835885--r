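test_that("lag tensor dimensions and index map match the definition", {
  # K = N - P + 1 at the protocol scale
  x <- matrix(rnorm(3 * 100), 3, 100)
  A <- build_lag_tensor(x, P = 41)
  expect_equal(dim(A), c(3, 41, 60))
  expect_equal(attr(A, "K"), 60)

  # hand-enumerated single-channel case: rows are reversed sample windows
  x1 <- matrix(c(1, 2, 3, 4), 1, 4)
  A1 <- build_lag_tensor(x1, P = 2)
  expect_equal(A1[, , 1], c(2, 1))
  expect_equal(A1[, , 2], c(3, 2))
  expect_equal(A1[, , 3], c(4, 3))

  # generic slice agrees with an explicit loop over the index map
  set.seed(3)
  x2 <- matrix(rnorm(2 * 9), 2, 9)
  A2 <- build_lag_tensor(x2, P = 3)
  for (n in c(1, 4, 7)) {
    expect_equal(A2[, , n], oracle_lag_matrix(x2, 3, n))
  }

  # P = 1 reduces A_n to the n-th sample column
  A3 <- build_lag_tensor(x2, P = 1)
  expect_equal(A3[, 1, 5], x2[, 5])

  expect_error(build_lag_tensor(x1, P = 5), class = "cstfp_invalid_filter_order")
  expect_error(build_lag_tensor(matrix(c(1, NA), 1, 2), P = 1),
               class = "cstfp_validation")
})

test_that("the bilinear form through the lag tensor equals direct convolution", {
  set.seed(7)
  x <- matrix(rnorm(2 * 8), 2, 8)
  P <- 3
  A <- build_lag_tensor(x, P)
  w <- unit(rnorm(2)); h <- unit(rnorm(P))
  direct <- sapply(seq_len(8 - P + 1), function(n) {
    sum(sapply(1:2, function(m) w[m] * sum(h * x[m, n + P - seq_len(P)])))
  })
  viaA <- sapply(seq_len(dim(A)[3]), function(n) drop(t(w) %*% A[, , n] %*% h))
  expect_equal(viaA, direct, tolerance = 1e-12)
})

test_that("alpha matrix form equals the explicit filtering-path oracle", {
  set.seed(11)
  for (case in 1:100) {
    M <- sample(1:4, 1); P <- sample(1:4, 1); N <- P + sample(4:12, 1)
    K <- N - P + 1
    x <- matrix(rnorm(M * N), M, N)
    w <- rnorm(M); h <- rnorm(P)
    b <- numeric(K)
    b[sample(K, max(2, sample(K, 1)))] <- 1
    expect_equal(alpha_variance(x, w, h, b),
                 oracle_alpha(x, w, h, b), tolerance = 1e-10)
    expect_equal(alpha_variance(x, w, h, b, norm = "euclidean"),
                 oracle_alpha(x, w, h, b, norm = "euclidean"),
                 tolerance = 1e-10)
  }
})

test_that("alpha scale law, shift invariance, and reductions hold", {
  set.seed(13)
  x <- matrix(rnorm(3 * 20), 3, 20)
  w <- rnorm(3); h <- rnorm(4); b <- c(rep(1, 10), rep(0, 7))
  a0 <- alpha_variance(x, w, h, b)
  expect_equal(alpha_variance(x, 3 * w, h, b), 9 * a0, tolerance = 1e-10)
  expect_equal(alpha_variance(x, w, -2 * h, b), 4 * a0, tolerance = 1e-10)
  # constant offset on all samples is removed by windowed centering
  expect_equal(alpha_variance(x + 5, w, h, b), a0, tolerance = 1e-8)
  # zero signal
  expect_equal(alpha_variance(0 * x, w, h, b), 0)
  # all-ones window, identity filter, unit channel selector = plain
  # (1/N-normalized) variance of that channel
  m <- 2
  a_chan <- alpha_variance(x, w = replace(numeric(3), m, 1), h = 1,
                           b = rep(1, 20))
  expect_equal(a_chan, mean((x[m, ] - mean(x[m, ]))^2), tolerance = 1e-12)
})

test_that("degenerate windows are rejected", {
  x <- matrix(rnorm(20), 2, 10)
  expect_error(alpha_variance(x, c(1, 0), 1, rep(0, 10)),
               class = "cstfp_validation")
  expect_error(alpha_variance(x, c(1, 0), 1, c(1, rep(0, 9))),
               class = "cstfp_degenerate_window")
  expect_error(alpha_variance(x, c(1, 0), 1, c(1, 2, rep(0, 8))),
               class = "cstfp_validation")
})

test_that("global-centering debug variant matches its definition", {
  set.seed(17)
  x <- matrix(rnorm(2 * 12), 2, 12)
  w <- rnorm(2); h <- rnorm(3); K <- 10
  b <- c(rep(1, 5), rep(0, 5))
  xt <- sapply(seq_len(K), function(n) {
    sum(sapply(1:2, function(m) w[m] * sum(h * x[m, n + 3 - 1:3])))
  })
  xw <- b * xt
  expect_equal(alpha_variance(x, w, h, b, centering = "global"),
               sum((xw - mean(xw))^2) / sum(b), tolerance = 1e-12)
})

test_that("low-pass preprocessing decimates and preserves passband amplitude", {
  fs <- 1000
  t <- seq_len(3500) / fs
  x <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  y <- bandpass_preprocess(x, fs = fs, cutoff_hz = 50, order = 4,
                           downsample_to = 100)
  expect_equal(dim(y), c(2, 350))
  # 10 Hz lies deep in the passband: amplitude preserved within 1%
  # (estimated from the RMS of the decimated sinusoid, away from the edges)
  mid <- 50:300
  expect_equal(sqrt(2 * mean(y[1, mid]^2)), 1, tolerance = 0.01)
  expect_equal(sqrt(2 * mean(y[2, mid]^2)), 1, tolerance = 0.01)
  expect_error(bandpass_preprocess(x, fs = 1000, cutoff_hz = 600),
               class = "cstfp_validation")
  expect_error(bandpass_preprocess(x, fs = 1000, downsample_to = 300),
               class = "cstfp_validation")
})

test_that("trial sets validate and round-trip through text files", {
  expect_error(trial_set(list(matrix(0, 2, 3)), labels = 1),
               class = "cstfp_validation")
  expect_error(trial_set(list(matrix(0, 2, 3), matrix(0, 2, 4)), c(1, 2)),
               class = "cstfp_validation")

  set.seed(19)
  ts <- random_trial_set(3, 7, 2)
  dir <- withr::local_tempdir()
  write_trial_set(ts, dir)
  ts2 <- read_trial_set(dir)
  expect_equal(ts2$trials, ts$trials, tolerance = 1e-12)
  expect_identical(ts2$labels, ts$labels)

  # malformed manifest is a distinct error class
  bad <- withr::local_tempdir()
  writeLines("a,b", file.path(bad, "manifest.csv"))
  expect_error(read_trial_set(bad), class = "cstfp_manifest")
})

test_that("long tibble and trial_set representations are interconvertible", {
  set.seed(23)
  ts <- random_trial_set(2, 5, 1)
  tb <- tibble::as_tibble(ts)
  expect_equal(nrow(tb), length(ts) * 2 * 5)
  ts2 <- as_trial_set(as.data.frame(tb))
  expect_equal(ts2$trials, ts$trials)
  expect_identical(ts2$labels, ts$labels)
})
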