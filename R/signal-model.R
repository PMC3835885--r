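#' Lagged-matrix stack of a trial
#'
#' Builds the stack of `K = N - P + 1` lagged matrices `A_n` (each
#' `M x P`) of a trial, defined elementwise (1-based) as
#' `[A_n]_{m,p} = X[m, n + P - p]`. Row `m` of `A_n` is the reversed window
#' of samples `x_m[n .. n + P - 1]`, so that the bilinear form
#' `w' A_n h` equals the spatially combined, FIR-filtered signal at time `n`.
#'
#' @param x Numeric `M x N` matrix (one trial).
#' @param P FIR filter order (number of taps), `1 <= P <= N`.
#' @return A 3-D array of dimension `c(M, P, K)` with class `lag_tensor`;
#'   slice `[ , , n]` is `A_n`.
#' @examples
#' A <- build_lag_tensor(matrix(1:4, 1, 4), P = 2)
#' A[, , 1]  # [x2, x1]
#' @export
build_lag_tensor <- function(x, P) {
  check_finite_matrix(x, "trial")
  N <- ncol(x)
  P <- as.integer(P)
  if (P < 1L || P > N) {
    abort(sprintf("filter order P = %d must satisfy 1 <= P <= N = %d", P, N),
          class = "cstfp_invalid_filter_order")
  }
  K <- N - P + 1L
  idx <- lag_index(K, P)
  out <- array(0, dim = c(nrow(x), P, K))
  for (n in seq_len(K)) out[, , n] <- x[, idx[n, ], drop = FALSE]
  structure(out, class = "lag_tensor", K = K, P = P)
}

check_window <- function(b, K) {
  b <- as.numeric(b)
  if (length(b) != K) {
    abort(sprintf("window length %d does not match filtered length K = %d",
                  length(b), K), class = "cstfp_validation")
  }
  if (!all(b %in% c(0, 1))) {
    abort("window entries must be 0 or 1", class = "cstfp_validation")
  }
  n_active <- sum(b)
  if (n_active == 0) {
    abort("window has no active samples", class = "cstfp_validation")
  }
  if (n_active < 2) {
    abort("window needs at least 2 active samples to define a variance",
          class = "cstfp_degenerate_window")
  }
  b
}

window_denom <- function(n_active, norm) {
  switch(norm, count = n_active, euclidean = sqrt(n_active),
         abort("`norm` must be 'count' or 'euclidean'", class = "cstfp_validation"))
}

#' Spatially combined FIR-filtered trial signal
#'
#' Computes `x_tilde[n] = w' A_n h` for `n = 1..K`, i.e. the channels are
#' combined with spatial weights `w` and the result convolved with the FIR
#' taps `h` (valid part only).
#' @noRd
filtered_signal <- function(x, w, h) {
  z <- as.vector(crossprod(w, x))  # length N
  N <- length(z)
  P <- length(h)
  K <- N - P + 1L
  y <- stats::filter(z, h, method = "convolution", sides = 1)
  as.numeric(y[P:N])
}

#' Windowed variance of a filtered, spatially combined trial
#'
#' The central functional of the method: the variance of the extracted
#' signal `x_tilde[n] = w' A_n h` over the active samples of a binary time
#' window `b`. In canonical form the lagged matrices are window-centered,
#' `A_hat_n = A_n - (1/denom) * sum_m b_m A_m`, and
#' `alpha = (1/denom) * sum_n b_n |w' A_hat_n h|^2`, where `denom` is the
#' active-sample count under `norm = "count"` (the default, giving a true
#' sample variance) or `sqrt(count)` under `norm = "euclidean"` (the literal
#' Euclidean norm of a binary vector).
#'
#' @param x Numeric `M x N` trial matrix.
#' @param w Spatial weight vector, length `M`.
#' @param h FIR coefficient vector, length `P`.
#' @param b Binary time window, length `K = N - P + 1`, with at least two
#'   active samples.
#' @param norm Averaging denominator convention: `"count"` (default) or
#'   `"euclidean"`.
#' @param centering `"windowed"` (default; center by the mean over active
#'   samples) or `"global"` (debug variant: the window is applied to the
#'   signal first and centering uses the plain mean over all `K` samples).
#' @return A nonnegative scalar.
#' @examples
#' x <- matrix(rnorm(40), 2, 20)
#' alpha_variance(x, w = c(1, 0), h = 1, b = rep(1, 20))
#' @export
alpha_variance <- function(x, w, h, b,
                           norm = c("count", "euclidean"),
                           centering = c("windowed", "global")) {
  norm <- match.arg(norm)
  centering <- match.arg(centering)
  check_finite_matrix(x, "trial")
  w <- as.numeric(w)
  h <- as.numeric(h)
  if (length(w) != nrow(x)) {
    abort("length of w must equal the channel count", class = "cstfp_validation")
  }
  N <- ncol(x)
  P <- length(h)
  if (P < 1 || P > N) {
    abort("filter order out of range", class = "cstfp_invalid_filter_order")
  }
  K <- N - P + 1L
  b <- check_window(b, K)
  xt <- filtered_signal(x, w, h)
  denom <- window_denom(sum(b), norm)
  if (centering == "windowed") {
    mu <- sum(b * xt) / denom
    sum(b * (xt - mu)^2) / denom
  } else {
    xw <- b * xt
    mu <- mean(xw)
    sum((xw - mu)^2) / denom
  }
}

#' Low-pass filter and decimate a trial
#'
#' Standard preprocessing for raw recordings: a zero-phase Butterworth
#' low-pass filter followed by integer-factor decimation. Defaults reproduce
#' the common pipeline of a 50 Hz cutoff, order 4, and resampling to 100 Hz.
#' Synthetic trials from [simulate_trials()] are generated at the target
#' rate already, so this stage is optional.
#'
#' @param x Numeric `M x N` trial matrix, or a [trial_set] (each trial is
#'   processed).
#' @param fs Sampling rate of `x` in Hz.
#' @param cutoff_hz Low-pass cutoff in Hz; must be below `fs / 2`.
#' @param order Butterworth filter order.
#' @param downsample_to Target rate in Hz; must divide `fs` evenly.
#' @return Object of the same type as `x`, filtered and decimated.
#' @export
bandpass_preprocess <- function(x, fs, cutoff_hz = 50, order = 4,
                                downsample_to = 100) {
  if (inherits(x, "trial_set")) {
    out <- lapply(x$trials, bandpass_preprocess, fs = fs, cutoff_hz = cutoff_hz,
                  order = order, downsample_to = downsample_to)
    return(trial_set(out, x$labels))
  }
  check_finite_matrix(x, "trial")
  if (cutoff_hz >= fs / 2) {
    abort("cutoff must be below the Nyquist frequency", class = "cstfp_validation")
  }
  fac <- fs / downsample_to
  if (fac != round(fac) || fac < 1) {
    abort("`downsample_to` must divide `fs` evenly", class = "cstfp_validation")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  keep <- seq(1, ncol(x), by = fac)
  y[, keep, drop = FALSE]
}
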