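# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn
NULL

sym_part <- function(A) (A + t(A)) / 2

#' Fix the sign of a vector so its largest-magnitude entry is positive
#' @noRd
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("cannot normalize a zero vector", class = "cstfp_validation")
  v / nv
}

#' Symmetric-definite generalized eigenvalue decomposition A v = lambda B v
#'
#' Solved by whitening B. If B is ill-conditioned (condition number above
#' `ridge_cond`), a ridge `delta * trace(B) / nrow(B)` is added to its
#' diagonal. Eigenvalues are returned in descending order; eigenvectors are
#' unit Euclidean length with the largest-magnitude entry positive.
#' @noRd
gevd <- function(A, B, ridge_cond = 1e10, delta = 1e-10) {
  A <- sym_part(A)
  B <- sym_part(B)
  eb <- eigen(B, symmetric = TRUE)
  lo <- min(eb$values)
  hi <- max(eb$values)
  if (hi <= 0) {
    abort("matrix pencil is degenerate: B has no positive eigenvalue",
          class = "cstfp_ill_conditioned")
  }
  if (lo <= 0 || hi / lo > ridge_cond) {
    B <- B + diag(delta * sum(diag(B)) / nrow(B), nrow(B))
    eb <- eigen(B, symmetric = TRUE)
    if (min(eb$values) <= 0) {
      abort("matrix pencil remains singular after ridge",
            class = "cstfp_ill_conditioned")
    }
  }
  # whitening transform W = B^{-1/2}
  W <- eb$vectors %*% (t(eb$vectors) / sqrt(eb$values))
  ec <- eigen(sym_part(W %*% A %*% W), symmetric = TRUE)
  V <- W %*% ec$vectors
  V <- matrix(apply(V, 2, function(v) fix_sign(unit_vec(v))), nrow = nrow(V))
  list(values = ec$values, vectors = V)
}

#' K x P lag-embedding index matrix: idx[n, p] = n + P - p (1-based)
#' @noRd
lag_index <- function(K, P) {
  outer(seq_len(K), seq_len(P), function(n, p) n + P - p)
}

#' N x K banded convolution matrix H with H[n + P - p, n] = h[p], so that for
#' an M x N trial X the matrix X %*% H holds the FIR-filtered channels
#' (valid part, length K = N - P + 1).
#' @noRd
conv_matrix <- function(h, N) {
  P <- length(h)
  K <- N - P + 1
  H <- matrix(0, N, K)
  hr <- rev(h)
  for (n in seq_len(K)) H[n:(n + P - 1), n] <- hr
  H
}

#' FIR magnitude response on a frequency grid (Hz)
#' @noRd
fir_response <- function(h, fs, n_freq = 512L) {
  f <- seq(0, fs / 2, length.out = n_freq)
  p <- seq_along(h) - 1
  mag <- vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi * p / fs)))
  }, numeric(1))
  tibble::tibble(freq_hz = f, magnitude = mag)
}

#' Frequency (Hz) at which the FIR magnitude response peaks
#' @noRd
fir_peak_freq <- function(h, fs, n_freq = 2048L) {
  r <- fir_response(h, fs, n_freq)
  r$freq_hz[which.max(r$magnitude)]
}

#' Run code with a locally-set RNG seed, restoring the caller's RNG state
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix", what), class = "cstfp_validation")
  }
  if (!all(is.finite(x))) {
    abort(sprintf("%s contains non-finite entries", what), class = "cstfp_validation")
  }
  invisible(x)
}
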