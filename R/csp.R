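#' Per-class average covariance matrices
#'
#' For each class, averages the per-trial time-centered scatter
#' `(1/N) * sum_n (x_n - mu)(x_n - mu)'` over the trials of that class.
#'
#' @param data A [trial_set] (or long data frame coercible with
#'   [as_trial_set()]).
#' @return A list of class `covariance_pair` with symmetric PSD matrices
#'   `sigma1` and `sigma2`.
#' @export
class_covariances <- function(data) {
  ts <- as_trial_set(data)
  N <- attr(ts, "N")
  scatter <- function(x) {
    xc <- x - rowMeans(x)
    tcrossprod(xc) / N
  }
  avg <- function(d) {
    idx <- which(ts$labels == d)
    Reduce(`+`, lapply(ts$trials[idx], scatter)) / length(idx)
  }
  structure(list(sigma1 = avg(1L), sigma2 = avg(2L)), class = "covariance_pair")
}

#' Common spatial patterns (CSP)
#'
#' Solves the generalized eigenvalue problem
#' `Sigma_c w = lambda (Sigma_1 + Sigma_2) w` for the spatial filters that
#' extremize the ratio of one class's filtered-signal variance to the total.
#' All `M` eigenpairs are returned, sorted by descending eigenvalue; callers
#' typically keep the `r` first and `r` last eigenvectors as the
#' discriminative bank.
#'
#' @param data A [trial_set], or a `covariance_pair` from
#'   [class_covariances()].
#' @param c Target class label (1 or 2) whose variance is placed in the
#'   numerator.
#' @return An object of class `csp_result` with `eigenvalues` (descending,
#'   each in `[0, 1]`) and `eigenvectors` (`M x M`, unit-length columns with
#'   largest-magnitude entry positive).
#' @examples
#' cfg <- default_sim_config(trials_per_class = 10)
#' ts <- simulate_trials(cfg, seed = 1)
#' fit <- csp_fit(ts)
#' fit$eigenvalues
#' @export
csp_fit <- function(data, c = 1L) {
  if (!c %in% c(1L, 2L)) abort("`c` must be 1 or 2", class = "cstfp_validation")
  cov <- if (inherits(data, "covariance_pair")) data else class_covariances(data)
  num <- if (c == 1L) cov$sigma1 else cov$sigma2
  g <- gevd(num, cov$sigma1 + cov$sigma2)
  structure(list(eigenvalues = g$values, eigenvectors = g$vectors, c = c),
            class = "csp_result")
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf("<csp_result> class %d, %d spatial filters\n", x$c,
              length(x$eigenvalues)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 3), "\n")
  invisible(x)
}

#' Discriminative bank of 2r CSP eigenvectors
#'
#' Returns, as columns, the eigenvectors of a `csp_result` (or any sorted
#' eigensystem) corresponding to the `r` largest and `r` smallest
#' eigenvalues, in that order.
#' @noRd
csp_bank <- function(vectors, r) {
  M <- ncol(vectors)
  if (2 * r > M) {
    abort("2 * r must not exceed the channel count", class = "cstfp_validation")
  }
  top <- vectors[, seq_len(r), drop = FALSE]
  bottom <- vectors[, M - seq_len(r) + 1, drop = FALSE]
  cbind(top, bottom)
}
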