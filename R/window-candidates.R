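#' Candidate sets of binary time windows
#'
#' The time window of each designed filter is chosen by exhaustive search
#' over a finite candidate set of binary vectors of length `K` (the filtered
#' trial length). Two construction schemes are provided.
#'
#' `window_block_candidates()` partitions the first `J * D` samples into `J`
#' disjoint blocks of length `D` and emits every nonzero 0/1 combination of
#' the blocks — `2^J - 1` candidates.
#'
#' `window_contiguous_candidates()` emits all windows of the form
#' `D` leading zeros, `O` ones, trailing zeros, with `D` and `O` drawn from
#' the arithmetic grid `{0, step, 2*step, ..., K}` subject to
#' `O > min_len` and `D + O <= K`.
#'
#' Candidates with fewer than two active samples are rejected at
#' construction time, ordering is deterministic (combination index, or
#' lexicographic in `(D, O)`), and duplicates are removed.
#'
#' @param K Filtered trial length (window length).
#' @param D Block length (block scheme) / number of leading zeros grid
#'   (contiguous scheme uses `step`).
#' @param J Number of blocks; `J * D <= K` required.
#' @param step Grid step for the contiguous scheme.
#' @param min_len Strict lower bound on the active length `O` of contiguous
#'   candidates.
#' @return An object of class `window_candidates`: a list with `candidates`
#'   (an `L x K` 0/1 matrix, one row per candidate), `scheme`, and `params`.
#' @examples
#' wc <- window_block_candidates(K = 60, D = 6, J = 10)
#' nrow(wc$candidates)  # 1023
#' window_contiguous_candidates(K = 10, step = 5, min_len = 4)
#' @export
window_block_candidates <- function(K, D, J) {
  K <- as.integer(K); D <- as.integer(D); J <- as.integer(J)
  if (J < 1 || D < 1) abort("D and J must be positive", class = "cstfp_validation")
  if (J > 20L) abort("J > 20 would enumerate over a million candidates",
                     class = "cstfp_validation")
  if (J * D > K) {
    abort(sprintf("J * D = %d exceeds K = %d", J * D, K), class = "cstfp_geometry")
  }
  blocks <- lapply(seq_len(J), function(j) {
    b <- integer(K)
    b[(D * (j - 1) + 1):(D * j)] <- 1L
    b
  })
  L <- 2L^J - 1L
  cand <- matrix(0L, L, K)
  for (l in seq_len(L)) {
    bits <- which(bitwAnd(l, bitwShiftL(1L, seq_len(J) - 1L)) != 0L)
    cand[l, ] <- Reduce(`+`, blocks[bits])
  }
  new_window_candidates(cand, "block_combination", list(K = K, D = D, J = J))
}

#' @rdname window_block_candidates
#' @export
window_contiguous_candidates <- function(K, step = 5, min_len = 50) {
  K <- as.integer(K); step <- as.integer(step); min_len <- as.integer(min_len)
  if (step < 1) abort("step must be >= 1", class = "cstfp_validation")
  if (min_len < 2) abort("min_len must be >= 2", class = "cstfp_validation")
  grid <- sort(unique(c(seq(0L, K, by = step), K)))
  combos <- expand.grid(O = grid, D = grid)
  combos <- combos[combos$O > min_len & combos$D + combos$O <= K, , drop = FALSE]
  combos <- combos[order(combos$D, combos$O), , drop = FALSE]
  if (nrow(combos) == 0) {
    abort("no contiguous window satisfies the constraints", class = "cstfp_empty_candidates")
  }
  cand <- t(mapply(function(D, O) {
    c(integer(D), rep(1L, O), integer(K - D - O))
  }, combos$D, combos$O))
  new_window_candidates(cand, "contiguous",
                        list(K = K, step = step, min_len = min_len))
}

new_window_candidates <- function(cand, scheme, params) {
  keep <- rowSums(cand) >= 2
  cand <- cand[keep, , drop = FALSE]
  cand <- unique(cand)
  if (nrow(cand) == 0) {
    abort("candidate set is empty after rejecting degenerate windows",
          class = "cstfp_empty_candidates")
  }
  structure(list(candidates = cand, scheme = scheme, params = params),
            class = "window_candidates")
}

#' @export
print.window_candidates <- function(x, ...) {
  cat(sprintf("<window_candidates> %s scheme, L = %d candidates of length K = %d\n",
              x$scheme, nrow(x$candidates), ncol(x$candidates)))
  invisible(x)
}

#' @export
as.matrix.window_candidates <- function(x, ...) x$candidates
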