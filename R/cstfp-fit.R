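#' Discriminative variance-ratio objective for one parameter triple
#'
#' Evaluates the per-filter objective: the ratio
#' `J_hat = E_c[alpha] / (E_1[alpha] + E_2[alpha])` of the class-`c` mean
#' windowed variance to the total over both classes, plus the window-length
#' reward `(epsilon / K) * ||b||` (Euclidean norm of the binary window, i.e.
#' the square root of the active-sample count).
#'
#' @param data A [trial_set] (or long data frame).
#' @param w,h,b Spatial weights (length `M`), FIR taps (length `P`), and
#'   binary window (length `K = N - P + 1`).
#' @param epsilon Window-length regularization weight (>= 0).
#' @param c Target class (1 or 2).
#' @param norm Averaging convention, see [alpha_variance()].
#' @return A list of class `cstfp_objective` with `j_hat` (in `[0, 1]`),
#'   `penalty`, and `total`.
#' @export
cstfp_objective <- function(data, w, h, b, epsilon = 0.1, c = 1L,
                            norm = c("count", "euclidean")) {
  norm <- match.arg(norm)
  ts <- as_trial_set(data)
  K <- length(b)
  a <- vapply(ts$trials, alpha_variance, numeric(1), w = w, h = h, b = b,
              norm = norm)
  m1 <- mean(a[ts$labels == 1L])
  m2 <- mean(a[ts$labels == 2L])
  if (m1 + m2 <= 0) {
    abort("all trials have zero windowed variance; objective undefined",
          class = "cstfp_degenerate_signal")
  }
  j_hat <- (if (c == 1L) m1 else m2) / (m1 + m2)
  penalty <- epsilon / K * sqrt(sum(b))
  structure(list(j_hat = j_hat, penalty = penalty, total = j_hat + penalty),
            class = "cstfp_objective")
}

#' @export
print.cstfp_objective <- function(x, ...) {
  cat(sprintf("J_hat = %.6f, penalty = %.6f, total = %.6f\n",
              x$j_hat, x$penalty, x$total))
  invisible(x)
}

# ---- block updates ---------------------------------------------------------

#' Per-class spatial scatter of the filtered, window-centered trials:
#' R_d = E_{X in class d}[ (1/denom) * sum_n b_n (A_hat_n h)(A_hat_n h)' ]
#' @noRd
spatial_scatter <- function(ts, h, b, norm) {
  N <- attr(ts, "N")
  M <- attr(ts, "M")
  H <- conv_matrix(h, N)
  denom <- window_denom(sum(b), norm)
  active <- which(b == 1)
  acc <- list(`1` = matrix(0, M, M), `2` = matrix(0, M, M))
  counts <- c(`1` = 0, `2` = 0)
  for (i in seq_along(ts$trials)) {
    Y <- ts$trials[[i]] %*% H                     # M x K filtered channels
    ybar <- as.vector(Y %*% b) / denom
    Yb <- (Y - ybar)[, active, drop = FALSE]
    d <- as.character(ts$labels[i])
    acc[[d]] <- acc[[d]] + tcrossprod(Yb) / denom
    counts[d] <- counts[d] + 1
  }
  list(R1 = acc[["1"]] / counts[["1"]], R2 = acc[["2"]] / counts[["2"]])
}

#' Spatial-weight update: top generalized eigenvector of
#' R_c w = lambda (R1 + R2) w, with the full sorted eigensystem.
#'
#' @param data A [trial_set].
#' @param h Current FIR taps.
#' @param b Current binary window.
#' @param c Target class.
#' @param norm Averaging convention.
#' @return List with `w` (unit length, sign-fixed), `lambda` (top
#'   eigenvalue), and the full sorted `values` / `vectors`.
#' @export
cstfp_update_w <- function(data, h, b, c = 1L, norm = c("count", "euclidean")) {
  norm <- match.arg(norm)
  ts <- as_trial_set(data)
  b <- check_window(b, attr(ts, "N") - length(h) + 1L)
  R <- spatial_scatter(ts, h, b, norm)
  num <- if (c == 1L) R$R1 else R$R2
  g <- gevd(num, R$R1 + R$R2)
  list(w = g$vectors[, 1], lambda = g$values[1],
       values = g$values, vectors = g$vectors)
}

#' Per-class lag scatter of the spatially combined, window-centered trials:
#' Q_d = E_{X in class d}[ (1/denom) * sum_n b_n (A_hat_n' w)(A_hat_n' w)' ]
#' @noRd
lag_scatter <- function(ts, w, b, norm, P) {
  N <- attr(ts, "N")
  K <- N - P + 1L
  idx <- lag_index(K, P)
  denom <- window_denom(sum(b), norm)
  active <- which(b == 1)
  acc <- list(`1` = matrix(0, P, P), `2` = matrix(0, P, P))
  counts <- c(`1` = 0, `2` = 0)
  for (i in seq_along(ts$trials)) {
    z <- as.vector(crossprod(w, ts$trials[[i]]))
    Z <- matrix(z[idx], K, P)                     # Z[n, p] = z[n + P - p]
    zbar <- as.vector(crossprod(Z, b)) / denom
    Zb <- Z[active, , drop = FALSE] - rep(zbar, each = length(active))
    d <- as.character(ts$labels[i])
    acc[[d]] <- acc[[d]] + crossprod(Zb) / denom
    counts[d] <- counts[d] + 1
  }
  list(Q1 = acc[["1"]] / counts[["1"]], Q2 = acc[["2"]] / counts[["2"]])
}

#' Deflation subspace for the next FIR filter
#'
#' The `i`-th filter is constrained to the orthogonal complement of the span
#' of all previously designed filters together with their one-sample
#' circular shifts (`h'[k] = h[(k mod P) + 1]`, i.e. shifted copies that have
#' the same magnitude response), plus an optional extra subspace for the
#' first filter. Rank-deficient spanning sets are pruned with a warning.
#'
#' @param previous_h List of previously designed unit-length FIR vectors
#'   (possibly empty).
#' @param extra Optional `P x d` matrix of additional spanning vectors.
#' @param shifts `"all"` (default; shifts of every previous filter) or
#'   `"last"` (shifts of the most recent filter only).
#' @param P Filter order; required when `previous_h` is empty and `extra`
#'   is `NULL`.
#' @return A `P x D_i` matrix `V` of linearly independent spanning vectors
#'   (`D_i = 0` columns for the first filter with no extra subspace).
#' @export
build_deflation_subspace <- function(previous_h, extra = NULL,
                                     shifts = c("all", "last"), P = NULL) {
  shifts <- match.arg(shifts)
  if (length(previous_h) == 0 && is.null(extra)) {
    if (is.null(P)) abort("P needed for an empty subspace", class = "cstfp_validation")
    return(matrix(0, P, 0))
  }
  P <- if (length(previous_h) > 0) length(previous_h[[1]]) else nrow(extra)
  shift1 <- function(h) c(h[-1], h[1])
  shifted <- if (shifts == "all") lapply(previous_h, shift1)
             else if (length(previous_h) > 0) list(shift1(previous_h[[length(previous_h)]]))
             else list()
  V <- do.call(cbind, c(previous_h, shifted, if (!is.null(extra)) list(extra)))
  if (is.null(V)) return(matrix(0, P, 0))
  qrv <- qr(V, tol = 1e-10)
  if (qrv$rank < ncol(V)) {
    warn(sprintf("deflation subspace rank %d < %d spanning vectors; pruning",
                 qrv$rank, ncol(V)))
    V <- V[, qrv$pivot[seq_len(qrv$rank)], drop = FALSE]
  }
  V
}

#' Orthonormal basis of the complement of span(V) in R^P
#' @noRd
complement_basis <- function(V, P) {
  if (ncol(V) == 0) return(diag(P))
  qr.Q(qr(V), complete = TRUE)[, (ncol(V) + 1):P, drop = FALSE]
}

#' FIR-filter update under the deflation constraint
#'
#' Maximizes the variance-ratio over FIR taps `h` with `w` and `b` fixed,
#' subject to `V' h = 0`. The constrained pencil is solved by projecting
#' onto an orthonormal basis of the complement of `span(V)`, solving the
#' reduced symmetric-definite generalized eigenproblem
#' `Q_c h = zeta (Q1 + Q2) h` there, and mapping back; this is equivalent to
#' the oblique-projector stationarity conditions and numerically stable.
#'
#' @param data A [trial_set].
#' @param w Current spatial weights.
#' @param b Current binary window.
#' @param V Deflation subspace matrix (`P x D_i`, possibly 0 columns) from
#'   [build_deflation_subspace()].
#' @param c Target class.
#' @param norm Averaging convention.
#' @return List with `h` (unit length, sign-fixed, `V' h = 0`), `zeta`
#'   (top constrained eigenvalue), and the reduced eigensystem.
#' @export
cstfp_update_h <- function(data, w, b, V, c = 1L, norm = c("count", "euclidean")) {
  norm <- match.arg(norm)
  ts <- as_trial_set(data)
  P <- nrow(V)
  b <- check_window(b, attr(ts, "N") - P + 1L)
  Q <- lag_scatter(ts, w, b, norm, P)
  num <- if (c == 1L) Q$Q1 else Q$Q2
  B <- complement_basis(V, P)
  g <- gevd(crossprod(B, num %*% B), crossprod(B, (Q$Q1 + Q$Q2) %*% B))
  h <- fix_sign(unit_vec(as.vector(B %*% g$vectors[, 1])))
  list(h = h, zeta = g$values[1], values = g$values,
       vectors = B %*% g$vectors)
}

#' Exhaustive time-window update over a candidate set
#'
#' With `w` and `h` fixed, the extracted signal `x_tilde[n] = w' A_n h` of
#' each trial is precomputed once and the objective
#' `J3(b) = g1 / (g1 + g2) + (epsilon / K) * ||b||` is evaluated for every
#' candidate window in one vectorized pass (`g_d` is the class-`d` mean of
#' the windowed variance of `x_tilde`). Ties go to the first candidate in
#' the set's deterministic ordering.
#'
#' @param data A [trial_set].
#' @param w,h Current spatial weights and FIR taps.
#' @param candidates A [window_candidates] set.
#' @param epsilon Window-length regularization weight.
#' @param c Target class.
#' @param norm Averaging convention.
#' @return List with `b` (the winning candidate), `index` (its row), and
#'   `j3` (its objective value).
#' @export
cstfp_update_b <- function(data, w, h, candidates, epsilon = 0.1, c = 1L,
                           norm = c("count", "euclidean")) {
  norm <- match.arg(norm)
  ts <- as_trial_set(data)
  Bm <- as.matrix(candidates)
  K <- ncol(Bm)
  if (K != attr(ts, "N") - length(h) + 1L) {
    abort("candidate length does not match filtered length", class = "cstfp_validation")
  }
  n_act <- rowSums(Bm)
  denom <- window_denom(n_act, norm)
  g <- list(`1` = numeric(nrow(Bm)), `2` = numeric(nrow(Bm)))
  counts <- c(`1` = 0, `2` = 0)
  for (i in seq_along(ts$trials)) {
    xt <- filtered_signal(ts$trials[[i]], w, h)
    s1 <- as.vector(Bm %*% xt)
    s2 <- as.vector(Bm %*% xt^2)
    mu <- s1 / denom
    a <- (s2 - 2 * mu * s1 + n_act * mu^2) / denom
    d <- as.character(ts$labels[i])
    g[[d]] <- g[[d]] + a
    counts[d] <- counts[d] + 1
  }
  g1 <- g[["1"]] / counts[["1"]]
  g2 <- g[["2"]] / counts[["2"]]
  gc_ <- if (c == 1L) g1 else g2
  j3 <- gc_ / (g1 + g2) + epsilon / K * sqrt(n_act)
  best <- which.max(j3)   # first index wins on ties
  list(b = as.numeric(Bm[best, ]), index = best, j3 = j3[best])
}

# ---- full fit --------------------------------------------------------------

#' Fit common spatio-time-frequency patterns
#'
#' Designs `n_filters` triples of spatial weights `w_i`, FIR bandpass taps
#' `h_i`, and binary time windows `b_i` that maximize the discriminative
#' variance ratio between the two classes, sequentially over filters with a
#' deflation constraint (each new filter is orthogonal to all previous
#' filters and their circular shifts, enforcing spectral diversity), and for
#' each filter by alternating exact block updates: a generalized eigenvalue
#' step for `w`, a constrained generalized eigenvalue step for `h`, and an
#' exhaustive search over the window candidate set for `b`. After
#' convergence of every filter, a bank of `2r` CSP eigenvectors is computed
#' per filter at its final `(h_i, b_i)` for feature extraction.
#'
#' @param data A [trial_set], or a long data frame coercible with
#'   [as_trial_set()].
#' @param n_filters Number of parameter triples `F` to design.
#' @param r Per-filter CSP bank half-size; features have length
#'   `2 * r * n_filters`. Requires `2 * r <= M`.
#' @param P FIR filter order (number of taps).
#' @param epsilon Window-length regularization weight; larger values favor
#'   longer windows.
#' @param c Target class (1 or 2) whose variance ratio is maximized.
#' @param candidates A [window_candidates] set of length `K = N - P + 1`;
#'   default is the contiguous scheme with step 5 and minimum active length
#'   `min(50, K - 1)`.
#' @param norm Averaging convention for windowed variances, see
#'   [alpha_variance()].
#' @param tol Convergence tolerance on the change of the objective between
#'   successive alternating sweeps.
#' @param max_iter Maximum alternating sweeps per filter; non-convergence
#'   produces a warning and keeps the last iterate.
#' @param seed Integer seed for the random filter initialization; the
#'   caller's RNG state is left untouched.
#' @param extra_subspace Optional `P x d` matrix spanning an extra subspace
#'   the first filter must be orthogonal to (default none).
#' @param shifts Which previous filters contribute circular shifts to the
#'   deflation subspace: `"all"` (default) or `"last"`.
#' @param loop_order Permutation of `c("w", "h", "b")` giving the block
#'   update order within each sweep.
#' @param init_window Optional initial binary window (length `K`); the
#'   default starts from the all-ones window. Alternating ascent converges
#'   to a local maximum, so multi-starting over both `seed` and
#'   `init_window` explores more basins on hard problems.
#' @return An object of class `cstfp`: parameter triples, per-filter CSP
#'   banks and eigenvalues, per-sweep objective traces, convergence flags,
#'   and the configuration. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()], [cstfp_features()], and JSON serialization via
#'   [write_cstfp_model()].
#' @examples
#' cfg <- default_sim_config(trials_per_class = 15)
#' ts <- simulate_trials(cfg, seed = 1)
#' fit <- cstfp(ts, n_filters = 2, r = 1, P = 21, seed = 1)
#' fit
#' tidy(fit)
#' @export
cstfp <- function(data, n_filters = 4L, r = 1L, P = 41L, epsilon = 0.1,
                  c = 1L, candidates = NULL,
                  norm = c("count", "euclidean"),
                  tol = 1e-5, max_iter = 100L, seed = NULL,
                  extra_subspace = NULL, shifts = c("all", "last"),
                  loop_order = c("w", "h", "b"), init_window = NULL) {
  norm <- match.arg(norm)
  shifts <- match.arg(shifts)
  if (!setequal(loop_order, c("w", "h", "b")) || length(loop_order) != 3) {
    abort("`loop_order` must be a permutation of c('w','h','b')",
          class = "cstfp_validation")
  }
  ts <- as_trial_set(data)
  M <- attr(ts, "M"); N <- attr(ts, "N")
  n_filters <- as.integer(n_filters); r <- as.integer(r); P <- as.integer(P)
  if (n_filters < 1 || r < 1 || epsilon < 0) {
    abort("need n_filters >= 1, r >= 1, epsilon >= 0", class = "cstfp_validation")
  }
  if (2L * r > M) abort("2 * r must not exceed the channel count",
                        class = "cstfp_validation")
  if (P > N) abort("filter order exceeds trial length",
                   class = "cstfp_invalid_filter_order")
  if (n_filters > P) abort("cannot design more mutually orthogonal filters than taps",
                           class = "cstfp_validation")
  K <- N - P + 1L
  if (is.null(candidates)) {
    candidates <- window_contiguous_candidates(K, step = 5L,
                                               min_len = min(50L, K - 1L))
  }
  if (ncol(as.matrix(candidates)) != K) {
    abort("candidate window length must equal K = N - P + 1",
          class = "cstfp_validation")
  }

  with_local_seed(seed, {
    hs <- list(); ws <- list(); bs <- list()
    traces <- list(); converged <- logical(n_filters); iters <- integer(n_filters)
    for (i in seq_len(n_filters)) {
      V <- build_deflation_subspace(hs, extra = extra_subspace,
                                    shifts = shifts, P = P)
      # random init orthonormalized against the deflation subspace
      h <- stats::rnorm(P)
      if (ncol(V) > 0) h <- h - V %*% qr.solve(crossprod(V), crossprod(V, h))
      h <- fix_sign(unit_vec(as.vector(h)))
      b <- if (is.null(init_window)) rep(1, K) else check_window(init_window, K)
      w <- cstfp_update_w(ts, h, b, c = c, norm = norm)$w
      trace <- numeric(0)
      prev <- -Inf
      conv <- FALSE
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        for (step in loop_order) {
          if (step == "w") {
            w <- cstfp_update_w(ts, h, b, c = c, norm = norm)$w
          } else if (step == "h") {
            h <- cstfp_update_h(ts, w, b, V, c = c, norm = norm)$h
          } else {
            b <- cstfp_update_b(ts, w, h, candidates, epsilon = epsilon,
                                c = c, norm = norm)$b
          }
        }
        obj <- cstfp_objective(ts, w, h, b, epsilon = epsilon, c = c,
                               norm = norm)$total
        trace <- c(trace, obj)
        if (is.finite(prev) && abs(obj - prev) < tol) {
          conv <- TRUE
          break
        }
        prev <- obj
      }
      if (!conv) {
        warn(sprintf("filter %d: no convergence within %d sweeps; keeping last iterate",
                     i, max_iter))
      }
      ws[[i]] <- fix_sign(w); hs[[i]] <- h; bs[[i]] <- b
      traces[[i]] <- trace; converged[i] <- conv; iters[i] <- it
    }

    # pairwise orthonormality is a hard contract of the sequential design
    for (i in seq_len(n_filters)) {
      for (j in seq_len(i)) {
        dot <- sum(hs[[i]] * hs[[j]])
        expect <- as.numeric(i == j)
        if (abs(dot - expect) > 1e-8) {
          abort(sprintf("filter orthonormality violated: h%d' h%d = %.3e",
                        i, j, dot), class = "cstfp_constraint")
        }
      }
    }

    # per-filter CSP bank at the converged (h_i, b_i)
    banks <- list(); eigvals <- list(); j_hat <- numeric(n_filters)
    for (i in seq_len(n_filters)) {
      up <- cstfp_update_w(ts, hs[[i]], bs[[i]], c = c, norm = norm)
      banks[[i]] <- csp_bank(up$vectors, r)
      eigvals[[i]] <- up$values
      j_hat[i] <- cstfp_objective(ts, ws[[i]], hs[[i]], bs[[i]],
                                  epsilon = epsilon, c = c, norm = norm)$j_hat
    }

    structure(list(
      w = ws, h = hs, b = bs,
      csp_banks = banks, eigenvalues = eigvals,
      j_hat = j_hat,
      objective_trace = traces,
      converged = converged, iterations = iters,
      config = list(
        n_filters = n_filters, r = r, P = P, K = K, M = M, N = N,
        epsilon = epsilon, c = c, norm = norm, tol = tol,
        max_iter = max_iter, seed = seed, shifts = shifts,
        loop_order = loop_order,
        candidate_scheme = candidates$scheme,
        candidate_params = candidates$params
      )
    ), class = "cstfp")
  })
}

#' @export
print.cstfp <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cstfp> %d filter(s), r = %d, P = %d taps, K = %d, epsilon = %g\n",
              cfg$n_filters, cfg$r, cfg$P, cfg$K, cfg$epsilon))
  for (i in seq_len(cfg$n_filters)) {
    act <- which(x$b[[i]] == 1)
    cat(sprintf(
      "  filter %d: J_hat = %.4f, window [%d, %d] (%d/%d active), %d sweep(s)%s\n",
      i, x$j_hat[i], min(act), max(act), length(act), cfg$K, x$iterations[i],
      if (x$converged[i]) "" else " (not converged)"
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-filter summary of a fitted model
#'
#' @param x A fitted [cstfp] model.
#' @param fs Sampling rate in Hz used to express the filter's peak response
#'   frequency (default taken from 100 Hz if not supplied).
#' @param ... Unused.
#' @return A tibble with one row per designed filter: discriminative ratio,
#'   peak response frequency, window extent, and iteration count.
#' @method tidy cstfp
#' @export
tidy.cstfp <- function(x, fs = 100, ...) {
  cfg <- x$config
  purrr::map_dfr(seq_len(cfg$n_filters), function(i) {
    act <- which(x$b[[i]] == 1)
    tibble::tibble(
      filter = i,
      j_hat = x$j_hat[i],
      peak_hz = fir_peak_freq(x$h[[i]], fs),
      window_start = min(act),
      window_end = max(act),
      n_active = length(act),
      iterations = x$iterations[i],
      converged = x$converged[i]
    )
  })
}

#' One-row summary of a fitted model
#' @param x A fitted [cstfp] model.
#' @param ... Unused.
#' @return A one-row tibble with configuration and aggregate fit summaries.
#' @method glance cstfp
#' @export
glance.cstfp <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_filters = cfg$n_filters, r = cfg$r, P = cfg$P, K = cfg$K,
    epsilon = cfg$epsilon, target_class = cfg$c,
    mean_j_hat = mean(x$j_hat),
    total_iterations = sum(x$iterations),
    all_converged = all(x$converged)
  )
}
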