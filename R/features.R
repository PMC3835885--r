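#' Log-variance features from a fitted model
#'
#' Maps each trial to the `2 * r * n_filters`-dimensional feature vector of
#' windowed variances `alpha(w_hat_i^(m), h_i, b_i)` for every filter `i`
#' and every eigenvector `m` of its CSP bank (top-`r` then bottom-`r`),
#' optionally log-transformed (natural log; the default, matching the
#' standard variance-feature pipeline). Layout is filter-major:
#' `f1_e1, ..., f1_e2r, f2_e1, ...`.
#'
#' @param data A [trial_set] (or long data frame).
#' @param model A fitted [cstfp] model with matching channel/sample counts.
#' @param log Apply the natural logarithm to each variance (default `TRUE`).
#' @param floor Positive lower bound applied before the log to guard
#'   zero-variance features; flooring raises a warning.
#' @return A tibble with columns `trial`, `label`, and one numeric column
#'   per feature.
#' @export
cstfp_features <- function(data, model, log = TRUE, floor = 1e-12) {
  ts <- as_trial_set(data)
  cfg <- model$config
  if (attr(ts, "M") != cfg$M || attr(ts, "N") != cfg$N) {
    abort("trial dimensions do not match the fitted model", class = "cstfp_dims")
  }
  n_feat <- 2L * cfg$r * cfg$n_filters
  vals <- matrix(NA_real_, length(ts$trials), n_feat)
  col <- 0L
  names <- character(n_feat)
  for (i in seq_len(cfg$n_filters)) {
    bank <- model$csp_banks[[i]]
    for (m in seq_len(2L * cfg$r)) {
      col <- col + 1L
      names[col] <- sprintf("f%d_e%d", i, m)
      vals[, col] <- vapply(ts$trials, alpha_variance, numeric(1),
                            w = bank[, m], h = model$h[[i]], b = model$b[[i]],
                            norm = cfg$norm)
    }
  }
  if (log) {
    if (any(vals < floor)) {
      warn("zero or near-zero variance features floored before log")
      vals <- pmax(vals, floor)
    }
    vals <- base::log(vals)
  }
  colnames(vals) <- names
  dplyr::bind_cols(
    tibble::tibble(trial = seq_along(ts$trials), label = ts$labels),
    tibble::as_tibble(vals)
  )
}

#' Fisher linear discriminant with midpoint threshold
#'
#' Fits the Fisher discriminant from the pooled within-class scatter and the
#' class-mean difference, `a = S_w^{-1} (mu_1 - mu_2)`, oriented so class 1
#' projects higher. The decision threshold is the midpoint of the two
#' projected class means (no class priors). A small ridge
#' `delta * trace / dim` stabilizes a singular scatter.
#'
#' @param features A data frame of numeric features; columns named `trial`
#'   and `label` are ignored as predictors (the latter supplies labels when
#'   `labels` is missing).
#' @param labels Class labels (1/2), one per row; defaults to
#'   `features$label`.
#' @param ridge_delta Relative ridge for a singular within-class scatter.
#' @return An object of class `fisher_lda` with `projector`, `threshold`,
#'   and `class_means_projected`.
#' @export
fisher_lda <- function(features, labels = NULL, ridge_delta = 1e-8) {
  X <- feature_matrix(features)
  if (is.null(labels)) {
    if (!"label" %in% names(features)) {
      abort("no labels supplied", class = "cstfp_validation")
    }
    labels <- features$label
  }
  labels <- as.integer(labels)
  if (any(table(factor(labels, levels = 1:2)) < 2)) {
    abort("need at least 2 samples per class", class = "cstfp_validation")
  }
  mu1 <- colMeans(X[labels == 1L, , drop = FALSE])
  mu2 <- colMeans(X[labels == 2L, , drop = FALSE])
  center <- X - rbind(mu1, mu2)[ifelse(labels == 1L, 1L, 2L), , drop = FALSE]
  Sw <- crossprod(center)
  Sw <- Sw + diag(ridge_delta * sum(diag(Sw)) / ncol(Sw), ncol(Sw))
  a <- solve(Sw, mu1 - mu2)
  p1 <- sum(a * mu1)
  p2 <- sum(a * mu2)
  if (p1 < p2) { # orient so class 1 projects higher
    a <- -a; p1 <- -p1; p2 <- -p2
  }
  structure(list(
    projector = a,
    threshold = (p1 + p2) / 2,
    class_means_projected = c(p1, p2),
    feature_names = colnames(X)
  ), class = "fisher_lda")
}

feature_matrix <- function(features) {
  df <- as.data.frame(features)
  drop <- intersect(c("trial", "label"), names(df))
  as.matrix(df[setdiff(names(df), drop)])
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda> %d features, threshold %.4f, projected means %.4f / %.4f\n",
              length(x$projector), x$threshold,
              x$class_means_projected[1], x$class_means_projected[2]))
  invisible(x)
}

#' Classify feature vectors with a fitted discriminant
#'
#' Projects each feature vector and thresholds: projections at or above the
#' midpoint are assigned the class with the larger projected mean (class 1
#' by the fitted orientation), so exact-threshold ties resolve
#' deterministically to that class.
#'
#' @param object A [fisher_lda] model.
#' @param newdata A data frame of features (columns `trial` / `label`
#'   ignored), or a numeric matrix.
#' @param ... Unused.
#' @return Integer vector of predicted class labels (1/2).
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(X) != length(object$projector)) {
    abort("feature dimension does not match the discriminant", class = "cstfp_dims")
  }
  proj <- as.vector(X %*% object$projector)
  ifelse(proj >= object$threshold, 1L, 2L)
}

#' Stratified repeated cross-validation of the full pipeline
#'
#' Repeats a stratified k-fold split; inside every training fold the whole
#' pipeline — filter design ([cstfp()]), feature extraction, and the Fisher
#' discriminant — is refitted from scratch, then the held-out fold is
#' classified. Held-out trials are never touched during fitting.
#'
#' @param data A [trial_set] (or long data frame).
#' @param folds Number of folds per repeat (>= 2).
#' @param repeats Number of repeats.
#' @param seed Integer seed controlling both the fold shuffling and the
#'   per-fit filter initialization.
#' @param ... Passed on to [cstfp()] (e.g. `n_filters`, `r`, `P`,
#'   `epsilon`, `candidates`).
#' @return A tibble of class `cstfp_cv` with columns `repeat_`, `fold`,
#'   `n_test`, `accuracy` (fraction correct), carrying the mean and sd as
#'   attributes; `summary()`/`print()` report mean +/- sd.
#' @export
cstfp_cross_validate <- function(data, folds = 5L, repeats = 5L, seed = NULL,
                                 ...) {
  ts <- as_trial_set(data)
  folds <- as.integer(folds)
  if (folds < 2L) abort("need folds >= 2", class = "cstfp_validation")
  if (min(table(factor(ts$labels, levels = 1:2))) < folds) {
    abort("each class needs at least one trial per fold", class = "cstfp_validation")
  }
  rows <- with_local_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(rep_i) {
      fold_of <- integer(length(ts$labels))
      for (d in 1:2) {
        idx <- which(ts$labels == d)
        fold_of[sample(idx)] <- rep_len(seq_len(folds), length(idx))
      }
      fit_seed <- sample.int(2^30, 1)
      purrr::map_dfr(seq_len(folds), function(f) {
        train <- ts[fold_of != f]
        test <- ts[fold_of == f]
        model <- cstfp(train, seed = fit_seed + f, ...)
        lda <- fisher_lda(cstfp_features(train, model))
        pred <- predict(lda, cstfp_features(test, model))
        tibble::tibble(
          repeat_ = rep_i, fold = f, n_test = length(test$labels),
          accuracy = mean(pred == test$labels)
        )
      })
    })
  })
  structure(rows, class = c("cstfp_cv", class(rows)),
            mean_accuracy = mean(rows$accuracy),
            sd_accuracy = stats::sd(rows$accuracy))
}

#' @export
print.cstfp_cv <- function(x, ...) {
  NextMethod()
  cat(sprintf("mean accuracy %.1f%% +/- %.1f%% over %d folds\n",
              100 * attr(x, "mean_accuracy"), 100 * attr(x, "sd_accuracy"),
              nrow(x)))
  invisible(x)
}

#' @export
summary.cstfp_cv <- function(object, ...) {
  tibble::tibble(
    folds = nrow(object),
    mean_accuracy = attr(object, "mean_accuracy"),
    sd_accuracy = attr(object, "sd_accuracy")
  )
}
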