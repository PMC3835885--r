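#' Labeled two-class collection of multichannel trials
#'
#' A `trial_set` holds an ordered list of equal-size trials, each an
#' `M x N` numeric matrix (channels by time samples), together with a class
#' label in `{1, 2}` per trial. It is the input container for every fitting
#' and feature-extraction function in the package.
#'
#' @param trials List of numeric matrices, all with identical dimensions
#'   `M x N`; rows are channels, columns are time samples.
#' @param labels Integer vector of class labels, one per trial, each 1 or 2.
#'   Both classes must be present.
#'
#' @return An object of class `trial_set` with elements `trials`, `labels`
#'   and scalar attributes `M` (channels) and `N` (samples).
#'
#' @examples
#' ts <- trial_set(
#'   trials = list(matrix(rnorm(20), 2, 10), matrix(rnorm(20), 2, 10)),
#'   labels = c(1, 2)
#' )
#' ts
#' @export
trial_set <- function(trials, labels) {
  if (!is.list(trials) || length(trials) == 0) {
    abort("`trials` must be a nonempty list of matrices", class = "cstfp_validation")
  }
  labels <- as.integer(labels)
  if (length(labels) != length(trials)) {
    abort("`labels` must have one entry per trial", class = "cstfp_validation")
  }
  if (!all(labels %in% c(1L, 2L))) {
    abort("labels must be 1 or 2", class = "cstfp_validation")
  }
  if (!all(c(1L, 2L) %in% labels)) {
    abort("both classes must be nonempty", class = "cstfp_validation")
  }
  for (i in seq_along(trials)) {
    trials[[i]] <- as.matrix(trials[[i]])
    check_finite_matrix(trials[[i]], sprintf("trial %d", i))
  }
  d <- dim(trials[[1]])
  same <- vapply(trials, function(x) identical(dim(x), d), logical(1))
  if (!all(same)) {
    abort("all trials must share identical channel and sample counts",
          class = "cstfp_validation")
  }
  structure(
    list(trials = trials, labels = labels),
    M = d[1], N = d[2],
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials (%d class 1, %d class 2), %d channels x %d samples\n",
    length(x$trials), sum(x$labels == 1L), sum(x$labels == 2L),
    attr(x, "M"), attr(x, "N")
  ))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Coerce tabular trial data to a `trial_set`
#'
#' The long ("tidy") representation has one row per recorded value with
#' columns `trial`, `channel`, `time`, `value` and `label`. `as_trial_set()`
#' pivots it into the matrix-list container used by the fitting functions;
#' `as_tibble()` on a `trial_set` performs the inverse.
#'
#' @param x A data frame with columns `trial`, `channel`, `time`, `value`,
#'   `label`, or an existing `trial_set` (returned unchanged).
#' @param ... Unused.
#' @return A [trial_set].
#' @export
as_trial_set <- function(x, ...) UseMethod("as_trial_set")

#' @export
as_trial_set.trial_set <- function(x, ...) x

#' @export
as_trial_set.data.frame <- function(x, ...) {
  needed <- c("trial", "channel", "time", "value", "label")
  if (!all(needed %in% names(x))) {
    abort(sprintf("data frame must have columns %s", paste(needed, collapse = ", ")),
          class = "cstfp_validation")
  }
  ids <- unique(x$trial)
  split_x <- split(x, factor(x$trial, levels = ids))
  trials <- lapply(split_x, function(d) {
    ch <- sort(unique(d$channel))
    tm <- sort(unique(d$time))
    m <- matrix(NA_real_, length(ch), length(tm))
    m[cbind(match(d$channel, ch), match(d$time, tm))] <- d$value
    if (anyNA(m)) {
      abort("incomplete trial grid: every (channel, time) pair needs a value",
            class = "cstfp_validation")
    }
    m
  })
  labels <- vapply(split_x, function(d) as.integer(d$label[1]), integer(1))
  trial_set(unname(trials), unname(labels))
}

#' @importFrom tibble as_tibble
#' @method as_tibble trial_set
#' @export
as_tibble.trial_set <- function(x, ...) {
  M <- attr(x, "M")
  N <- attr(x, "N")
  purrr::map2_dfr(x$trials, seq_along(x$trials), function(m, i) {
    tibble::tibble(
      trial = i,
      channel = rep(seq_len(M), times = N),
      time = rep(seq_len(N), each = M),
      value = as.vector(m),
      label = x$labels[i]
    )
  })
}

#' Subset a trial set by trial index
#' @param x A [trial_set].
#' @param i Integer or logical index over trials.
#' @export
`[.trial_set` <- function(x, i) {
  trial_set(x$trials[i], x$labels[i])
}

#' Read and write trial sets as delimited text plus a manifest
#'
#' Trials are stored one file per trial as tab-separated text (rows =
#' channels, columns = samples) next to a `manifest.csv` with columns
#' `trial_id`, `file`, `label`. Text round-trips are exact to full double
#' precision.
#'
#' @param dir Directory holding (or to receive) the manifest and trial files.
#' @param x A [trial_set] to write.
#' @return `read_trial_set()` returns a [trial_set]; `write_trial_set()`
#'   returns `dir` invisibly.
#' @export
read_trial_set <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path), class = "cstfp_manifest")
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "file", "label") %in% names(man))) {
    abort("manifest must have columns trial_id, file, label", class = "cstfp_manifest")
  }
  if (!all(man$label %in% c(1L, 2L))) {
    abort("manifest labels must be 1 or 2", class = "cstfp_manifest")
  }
  trials <- lapply(man$file, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("trial file missing: %s", p), class = "cstfp_manifest")
    as.matrix(utils::read.table(p, sep = "\t"))
  })
  trials <- lapply(trials, function(m) {
    dimnames(m) <- NULL
    m
  })
  trial_set(trials, man$label)
}

#' @rdname read_trial_set
#' @export
write_trial_set <- function(x, dir) {
  x <- as_trial_set(x)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trial_%04d.tsv", seq_along(x$trials))
  for (i in seq_along(x$trials)) {
    utils::write.table(
      format(x$trials[[i]], digits = 17, scientific = TRUE, trim = TRUE),
      file.path(dir, files[i]),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  man <- data.frame(trial_id = seq_along(x$trials), file = files, label = x$labels)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
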