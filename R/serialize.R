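#' Serialize a fitted model to JSON and back
#'
#' A fitted [cstfp] model is stored as a single JSON container holding, per
#' filter, the arrays `w`, `h`, `b`, the CSP bank, the eigenvalues, the
#' objective trace, and the configuration. Numbers are written at full
#' double precision so the round trip is exact.
#'
#' @param model A fitted [cstfp] model.
#' @param path File path for the JSON container.
#' @return `write_cstfp_model()` returns `path` invisibly;
#'   `read_cstfp_model()` returns the reconstructed [cstfp] model.
#' @export
write_cstfp_model <- function(model, path) {
  if (!inherits(model, "cstfp")) {
    abort("`model` must be a fitted cstfp model", class = "cstfp_validation")
  }
  payload <- list(
    format = "cstfp-model",
    version = 1L,
    config = model$config,
    filters = purrr::map(seq_along(model$w), function(i) {
      list(
        w = model$w[[i]],
        h = model$h[[i]],
        b = model$b[[i]],
        csp_bank = apply(model$csp_banks[[i]], 2, identity, simplify = FALSE),
        eigenvalues = model$eigenvalues[[i]],
        j_hat = model$j_hat[i],
        objective_trace = model$objective_trace[[i]],
        converged = model$converged[i],
        iterations = model$iterations[i]
      )
    })
  )
  # digits = I(17) emits significant digits, enough for exact double round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_cstfp_model
#' @export
read_cstfp_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path), class = "cstfp_model_io")
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) abort(sprintf("unreadable model file: %s", path),
                              class = "cstfp_model_io")
  )
  if (!identical(payload$format, "cstfp-model")) {
    abort("not a cstfp model container", class = "cstfp_model_io")
  }
  cfg <- payload$config
  cfg$loop_order <- as.character(cfg$loop_order)
  cfg$candidate_params <- as.list(cfg$candidate_params)
  if (!is.null(cfg$seed) && length(cfg$seed) == 0) cfg$seed <- NULL
  fl <- payload$filters
  structure(list(
    w = purrr::map(fl, ~ as.numeric(.x$w)),
    h = purrr::map(fl, ~ as.numeric(.x$h)),
    b = purrr::map(fl, ~ as.numeric(.x$b)),
    csp_banks = purrr::map(fl, ~ do.call(cbind, purrr::map(.x$csp_bank, as.numeric))),
    eigenvalues = purrr::map(fl, ~ as.numeric(.x$eigenvalues)),
    j_hat = purrr::map_dbl(fl, "j_hat"),
    objective_trace = purrr::map(fl, ~ as.numeric(.x$objective_trace)),
    converged = purrr::map_lgl(fl, "converged"),
    iterations = purrr::map_int(fl, ~ as.integer(.x$iterations)),
    config = cfg
  ), class = "cstfp")
}
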