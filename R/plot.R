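#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the spatio-time-frequency patterns of a fitted model
#'
#' Produces, per designed filter, one of three panels: the FIR magnitude
#' response over frequency (`"filters"`), the binary time window
#' (`"windows"`), or the spatial weight profile across channels
#' (`"weights"`).
#'
#' @param object A fitted [cstfp] model.
#' @param type Which pattern family to draw.
#' @param fs Sampling rate in Hz for the frequency axis.
#' @param ... Unused.
#' @return A ggplot object faceted by filter.
#' @method autoplot cstfp
#' @export
autoplot.cstfp <- function(object, type = c("filters", "windows", "weights"),
                           fs = 100, ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (type == "filters") {
    df <- purrr::map_dfr(seq_len(cfg$n_filters), function(i) {
      dplyr::mutate(fir_response(object$h[[i]], fs), filter = factor(i))
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~filter, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "frequency (Hz)", y = "|H(f)|",
                    title = "FIR magnitude responses")
  } else if (type == "windows") {
    df <- purrr::map_dfr(seq_len(cfg$n_filters), function(i) {
      tibble::tibble(filter = factor(i), sample = seq_len(cfg$K),
                     active = object$b[[i]])
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$active)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~filter, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "filtered sample index", y = "window",
                    title = "Binary time windows")
  } else {
    df <- purrr::map_dfr(seq_len(cfg$n_filters), function(i) {
      tibble::tibble(filter = factor(i), channel = seq_len(cfg$M),
                     weight = object$w[[i]])
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~filter, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "channel", y = "spatial weight",
                    title = "Spatial weight profiles")
  }
}

#' Plot cross-validation accuracies
#'
#' @param object A [cstfp_cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot boxplot of per-fold accuracy by repeat.
#' @method autoplot cstfp_cv
#' @export
autoplot.cstfp_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$repeat_),
                                       y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_accuracy"),
                        linetype = "dashed") +
    ggplot2::labs(x = "repeat", y = "held-out accuracy",
                  title = "Cross-validated decoding accuracy")
}

#' @importFrom rlang .data
NULL
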