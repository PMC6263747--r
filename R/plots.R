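#' Plot a signal frame
#'
#' Line plot of the three axes over time, faceted by activity label (first
#' user by default) — a quick visual check that periodic and static classes
#' look as intended.
#'
#' @param object A `signal_frame`.
#' @param users Users to include (default: the first).
#' @param max_seconds Truncate each facet to this many seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_frame <- function(object, users = NULL, max_seconds = 5, ...) {
  df <- tibble::as_tibble(object)
  users <- users %||% df$user_id[1]
  df <- df[df$user_id %in% users, ]
  df <- df |>
    dplyr::group_by(.data$activity) |>
    dplyr::filter(.data$timestamp - min(.data$timestamp) <= max_seconds) |>
    dplyr::mutate(t = .data$timestamp - min(.data$timestamp)) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(c("x", "y", "z")),
                        names_to = "axis", values_to = "acceleration")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$acceleration,
                                   colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~activity) +
    ggplot2::labs(x = "time (s)", y = "acceleration", colour = NULL)
}

#' Plot a cross-validation result
#'
#' Confusion-matrix heat map annotated with counts; the subtitle reports the
#' mean accuracy.
#'
#' @param object A `har_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.har_cv <- function(object, ...) {
  cm <- as.data.frame(object$confusion)
  names(cm) <- c("truth", "predicted", "n")
  ggplot2::ggplot(cm, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s / %s fusion", object$pipeline$classifier,
                      object$pipeline$fusion),
      subtitle = sprintf("%d-fold CV mean accuracy %.1f%%", object$k,
                         100 * object$mean_accuracy),
      x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
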