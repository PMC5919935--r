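#' Plot a mood trace with its ratings
#'
#' Theoretical mood level across trials, with observed ratings overlaid when
#' a trial table is supplied.
#'
#' @param object A `mood_trace` (from [compute_tml()]).
#' @param table Optional trial table providing `mood_rating`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mood_trace <- function(object, table = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$tml)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "trial", y = "theoretical mood level") +
    ggplot2::theme_minimal()
  if (!is.null(table) && "mood_rating" %in% names(table)) {
    rated <- table[!is.na(table$mood_rating), c("trial", "mood_rating")]
    p <- p + ggplot2::geom_point(
      data = rated,
      ggplot2::aes(x = .data$trial, y = .data$mood_rating),
      colour = "steelblue", size = 1.2)
  }
  p
}

#' Plot model-selection results
#'
#' Exceedance probability (bars) and expected frequency (points) per model.
#'
#' @param object A `bms_result`.
#' @param top Show only the `top` models by exceedance probability
#'   (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bms_result <- function(object, top = NULL, ...) {
  df <- tidy.bms_result(object)
  df <- df[order(-df$exceedance_probability), ]
  if (!is.null(top)) df <- utils::head(df, top)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$exceedance_probability),
                      fill = "grey35") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_frequency),
                        colour = "tomato", size = 1.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "exceedance probability (bars), expected frequency (points)") +
    ggplot2::theme_minimal()
}

#' Plot acceptance against a binned covariate
#'
#' Observed acceptance rate across covariate bins with the fitted model's
#' mean prediction, the standard diagnostic for choice-model fit.
#'
#' @param table Trial table with `choice`.
#' @param spec,params Fitted choice model.
#' @param covariate Per-trial covariate (defaults to the model's predicted
#'   utility difference via the acceptance probability itself).
#' @param n_bins Number of bins (default 6).
#' @return A ggplot object.
#' @export
plot_choice_fit <- function(table, spec, params, covariate = NULL,
                            n_bins = 6) {
  p <- accept_probability(table, spec, params)
  x <- covariate %||% p
  bins <- cut(x, breaks = stats::quantile(x, seq(0, 1, length.out = n_bins + 1)),
              include.lowest = TRUE, labels = FALSE)
  df <- tibble::tibble(bin = bins, choice = table$choice, p = p, x = x) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$x), observed = mean(.data$choice),
                     predicted = mean(.data$p), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::labs(x = "covariate (bin mean)", y = "acceptance rate") +
    ggplot2::theme_minimal()
}
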