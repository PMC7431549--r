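#' Plot a match's cumulative score trajectory
#'
#' The AI's cumulative competitive score (wins minus losses) against the
#' round index — the standard single-match diagnostic. The dominant model
#' can be overlaid as point colour to show when the ensemble switched.
#'
#' @param object A `rps_match`.
#' @param show_dominant Colour points by the dominant member's order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rps_match <- function(object, show_dominant = FALSE, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$t, y = .data$cum_score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "round", y = "cumulative AI score",
      title = sprintf("Multi-AI vs %s (%d rounds, final score %d)",
                      object$config$opponent, object$summary$rounds,
                      object$summary$ai_score)
    )
  if (show_dominant) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$dominant_order)), size = 0.8
    ) + ggplot2::labs(colour = "dominant AI")
  }
  p
}

#' Plot per-opponent total scores for a population run
#'
#' One bar per opponent showing the AI's final match score, the standard
#' cohort-level display.
#'
#' @param object A `rps_population`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rps_population <- function(object, ...) {
  s <- object$summaries
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$match), y = .data$ai_score,
                                  fill = .data$ai_score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(
      x = "opponent", y = "AI total score",
      title = sprintf("Multi-AI vs %d opponents: won %.0f%% of matches",
                      nrow(s), 100 * object$fraction_won)
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot standalone per-order model scores
#'
#' Distribution of total scores per model order from
#' [standalone_model_scores()], one box per order across seeds.
#'
#' @param scores A tibble with `order`, `seed`, `ai_score` columns.
#' @return A ggplot object.
#' @export
plot_model_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = factor(.data$order),
                                       y = .data$ai_score)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "Markov chain order m", y = "total score")
}
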