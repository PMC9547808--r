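#' Plot a ranked candidate table
#'
#' Horizontal bar chart of the top candidates by propagation score.
#'
#' @param object A `ranked_table`.
#' @param n Number of top candidates to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_table <- function(object, n = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$identifier, .data$score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "propagation score", y = NULL,
      title = sprintf("Top %s candidates", attr(object, "entity_type")),
      subtitle = sprintf("%d candidates screened",
                         attr(object, "n_candidates"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot propagation scores by layer and entity type
#'
#' Jittered strip plot of per-node scores (log scale) faceted by layer —
#' a quick view of where the walk mass settled.
#'
#' @param object A `score_vector` carrying a node index.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_vector <- function(object, ...) {
  d <- tidy(object)
  if (!"layer_name" %in% names(d)) {
    abort("This score vector carries no node index to plot")
  }
  d <- d[d$score > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$entity_type, y = .data$score, colour = .data$entity_type
  )) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$layer_name) +
    ggplot2::labs(x = NULL, y = "propagation score (log scale)",
                  title = "Score mass by layer and entity type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a planted-recovery report
#'
#' Histogram of the planted partner's rank across replicates.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  d <- object$replicates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$partner_rank)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(
      x = "planted partner rank", y = "replicates",
      title = "Planted-partner recovery",
      subtitle = sprintf(
        "rank-1 fraction %.2f over %d replicates (planted degree %d)",
        object$summary$fraction_rank1, object$summary$n_replicates,
        object$summary$planted_partner_degree
      )
    ) +
    ggplot2::theme_minimal()
}
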