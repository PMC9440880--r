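# ggplot2 views of the result objects; analysis tables stay the interface,
# these are quick-look figures

#' Boxplot view of influence by outcome and experience bin
#'
#' @param object,x An `influence_outcome` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot influence_outcome
#' @export
autoplot.influence_outcome <- function(object, ...) {
  s <- object$summary[object$summary$n > 0, ]
  ggplot2::ggplot(
    s,
    ggplot2::aes(
      x = .data$experience_bin, middle = .data$median,
      lower = .data$q1, upper = .data$q3,
      ymin = .data$q1, ymax = .data$q3, fill = .data$outcome
    )
  ) +
    ggplot2::geom_boxplot(stat = "identity", position = "dodge") +
    ggplot2::labs(
      x = "previous climbs", y = "influence (maximal simplicial dimension)",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.influence_outcome <- function(x, ...) print(autoplot(x, ...))

#' Histogram of influence fractions per outcome category
#'
#' @param object An `influence_outcome` result.
#' @return A ggplot of the per-category normalized influence distribution.
#' @export
plot_influence_histogram <- function(object) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(x = .data$influence, y = .data$fraction, fill = .data$outcome)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "influence (maximal simplicial dimension)",
      y = "fraction of category", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Outsider success against maximal dimension, per threshold
#'
#' @param object,x A `style_curves` result.
#' @param ... Ignored.
#' @return A ggplot with standard-error bars per dimension.
#' @method autoplot style_curves
#' @export
autoplot.style_curves <- function(object, ...) {
  ggplot2::ggplot(
    object$by_dimension,
    ggplot2::aes(x = .data$max_dimension, y = .data$mean_outsider_success)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_outsider_success - .data$se_outsider_success,
      ymax = .data$mean_outsider_success + .data$se_outsider_success
    ), colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tau), labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "maximal simplicial dimension", y = "outsider success rate"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.style_curves <- function(x, ...) print(autoplot(x, ...))

#' Feature centralities of success and no-success groups
#'
#' @param object,x A `centrality_comparison` result.
#' @param ... Ignored.
#' @return A ggplot ordered by increasing centrality difference.
#' @method autoplot centrality_comparison
#' @export
autoplot.centrality_comparison <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      c("mean_success", "mean_no_success"),
      names_to = "group", values_to = "centrality"
    ) |>
    dplyr::mutate(
      se = ifelse(.data$group == "mean_success",
        .data$se_success, .data$se_no_success
      ),
      feature = factor(.data$feature, levels = object$feature)
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$feature, y = .data$centrality, colour = .data$group)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$centrality - .data$se, ymax = .data$centrality + .data$se
    ), position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "mean eigenvector centrality", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Failure-ratio bars by experience bin and category
#'
#' @param ratios A [failure_ratio_analysis()] result.
#' @return A ggplot; the horizontal line at 1 marks no partner effect.
#' @export
plot_failure_ratios <- function(ratios) {
  ggplot2::ggplot(
    ratios[!is.na(ratios$ratio), ],
    ggplot2::aes(
      x = .data$experience_bin, y = .data$ratio, fill = .data$failure_category
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = "previous climbs",
      y = "failure rate with repeated partner / personal average",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
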