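#' Plot Shapley values with credible intervals
#'
#' One panel per requested covariate: per-individual posterior-mean Shapley
#' values with their credible intervals, individuals ordered by estimate. A
#' noise covariate should show intervals hugging zero.
#'
#' @param object A `shapley_result`.
#' @param covariates Covariates to show (default: all players).
#' @param component `"total"`, `"main"`, or `"interaction"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shapley_result <- function(object, covariates = NULL,
                                    component = "total", ...) {
  td <- tidy(object)
  td <- td[td$component == component, ]
  if (!is.null(covariates)) td <- td[td$covariate %in% covariates, ]
  td <- dplyr::group_by(td, .data$covariate)
  td <- dplyr::mutate(td, rank = rank(.data$estimate, ties.method = "first"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      size = 0.2
    ) +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::labs(x = "individual (ordered by Shapley value)",
                  y = "Shapley value")
}

#' Plot global Shapley importance scores
#'
#' Bars of `I_j` (mean absolute posterior-mean Shapley value), with the
#' main-effect and interaction components alongside.
#'
#' @param x A `shapley_result`.
#' @return A ggplot object.
#' @export
plot_importance <- function(x) {
  imp <- global_importance(x)
  long <- tidyr::pivot_longer(imp, -"covariate",
                              names_to = "component", values_to = "score")
  long$component <- factor(
    long$component,
    levels = c("importance", "importance_main", "importance_int"),
    labels = c("total", "main", "interaction")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$covariate, .data$score),
    y = .data$score, fill = .data$component
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean |Shapley value|", fill = NULL)
}

#' Plot the range of significance of an interacting pair
#'
#' Credible band for `beta_j + beta_jk x_k` across the grid of x_k values;
#' the range of significance is where the band excludes zero.
#'
#' @param fit A `bayint_fit`.
#' @inheritParams range_of_significance
#' @return A ggplot object.
#' @export
plot_range_of_significance <- function(fit, j, k, grid = NULL, level = 0.95) {
  rs <- range_of_significance(fit, j, k, grid = grid, level = level)
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$x_k, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "interacting covariate value",
                  y = "effect of a unit change")
}
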