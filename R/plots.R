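# ggplot2 displays for fitted models and recovery summaries.

#' Plot posterior class probabilities
#'
#' Stacked per-person posterior membership probabilities, persons ordered
#' by modal class and within class by the probability of that class.
#'
#' @param fit A mixture `irtree_fit`.
#' @return A ggplot object.
#' @export
plot_class_probabilities <- function(fit) {
  pz <- posterior_class_probabilities(fit)
  zh <- modal_assignment(fit)
  ord <- order(zh, -pz_matrix(pz)[cbind(seq_len(nrow(pz)), zh)])
  long <- tidyr::pivot_longer(pz[ord, ], -"person", names_to = "class",
                              values_to = "prob")
  long$class <- factor(long$class, levels = c("p_ers", "p_mrs", "p_2rs", "p_0rs"),
                       labels = CLASS_LABELS)
  long$rank <- rep(seq_len(nrow(pz)), each = 4)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$prob,
                                     fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "respondent (sorted by modal class)",
                  y = "posterior class probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class hit rates
#'
#' @param hits A tibble from [hit_rate()], optionally row-bound across
#'   conditions/replications (columns `label`, `hit_rate`, optionally
#'   `condition`).
#' @return A ggplot object.
#' @export
plot_hit_rates <- function(hits) {
  p <- ggplot2::ggplot(hits, ggplot2::aes(x = .data$label, y = .data$hit_rate)) +
    ggplot2::geom_col(position = "dodge", fill = "grey35") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "hit rate") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(hits)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot recovery of a parameter block
#'
#' Scatter of posterior means against generating values with the identity
#' line, faceted by parameter block.
#'
#' @param estimate,truth Aligned numeric vectors.
#' @param block Optional block labels for faceting.
#' @return A ggplot object.
#' @export
plot_recovery <- function(estimate, truth, block = NULL) {
  df <- tibble::tibble(estimate = estimate, truth = truth,
                       block = if (is.null(block)) "parameters" else block)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey55") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~block, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior mean") +
    ggplot2::theme_minimal()
}

#' Autoplot of a fitted IRTree model
#'
#' For mixture fits, the posterior class-probability display of
#' [plot_class_probabilities()]; for single-class fits, the posterior
#' means of the item parameters with 2-SD intervals.
#'
#' @param object An `irtree_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot irtree_fit
#' @export
autoplot.irtree_fit <- function(object, ...) {
  if (object$model == "mm") return(plot_class_probabilities(object))
  td <- object$summary
  td <- td[grep("^(alpha|beta|omega)", td$term), ]
  td$block <- sub("\\[.*", "", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$std.error,
      ymax = .data$estimate + 2 * .data$std.error), size = 0.2) +
    ggplot2::facet_wrap(~block, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior mean ± 2 SD") +
    ggplot2::theme_minimal()
}
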