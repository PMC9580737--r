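# broom-style verbs and ggplot2 autoplot methods for the result objects.

#' @export
tidy.roc_eval <- function(x, ...) x$points

#' @export
glance.roc_eval <- function(x, ...) {
  tibble(auc = x$auc, n_inflamed = x$n_pos, n_normal = x$n_neg,
         n_cutoffs = nrow(x$points))
}

#' @export
tidy.gram_eval <- function(x, ...) x$roc$points

#' @export
glance.gram_eval <- function(x, ...) {
  tibble(
    auc = x$roc$auc,
    youden_cutoff = x$youden$cutoff,
    youden_j = x$youden$youden_j,
    cutoff_used = x$cutoff$value,
    cutoff_source = x$cutoff_source,
    n_concordant = x$concordance$n_concordant,
    n_discordant = x$concordance$n_discordant,
    total = x$concordance$total,
    percent_concordance = x$concordance$percent
  )
}

#' @export
tidy.gram_lr <- function(x, ...) x$table

#' @export
glance.gram_lr <- function(x, ...) {
  tibble(n = x$n, separation = x$separation,
         n_dropped = length(x$dropped),
         deviance = x$fit$deviance, aic = x$fit$aic)
}

#' @export
tidy.gram_development <- function(x, ...) x$report

#' @export
glance.gram_development <- function(x, ...) {
  x$report |>
    filter(.data$level == x$recommendation_level,
           .data$matrix_id == x$recommended)
}

#' ROC curve plot for an evaluation
#'
#' @param object A `roc_eval` or `gram_eval` object.
#' @param ... Unused.
#' @return A ggplot: the ROC step curve in 1 - specificity vs sensitivity
#'   space with the chance diagonal; for `gram_eval` the Youden-optimal
#'   point is marked.
#' @export
autoplot.roc_eval <- function(object, ...) {
  pts <- object$points
  df <- tibble(
    fpr = c(0, 1 - pts$specificity, 1),
    tpr = c(0, pts$sensitivity, 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = df[-c(1, nrow(df)), , drop = FALSE],
                        size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gram_eval <- function(object, ...) {
  p <- autoplot(object$roc)
  y <- object$youden
  p +
    ggplot2::annotate("point", x = 1 - y$specificity, y = y$sensitivity,
                      colour = "red", size = 3, shape = 1) +
    ggplot2::annotate("text", x = 1 - y$specificity, y = y$sensitivity,
                      label = sprintf(" Y >= %g", y$cutoff),
                      hjust = 0, vjust = 1, colour = "red", size = 3)
}

#' AUC comparison plot for a development run
#'
#' @param object A `gram_development` object.
#' @param ... Unused.
#' @return A ggplot: AUC per candidate matrix and evaluation level, with
#'   the acceptable-predictive-ability reference line at 0.7.
#' @export
autoplot.gram_development <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$matrix_id, y = .data$auc,
                               colour = .data$level,
                               shape = .data$level)) +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey70") +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "ROC AUC",
                  title = "Candidate scoring matrices") +
    ggplot2::theme_minimal()
}
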