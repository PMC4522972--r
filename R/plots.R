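# ggplot2 autoplot methods for the package's result objects.

#' Plot a Kaplan-Meier curve
#'
#' Step curves per group with censoring tick marks.
#'
#' @param object A [kaplan_meier()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot km_curve
autoplot.km_curve <- function(object, ...) {
  tab <- object$table
  anchors <- dplyr::summarise(dplyr::group_by(tab, .data$group),
                              time = 0, survival = 1, .groups = "drop")
  steps <- dplyr::bind_rows(anchors, tab[c("group", "time", "survival")])
  cens <- tab[tab$n_censor > 0, ]
  p <- ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$survival,
                                           colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 2, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!object$grouped) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot an ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot roc_result
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.3f (p = %.3g)", object$auc,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a signature derivation
#'
#' Location difference (high minus low, log scale) against -log10 p, with
#' selected signature genes highlighted.
#'
#' @param object A [derive_signature()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot signature_fit
autoplot.signature_fit <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$fold, -log10(.data$p_value),
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                                 labels = c("not selected", "signature"),
                                 name = NULL) +
    ggplot2::labs(x = "Location difference (high - low, log scale)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Score distribution by protein group
#'
#' Convenience plot: signature scores stratified by proteomic group labels.
#'
#' @param scores Tibble `sample_id`, `score`.
#' @param labels Tibble `sample_id`, `label` (e.g. [quartile_groups()]).
#' @return A ggplot.
#' @export
plot_score_by_group <- function(scores, labels) {
  d <- dplyr::inner_join(scores, labels, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Signature score") +
    ggplot2::theme_minimal()
}
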