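#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.t1d_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot full and null ROC curves together
#'
#' @param object A [run_full_vs_null()] result.
#' @param ... Unused.
#' @return A ggplot overlaying the full (glycans + age + sex) and null
#'   (age + sex) out-of-fold ROC curves.
#' @export
autoplot.t1d_discrimination <- function(object, ...) {
  curves <- dplyr::bind_rows(
    dplyr::mutate(object$roc_full$curve,
                  model = sprintf("full (AUC %.3f)", object$roc_full$auc)),
    dplyr::mutate(object$roc_null$curve,
                  model = sprintf("null (AUC %.3f)", object$roc_null$auc)))
  ggplot2::ggplot(curves, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$model)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c("#2166ac", "grey30")) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  subtitle = sprintf("bootstrap p = %.2g", object$comparison$p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Forest plot of per-glycan odds ratios
#'
#' @param results A [disease_association()] tibble.
#' @param q_threshold Highlight glycans with `q` below this value.
#' @return A ggplot with ORs and 95% CIs on a log scale.
#' @export
plot_association_forest <- function(results, q_threshold = 0.05) {
  results <- dplyr::mutate(results,
    glycan = factor(.data$glycan, levels = rev(unique(.data$glycan))),
    significant = .data$q < q_threshold)
  ggplot2::ggplot(results, ggplot2::aes(x = .data$or, y = .data$glycan,
                                        colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "OR per SD of glycan (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated marginal means of a sex-by-age-group model
#'
#' @param object A [fit_sex_age_model()] result.
#' @param ... Unused.
#' @return A ggplot of cell means with 95% CIs per sex across age groups.
#' @export
autoplot.t1d_sexage_fit <- function(object, ...) {
  emm <- as_tibble(summary(object$emmeans))
  if (!"age_group" %in% names(emm)) emm$age_group <- "all"
  if (!"sex" %in% names(emm)) emm$sex <- "all"
  ggplot2::ggplot(emm, ggplot2::aes(x = .data$age_group, y = .data$emmean,
                                    colour = .data$sex,
                                    group = .data$sex)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower.CL,
                                        ymax = .data$upper.CL),
                           width = 0.15,
                           position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "Age group", y = "Glycan (SD units)", colour = "Sex") +
    ggplot2::theme_minimal()
}
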