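#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an integrity comparison
#'
#' One row per model term of the covariate-adjusted group regression.
#'
#' @param x An `integrity_comparison` from [compare_integrity()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy integrity_comparison
#' @export
tidy.integrity_comparison <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' Glance at an integrity comparison
#'
#' One row mirroring the layout of a published network-integrity table:
#' group means/SDs, the adjusted group t and p, and Cohen's d.
#'
#' @inheritParams tidy.integrity_comparison
#' @return A one-row tibble.
#' @method glance integrity_comparison
#' @export
glance.integrity_comparison <- function(x, ...) {
  tibble::tibble(
    network = x$network, method = x$method, MO = paste(x$MO, collapse = ","),
    mean_patient = x$mean_patient, sd_patient = x$sd_patient,
    mean_control = x$mean_control, sd_control = x$sd_control,
    n_patient = x$n_patient, n_control = x$n_control,
    statistic = x$t, p.value = x$p, cohens_d = x$d
  )
}

#' Tidy a classification result
#'
#' @param x A `classification_result` from [loocv_logistic_auc()].
#' @param ... Unused.
#' @return A tibble of per-subject held-out probabilities (`subject_id`,
#'   `truth`, `probability`).
#' @method tidy classification_result
#' @export
tidy.classification_result <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    truth = x$truth,
    probability = x$probability
  )
}

#' Glance at a classification result
#'
#' @inheritParams tidy.classification_result
#' @return A one-row tibble with `network`, `method`, `MO`, `auc`, `n`.
#' @method glance classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(
    network = x$network, method = x$method, MO = paste(x$MO, collapse = ","),
    auc = x$auc, n = length(x$truth)
  )
}

#' Plot an ROC curve
#'
#' @param object A `classification_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classification_result
#' @export
autoplot.classification_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s (%s), LOOCV AUC = %.2f",
                      object$network, object$method, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group integrity distributions
#'
#' Boxplots of the unadjusted integrity values by group, annotated with the
#' effect size, for one comparison.
#'
#' @param object An `integrity_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot integrity_comparison
#' @export
autoplot.integrity_comparison <- function(object, ...) {
  df <- object$fit$model
  df$group <- factor(ifelse(df$group_patient == 1, "patient", "control"),
                     levels = c("control", "patient"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$z)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(
      x = NULL, y = "network integrity (Fisher-Z)",
      title = sprintf("%s (%s): d = %.2f, p = %.3g",
                      object$network, object$method, object$d, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot integrity across a model-order sweep
#'
#' Effect size per network, method and model order, from a pipeline report's
#' comparison table.
#'
#' @param comparisons Tibble of glanced comparisons (as in
#'   `run_pipeline()$comparisons`).
#' @return A ggplot object.
#' @export
plot_mo_sweep <- function(comparisons) {
  ggplot2::ggplot(
    comparisons,
    ggplot2::aes(x = .data$MO, y = .data$cohens_d,
                 colour = .data$network, group = .data$network)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "model order", y = "Cohen's d") +
    ggplot2::theme_minimal()
}
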