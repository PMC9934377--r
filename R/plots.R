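#' Plot the strongest partial risk scores of a fitted model
#'
#' Lollipop chart of the `top_n` features by absolute partial risk score;
#' adverse factors point right, protective factors left.
#'
#' @param object A [fit_prs()] model.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prs_model
#' @export
autoplot.prs_model <- function(object, top_n = 20, ...) {
  df <- object$features |>
    dplyr::arrange(dplyr::desc(abs(.data$prs))) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(label = stats::reorder(.data$feature_id, .data$prs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prs, y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$prs,
                                       yend = .data$label),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$prs > 0), size = 2,
                        show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "partial risk score (log odds ratio)", y = NULL)
}

#' Plot a ROC curve
#'
#' @param object A [roc_points()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_points
#' @export
autoplot.roc_points <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

#' Plot validation AUC per training arm
#'
#' @param object A [run_three_arm_comparison()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot three_arm_comparison
#' @export
autoplot.three_arm_comparison <- function(object, ...) {
  ggplot2::ggplot(object$arms,
                  ggplot2::aes(x = .data$arm, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "training set", y = "validation AUC") +
    ggplot2::ylim(0, 1)
}

#' Plot cumulative risk trajectories
#'
#' Step plot of `risk_t` over time for the selected patients, with optional
#' horizontal lines at the calibrated cutoffs.
#'
#' @param trajectories Output of [build_trajectories()].
#' @param patients Patient ids to show (default: up to 12).
#' @param thresholds Optional [select_thresholds()] set.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, patients = NULL,
                              thresholds = NULL) {
  if (is.null(patients)) {
    patients <- utils::head(unique(trajectories$patient_id), 12)
  }
  df <- dplyr::filter(trajectories, .data$patient_id %in% patients)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$risk_t,
                                        group = .data$patient_id,
                                        colour = .data$patient_id)) +
    ggplot2::geom_step(show.legend = length(patients) <= 12) +
    ggplot2::labs(x = NULL, y = "cumulative risk score")
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(data = tibble::as_tibble(thresholds),
                                 ggplot2::aes(yintercept = .data$cutoff),
                                 linetype = 2, colour = "black")
  }
  p
}
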