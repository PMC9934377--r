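#' Odds ratio from a 2x2 prevalence table
#'
#' Computes `OR = (cases_with / cases_without) / (controls_with /
#' controls_without)`. When any of the four cells is zero the
#' Haldane--Anscombe correction adds 0.5 to all four cells (and the row is
#' flagged `smoothed`), keeping every log odds ratio finite. All arguments
#' are vectorized.
#'
#' @param cases_with,cases_without,controls_with,controls_without
#'   Nonnegative patient counts.
#' @return A tibble with the input counts plus `or`, `log_or`, `smoothed`.
#' @export
#' @examples
#' odds_ratio(11, 95, 123, 14797)$or # 13.93
odds_ratio <- function(cases_with, cases_without, controls_with,
                       controls_without) {
  a <- as.numeric(cases_with); b <- as.numeric(cases_without)
  c <- as.numeric(controls_with); d <- as.numeric(controls_without)
  stopifnot(all(c(a, b, c, d) >= 0))
  if (any(a + b == 0 & c + d == 0)) {
    stop("odds_ratio undefined: a table has zero cases and zero controls")
  }
  smoothed <- a == 0 | b == 0 | c == 0 | d == 0
  h <- 0.5 * smoothed
  or <- ((a + h) / (b + h)) / ((c + h) / (d + h))
  tibble::tibble(
    cases_with = cases_with, cases_without = cases_without,
    controls_with = controls_with, controls_without = controls_without,
    or = or, log_or = log(or), smoothed = smoothed
  )
}

#' Fit partial risk scores on the training arm
#'
#' For every vocabulary feature, counts the training patients carrying it
#' among cases and controls and sets the partial risk score (PRS) to the
#' natural-log odds ratio of those patient counts. Positive scores mark
#' adverse factors, negative scores protective ones. Counts are of patients
#' ever coded, never of events.
#'
#' @param features Training-arm output of [extract_features()].
#' @param labels Label tibble covering every training patient (defines
#'   `is_case`; patients with no features still count in the denominators).
#' @param vocabulary Vocabulary from [build_vocabulary()].
#' @return A `prs_model` object: use [tidy()] for the per-feature table
#'   (counts, `or`, `prs`, `smoothed`) and [glance()] for model-level
#'   summaries.
#' @export
fit_prs <- function(features, labels, vocabulary) {
  train <- dplyr::select(labels, "patient_id", "is_case")
  n_cases <- sum(train$is_case)
  n_controls <- sum(!train$is_case)
  if (n_cases == 0) stop("training arm has no cases")
  if (n_controls == 0) stop("training arm has no controls")

  counts <- features |>
    dplyr::filter(.data$in_vocab) |>
    dplyr::distinct(.data$patient_id, .data$feature_id) |>
    dplyr::inner_join(train, by = "patient_id") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(cases_with = sum(.data$is_case),
                     controls_with = sum(!.data$is_case), .groups = "drop")

  tab <- vocabulary |>
    dplyr::left_join(counts, by = "feature_id") |>
    dplyr::mutate(
      cases_with = dplyr::coalesce(.data$cases_with, 0L),
      controls_with = dplyr::coalesce(.data$controls_with, 0L),
      cases_without = n_cases - .data$cases_with,
      controls_without = n_controls - .data$controls_with
    )
  ors <- odds_ratio(tab$cases_with, tab$cases_without, tab$controls_with,
                    tab$controls_without)
  tab <- dplyr::bind_cols(
    dplyr::select(tab, "feature_id", "code_type", "code", "value_flag"),
    dplyr::select(ors, "cases_with", "cases_without", "controls_with",
                  "controls_without", "or", "smoothed")
  )
  tab$prs <- log(tab$or)

  structure(
    list(features = tab, n_cases = n_cases, n_controls = n_controls),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat("<prs_model>", nrow(x$features), "features fit on", x$n_cases,
      "cases /", x$n_controls, "controls\n")
  cat("  PRS range:", paste(signif(range(x$features$prs), 3),
                            collapse = " .. "),
      "|", sum(x$features$smoothed), "smoothed\n")
  invisible(x)
}

#' @rdname fit_prs
#' @param x A `prs_model`.
#' @param ... Unused.
#' @method tidy prs_model
#' @export
tidy.prs_model <- function(x, ...) x$features

#' @rdname fit_prs
#' @method glance prs_model
#' @export
glance.prs_model <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$features),
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    n_smoothed = sum(x$features$smoothed),
    n_protective = sum(x$features$prs < 0)
  )
}

#' Total risk score of each patient under a fitted model
#'
#' Sums the partial risk scores of the distinct model features a patient
#' carries; features outside the model contribute 0, and repeat codings
#' contribute nothing beyond the first.
#'
#' @param features Output of [extract_features()].
#' @param model A [fit_prs()] model.
#' @param patients Optional character vector of patient ids that must appear
#'   in the output even with empty records (score 0).
#' @return A tibble `patient_id`, `score`.
#' @export
total_score <- function(features, model, patients = NULL) {
  scores <- features |>
    dplyr::distinct(.data$patient_id, .data$feature_id) |>
    dplyr::inner_join(dplyr::select(model$features, "feature_id", "prs"),
                      by = "feature_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(score = sum(.data$prs), .groups = "drop")
  complete_patients(scores, features, patients, fill = list(score = 0))
}

complete_patients <- function(out, features, patients, fill) {
  universe <- unique(c(features$patient_id, patients))
  missing <- setdiff(universe, out$patient_id)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(patient_id = missing, !!!fill))
  }
  dplyr::arrange(out, .data$patient_id)
}

#' Calibrate classification thresholds at benchmark specificities
#'
#' For each specificity target, the cutoff is the smallest observed training
#' control score `s` such that the fraction of control scores strictly above
#' `s` is at most `1 - target`. Classifying positive when a score is
#' strictly greater than the cutoff then achieves a training specificity of
#' at least the target even in the presence of ties, and the achieved
#' specificity never overshoots by more than one control.
#'
#' @param control_scores Numeric scores of the training-arm controls (at
#'   least 20).
#' @param specificity_targets Targets in (0, 1], default 90% and 95%.
#' @return A tibble `target`, `cutoff`, `achieved_specificity` (on the
#'   training controls), with class `threshold_set`.
#' @export
select_thresholds <- function(control_scores,
                              specificity_targets = c(0.90, 0.95)) {
  stopifnot(all(specificity_targets > 0 & specificity_targets <= 1))
  n <- length(control_scores)
  if (n < 20) stop("need at least 20 control scores to calibrate thresholds")
  s <- sort(control_scores)
  u <- unique(s)
  n_at_or_below <- findInterval(u, s)
  out <- purrr::map_dfr(sort(specificity_targets), function(target) {
    # fraction above <= 1 - target, i.e. count at-or-below >= n * target;
    # the epsilon guards the comparison against floating-point slop
    need <- ceiling(n * target - 1e-9)
    k <- which(n_at_or_below >= need)[1]
    tibble::tibble(target = target, cutoff = u[k],
                   achieved_specificity = n_at_or_below[k] / n)
  })
  class(out) <- c("threshold_set", class(out))
  out
}

#' Z-scale a vector of odds ratios
#'
#' Expresses each odds ratio as the number of standard deviations (sample
#' SD) from the mean of the supplied set. The caller chooses the feature set
#' over which to scale; scaling is relative to that set by construction.
#'
#' @param or Numeric vector, length at least 2, nonconstant.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
z_scale_ors <- function(or) {
  stopifnot(is.numeric(or), length(or) >= 2)
  s <- sd(or)
  if (!is.finite(s) || s == 0) stop("cannot Z-scale a constant vector")
  (or - mean(or)) / s
}
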