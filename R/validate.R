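#' Cumulative risk trajectories under simulated-prospective replay
#'
#' Replays each patient's record in chronological order: every distinct
#' variable contributes its partial risk score once, at its first
#' occurrence; variables sharing a date are aggregated before the day's
#' cumulative score `risk_t` is emitted, so trajectories are invariant to
#' within-day event order. Features outside the model are logged at score 0.
#' The final `risk_t` equals [total_score()] of the full record.
#'
#' @param features Output of [extract_features()] (case records must have
#'   been censored upstream).
#' @param model A [fit_prs()] model.
#' @return A tibble `patient_id`, `date`, `risk_t` with strictly increasing
#'   dates within patient.
#' @export
build_trajectories <- function(features, model) {
  features |>
    dplyr::distinct(.data$patient_id, .data$feature_id,
                    .data$first_date) |>
    dplyr::left_join(dplyr::select(model$features, "feature_id", "prs"),
                     by = "feature_id") |>
    dplyr::mutate(prs = dplyr::coalesce(.data$prs, 0)) |>
    # a feature's PRS is credited once, at its earliest date; later repeats
    # still emit a (zero-increment) trajectory point
    dplyr::group_by(.data$patient_id, .data$feature_id) |>
    dplyr::mutate(prs = .data$prs *
                    (.data$first_date == min(.data$first_date))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$patient_id, date = .data$first_date) |>
    dplyr::summarise(day_score = sum(.data$prs), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(risk_t = cumsum(.data$day_score)) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "date", "risk_t")
}

#' Overall risk score: the running maximum of a trajectory
#'
#' The overall risk score (ORS) of a patient is the maximum cumulative score
#' reached at any point of their trajectory. Patients with empty records
#' receive ORS 0 and are flagged.
#'
#' @param trajectories Output of [build_trajectories()].
#' @param patients Optional ids to force into the output (empty records).
#' @return A tibble `patient_id`, `ors`, `empty_record`.
#' @export
overall_risk_scores <- function(trajectories, patients = NULL) {
  out <- trajectories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ors = max(.data$risk_t), .groups = "drop") |>
    dplyr::mutate(empty_record = FALSE)
  universe <- unique(c(trajectories$patient_id, patients))
  missing <- setdiff(universe, out$patient_id)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(patient_id = missing, ors = 0,
                          empty_record = TRUE))
  }
  dplyr::arrange(out, .data$patient_id)
}

#' Earliest date a trajectory exceeds each threshold
#'
#' @param trajectories Output of [build_trajectories()].
#' @param thresholds A [select_thresholds()] set.
#' @return A tibble `patient_id`, `target`, `cutoff`,
#'   `first_crossing_date` (`NA` when the trajectory never exceeds the
#'   cutoff).
#' @export
first_crossings <- function(trajectories, thresholds) {
  ids <- unique(trajectories$patient_id)
  purrr::map_dfr(seq_len(nrow(thresholds)), function(i) {
    cross <- trajectories |>
      dplyr::filter(.data$risk_t > thresholds$cutoff[i]) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_crossing_date = min_typed(.data$date),
                       .groups = "drop")
    tibble::tibble(patient_id = ids) |>
      dplyr::left_join(cross, by = "patient_id") |>
      dplyr::mutate(target = thresholds$target[i],
                    cutoff = thresholds$cutoff[i]) |>
      dplyr::select("patient_id", "target", "cutoff", "first_crossing_date")
  })
}

#' Classify overall risk scores against calibrated thresholds
#'
#' A patient is positive at a threshold when their ORS is strictly greater
#' than the cutoff (a score exactly at the cutoff is negative, matching the
#' calibration rule of [select_thresholds()]).
#'
#' @param scores Tibble with `patient_id`, `ors` (see
#'   [overall_risk_scores()]).
#' @param thresholds A [select_thresholds()] set.
#' @return A tibble `patient_id`, `target`, `cutoff`, `positive`.
#' @export
classify_scores <- function(scores, thresholds) {
  tidyr::crossing(
    dplyr::select(scores, "patient_id", "ors"),
    dplyr::select(tibble::as_tibble(thresholds), "target", "cutoff")
  ) |>
    dplyr::mutate(positive = .data$ors > .data$cutoff) |>
    dplyr::select("patient_id", "target", "cutoff", "positive")
}

#' Derived metrics from confusion counts
#'
#' Computes sensitivity, specificity, PPV, NPV and likelihood ratios, each
#' in an exact form and in a rounded-percent form in which sensitivity and
#' specificity are first rounded to integer percents and the likelihood
#' ratios recomputed from the rounded values (the arithmetic used in printed
#' clinical summary tables). Undefined ratios (e.g. PPV with no positives)
#' are `NA`; LR+ at specificity 1 is `Inf`.
#'
#' @param tp,tn,fp,fn Confusion counts (vectorized).
#' @return A tibble of counts plus exact and rounded metric columns.
#' @export
#' @examples
#' confusion_metrics(19, 6757, 751, 33)[, c("sens_pct", "lr_pos_rounded")]
confusion_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  sens_pct <- round(100 * sens)
  spec_pct <- round(100 * spec)
  rsens <- sens_pct / 100
  rspec <- spec_pct / 100
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sens, specificity = spec,
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
    lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec,
    sens_pct = sens_pct, spec_pct = spec_pct,
    ppv_pct = round(100 * div(tp, tp + fp)),
    npv_pct = round(100 * div(tn, tn + fn)),
    lr_pos_rounded = round(rsens / (1 - rspec), 2),
    lr_neg_rounded = round((1 - rsens) / rspec, 2)
  )
}

#' Metric panel at calibrated thresholds
#'
#' Builds the per-threshold confusion counts and derived metrics for a set
#' of scored patients with known outcomes, and attaches the global AUC.
#'
#' @param scores Tibble `patient_id`, `ors`.
#' @param labels Label tibble giving `is_case` for every scored patient.
#' @param thresholds A [select_thresholds()] set.
#' @return A `metric_panel` tibble: one row per threshold with `target`,
#'   `cutoff`, counts and metrics; the AUC is in attribute `"auc"` (see
#'   [glance()]).
#' @export
metric_panel <- function(scores, labels, thresholds) {
  scored <- dplyr::inner_join(
    scores, dplyr::select(labels, "patient_id", "is_case"),
    by = "patient_id")
  stopifnot(nrow(scored) == nrow(scores))
  counts <- classify_scores(scored, thresholds) |>
    dplyr::inner_join(dplyr::select(scored, "patient_id", "is_case"),
                      by = "patient_id") |>
    dplyr::group_by(.data$target, .data$cutoff) |>
    dplyr::summarise(
      tp = sum(.data$positive & .data$is_case),
      tn = sum(!.data$positive & !.data$is_case),
      fp = sum(.data$positive & !.data$is_case),
      fn = sum(!.data$positive & .data$is_case),
      .groups = "drop")
  out <- dplyr::bind_cols(
    dplyr::select(counts, "target", "cutoff"),
    confusion_metrics(counts$tp, counts$tn, counts$fp, counts$fn))
  attr(out, "auc") <- roc_auc(scored$ors, scored$is_case)
  class(out) <- c("metric_panel", class(out))
  out
}

#' @rdname metric_panel
#' @param x A `metric_panel`.
#' @param ... Unused.
#' @method glance metric_panel
#' @export
glance.metric_panel <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"),
                 n_cases = x$tp[1] + x$fn[1],
                 n_controls = x$tn[1] + x$fp[1])
}

#' Area under the ROC curve (Mann--Whitney form)
#'
#' `AUC = P(score_case > score_control) + 0.5 P(tie)` over all case-control
#' pairs, computed from midranks so it agrees exactly with pairwise
#' enumeration.
#'
#' @param scores Numeric scores.
#' @param is_case Logical outcome per score.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, is_case) {
  stopifnot(length(scores) == length(is_case), !anyNA(scores),
            !anyNA(is_case))
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc needs at least one case and one control")
  }
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs at every distinct score cutoff (positive
#' iff score strictly greater), suitable for plotting or export.
#'
#' @inheritParams roc_auc
#' @return A `roc_points` tibble `fpr`, `tpr`, `threshold`, anchored at
#'   (0,0) and (1,1); plot with [autoplot()].
#' @export
roc_points <- function(scores, is_case) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  tpr <- vapply(cuts, function(s) sum(scores[is_case] > s), numeric(1)) / n1
  fpr <- vapply(cuts, function(s) sum(scores[!is_case] > s), numeric(1)) / n0
  out <- tibble::tibble(
    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
    threshold = c(Inf, cuts, -Inf))
  class(out) <- c("roc_points", class(out))
  out
}

#' Lead time between first threshold crossing and the case-defining event
#'
#' Among the cases detected at each threshold (trajectory exceeded the
#' cutoff), measures the interval from the first crossing to the first
#' case-defining event, in years of 365.25 days, with a normal-approximation
#' 95% confidence interval of the mean. Crossings use only pre-event data
#' (the record is censored), so every lead time is positive.
#'
#' @param trajectories Output of [build_trajectories()] for the test arm.
#' @param labels Label tibble with `is_case` and `first_event_date`.
#' @param thresholds A [select_thresholds()] set.
#' @return A tibble per threshold: `target`, `cutoff`, `n_cases`,
#'   `n_detected`, `mean_lead_years`, `sd_lead_years`, `ci_low`, `ci_high`.
#' @export
lead_times <- function(trajectories, labels, thresholds) {
  cases <- dplyr::filter(labels, .data$is_case)
  first_crossings(
    dplyr::semi_join(trajectories, cases, by = "patient_id"), thresholds) |>
    dplyr::inner_join(
      dplyr::select(cases, "patient_id", "first_event_date"),
      by = "patient_id") |>
    dplyr::mutate(lead_years = as.numeric(
      .data$first_event_date - .data$first_crossing_date) / 365.25) |>
    dplyr::group_by(.data$target, .data$cutoff) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      n_detected = sum(!is.na(.data$lead_years)),
      mean_lead_years = mean(.data$lead_years, na.rm = TRUE),
      sd_lead_years = sd(.data$lead_years, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      se = .data$sd_lead_years / sqrt(.data$n_detected),
      ci_low = .data$mean_lead_years - qnorm(0.975) * .data$se,
      ci_high = .data$mean_lead_years + qnorm(0.975) * .data$se
    ) |>
    dplyr::select(-"se")
}

#' Export a metric panel as TSV
#'
#' Columns mirror the printed summary-table layout: Spec, Sens, PPV, NPV,
#' TP, TN, FP, FN, LR+, LR- (rounded-percent variants).
#'
#' @param panel A [metric_panel()].
#' @param path File path.
#' @export
write_metric_panel <- function(panel, path) {
  out <- tibble::tibble(
    Spec = sprintf("%d%%", panel$spec_pct),
    Sens = sprintf("%d%%", panel$sens_pct),
    PPV = sprintf("%d%%", panel$ppv_pct),
    NPV = sprintf("%d%%", panel$npv_pct),
    TP = panel$tp, TN = panel$tn, FP = panel$fp, FN = panel$fn,
    `LR+` = sprintf("%.2f", panel$lr_pos_rounded),
    `LR-` = sprintf("%.2f", panel$lr_neg_rounded)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export per-patient trajectories and ROC points
#'
#' @param trajectories Output of [build_trajectories()].
#' @param points Output of [roc_points()].
#' @param path File path (CSV).
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(
    dplyr::select(trajectories, "patient_id", "date", risk_t = "risk_t"),
    path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
write_roc_points <- function(points, path) {
  readr::write_csv(tibble::as_tibble(points), path)
  invisible(path)
}
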