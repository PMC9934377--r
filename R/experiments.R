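#' Three-arm comparison: subpopulation-trained vs general-trained models
#'
#' Evaluates three models on one fixed validation set drawn from the marked
#' subpopulation: arm `subpop` trains on the subpopulation's training half;
#' arm `general_sampled` trains on a uniform random sample of the general
#' cohort of exactly the same size (never containing validation patients);
#' arm `general_all` trains on the entire general cohort minus the
#' validation patients. All three pipelines are otherwise identical:
#' vocabulary and partial risk scores fit on the arm's training patients
#' only, thresholds calibrated on the arm's training controls' overall risk
#' scores, and evaluation by simulated-prospective replay of the validation
#' patients.
#'
#' @param events Uncensored event table of the full general cohort (must
#'   contain the subpopulation, identified by a non-missing
#'   `first_marker_date` in `labels`).
#' @param demographics Demographics for the full cohort.
#' @param labels Final label tibble (after [apply_inclusion()] and
#'   [apply_case_exclusions()]).
#' @param split_seed Seed for the subpopulation train/validation split and
#'   the arm-B sample.
#' @param specificity_targets Benchmark specificities for the panels.
#' @param min_count Vocabulary floor, as in [build_vocabulary()].
#' @param exclude_all_subpop_from_b If `TRUE`, the size-matched general
#'   sample contains no subpopulation patients at all; by default it simply
#'   excludes the validation patients, so subpopulation training patients
#'   may enter at their natural population rate.
#' @return A `three_arm_comparison` object; [tidy()] gives one row per arm
#'   (`arm`, `n_train`, `n_train_cases`, `auc`), `$panels` holds the
#'   per-arm [metric_panel()]s, `$validation_ids` the shared validation set.
#' @export
run_three_arm_comparison <- function(events, demographics, labels,
                                     split_seed = 1L,
                                     specificity_targets = c(0.90, 0.95),
                                     min_count = 5,
                                     exclude_all_subpop_from_b = FALSE) {
  labels <- dplyr::mutate(labels,
                          is_subpop = !is.na(.data$first_marker_date))
  included <- dplyr::filter(labels, .data$included)
  sub <- dplyr::filter(included, .data$is_subpop)
  if (nrow(sub) < 4) stop("subpopulation too small to split")

  split <- split_train_test(sub, split_seed = split_seed)
  train_a <- split$patient_id[split$arm == "train"]
  val_ids <- split$patient_id[split$arm == "test"]

  pool_b <- if (exclude_all_subpop_from_b) {
    dplyr::filter(included, !.data$is_subpop)$patient_id
  } else {
    setdiff(included$patient_id, val_ids)
  }
  if (length(pool_b) < length(train_a)) {
    stop("general cohort too small for a size-matched sample of ",
         length(train_a))
  }
  train_b <- withr::with_seed(split_seed,
                              sample(pool_b, length(train_a)))
  train_c <- setdiff(included$patient_id, val_ids)

  censored <- censor_case_records(events, labels)
  arms <- list(subpop = train_a, general_sampled = train_b,
               general_all = train_c)
  fits <- purrr::imap(arms, function(ids, arm) {
    evaluate_model_arm(censored, demographics, labels, train_ids = ids,
                       val_ids = val_ids,
                       specificity_targets = specificity_targets,
                       min_count = min_count)
  })

  structure(
    list(
      arms = purrr::imap_dfr(fits, function(f, arm) {
        tibble::tibble(arm = arm, n_train = f$n_train,
                       n_train_cases = f$n_train_cases, auc = f$auc)
      }),
      panels = purrr::map(fits, "panel"),
      models = purrr::map(fits, "model"),
      validation_ids = sort(val_ids)
    ),
    class = "three_arm_comparison"
  )
}

# Fit on train_ids, calibrate on training controls, evaluate prospectively
# on val_ids. Events must already be censored.
evaluate_model_arm <- function(censored_events, demographics, labels,
                               train_ids, val_ids, specificity_targets,
                               min_count) {
  train_labels <- dplyr::filter(labels, .data$patient_id %in% train_ids)
  train_events <- dplyr::filter(censored_events,
                                .data$patient_id %in% train_ids)
  demo <- tibble::as_tibble(demographics)
  train_demo <- dplyr::filter(demo, .data$patient_id %in% train_ids)

  vocab <- build_vocabulary(train_events, train_demo, min_count = min_count)
  train_feats <- extract_features(train_events, train_demo, vocab)
  model <- fit_prs(train_feats, train_labels, vocab)

  train_traj <- build_trajectories(train_feats, model)
  control_ids <- train_labels$patient_id[!train_labels$is_case]
  train_ors <- overall_risk_scores(train_traj, patients = train_ids)
  thresholds <- select_thresholds(
    train_ors$ors[train_ors$patient_id %in% control_ids],
    specificity_targets)

  val_events <- dplyr::filter(censored_events,
                              .data$patient_id %in% val_ids)
  val_feats <- extract_features(
    val_events, dplyr::filter(demo, .data$patient_id %in% val_ids), vocab)
  val_traj <- build_trajectories(val_feats, model)
  val_ors <- overall_risk_scores(val_traj, patients = val_ids)
  panel <- metric_panel(val_ors,
                        dplyr::filter(labels, .data$patient_id %in% val_ids),
                        thresholds)

  list(model = model, thresholds = thresholds, panel = panel,
       auc = attr(panel, "auc"), n_train = length(train_ids),
       n_train_cases = sum(train_labels$is_case))
}

#' @export
print.three_arm_comparison <- function(x, ...) {
  cat("<three_arm_comparison> validation n =", length(x$validation_ids),
      "\n")
  print(x$arms)
  invisible(x)
}

#' @rdname run_three_arm_comparison
#' @param x A `three_arm_comparison`.
#' @param ... Unused.
#' @method tidy three_arm_comparison
#' @export
tidy.three_arm_comparison <- function(x, ...) x$arms

#' Dual-cohort odds-ratio table with per-cohort Z-scaling
#'
#' Compares feature odds ratios between two cohorts (e.g. a marked
#' subpopulation and the general population). Odds ratios are computed per
#' cohort from ever-coded patient counts, optionally after mapping codes to
#' broader groups (a patient carries a group if they carry any member code),
#' and each cohort's odds ratios are Z-scaled over the common feature set so
#' the two columns are comparable despite cohort-size-driven differences in
#' raw magnitude.
#'
#' @param features_a,features_b [extract_features()] output per cohort.
#' @param labels_a,labels_b Matching label tibbles (define `is_case`).
#' @param code_group_map Optional tibble `code`, `group` mapping codes to
#'   grouped features before counting.
#' @param cohort_names Length-2 names for the output columns.
#' @param include_p Add a two-sided two-proportion test comparing the
#'   feature's case rate between cohorts (carriers only).
#' @return A tibble with one row per feature present in both cohorts:
#'   counts, `or`, and `z` per cohort (suffixance by cohort name), sorted by
#'   the first cohort's odds ratio.
#' @export
dual_cohort_or_table <- function(features_a, labels_a, features_b, labels_b,
                                 code_group_map = NULL,
                                 cohort_names = c("subpop", "general"),
                                 include_p = FALSE) {
  tab_a <- cohort_feature_ors(features_a, labels_a, code_group_map)
  tab_b <- cohort_feature_ors(features_b, labels_b, code_group_map)
  joined <- dplyr::inner_join(tab_a, tab_b, by = "feature_id",
                              suffix = paste0("_", cohort_names))
  if (nrow(joined) >= 2) {
    or_a <- joined[[paste0("or_", cohort_names[1])]]
    or_b <- joined[[paste0("or_", cohort_names[2])]]
    if (sd(or_a) > 0) joined[[paste0("z_", cohort_names[1])]] <-
      z_scale_ors(or_a)
    if (sd(or_b) > 0) joined[[paste0("z_", cohort_names[2])]] <-
      z_scale_ors(or_b)
  }
  if (include_p) {
    joined$p_value <- purrr::pmap_dbl(
      list(joined[[paste0("cases_with_", cohort_names[1])]],
           joined[[paste0("controls_with_", cohort_names[1])]],
           joined[[paste0("cases_with_", cohort_names[2])]],
           joined[[paste0("controls_with_", cohort_names[2])]]),
      function(a1, c1, a2, c2) {
        if (a1 + c1 == 0 || a2 + c2 == 0) return(NA_real_)
        suppressWarnings(
          stats::prop.test(c(a1, a2), c(a1 + c1, a2 + c2))$p.value)
      })
  }
  dplyr::arrange(joined, dplyr::desc(
    joined[[paste0("or_", cohort_names[1])]]))
}

cohort_feature_ors <- function(features, labels, code_group_map = NULL) {
  feats <- dplyr::filter(features, .data$in_vocab)
  if (!is.null(code_group_map)) {
    feats <- feats |>
      dplyr::inner_join(tibble::as_tibble(code_group_map), by = "code") |>
      dplyr::mutate(feature_id = .data$group)
  }
  train <- dplyr::select(labels, "patient_id", "is_case")
  n_cases <- sum(train$is_case)
  n_controls <- sum(!train$is_case)
  counts <- feats |>
    dplyr::distinct(.data$patient_id, .data$feature_id) |>
    dplyr::inner_join(train, by = "patient_id") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(cases_with = sum(.data$is_case),
                     controls_with = sum(!.data$is_case), .groups = "drop")
  ors <- odds_ratio(counts$cases_with, n_cases - counts$cases_with,
                    counts$controls_with, n_controls - counts$controls_with)
  dplyr::bind_cols(
    dplyr::select(counts, "feature_id"),
    dplyr::select(ors, "cases_with", "controls_with", "or", "smoothed"))
}
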