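# First-occurrence long table of every codable feature a patient carries.
# Coded features are keyed (code_type, code, value_flag); demographic
# categories are keyed (DEMO, field, category) and dated at the patient's
# first visit, since the prospective replay needs a date for every scored
# variable. Age enters as a per-decade bucket at first visit.
patient_feature_dates <- function(events, demographics) {
  events <- tibble::as_tibble(events)
  coded <- events |>
    dplyr::group_by(.data$patient_id, .data$code_type, .data$code,
                    .data$value_flag) |>
    dplyr::summarise(first_date = min_typed(.data$date), .groups = "drop")

  first_visit <- events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_date = min_typed(.data$date), .groups = "drop")
  demo <- dplyr::inner_join(tibble::as_tibble(demographics), first_visit,
                            by = "patient_id") |>
    dplyr::mutate(
      age_bucket = age_decade(
        as.integer(format(.data$first_date, "%Y")) - .data$birth_year)
    ) |>
    dplyr::select("patient_id", "first_date", sex = "sex", race = "race",
                  marital_status = "marital_status",
                  age_bucket = "age_bucket") |>
    tidyr::pivot_longer(-c("patient_id", "first_date"), names_to = "code",
                        values_to = "value_flag") |>
    dplyr::filter(!is.na(.data$value_flag)) |>
    dplyr::mutate(code_type = "DEMO") |>
    dplyr::select("patient_id", "code_type", "code", "value_flag",
                  "first_date")

  dplyr::bind_rows(coded, demo) |>
    dplyr::mutate(feature_id = feature_key(.data$code_type, .data$code,
                                           .data$value_flag))
}

age_decade <- function(age) {
  lo <- (age %/% 10L) * 10L
  ifelse(is.na(age), NA_character_, sprintf("%d-%d", lo, lo + 9L))
}

feature_key <- function(code_type, code, value_flag) {
  paste(code_type, code, dplyr::coalesce(value_flag, ""), sep = "|")
}

#' Build the model vocabulary from the training arm
#'
#' Enumerates every distinct feature key observed among training-arm
#' patients — coded keys `(code_type, code, value_flag)`, where a lab code
#' contributes up to three keys (`L`/`N`/`H`), plus demographic category
#' keys — and drops keys carried by fewer than `min_count` training
#' patients. The vocabulary must be built from the training arm only;
#' building it on anything wider leaks test-arm information into the model.
#'
#' @param train_events Censored event table restricted to training patients.
#' @param train_demographics Demographics restricted to training patients.
#' @param min_count Minimum number of distinct training patients carrying a
#'   key (default 5, which stabilizes rare-feature odds ratios).
#' @return A tibble `code_type`, `code`, `value_flag`, `n_train_patients`,
#'   `feature_id`, ordered deterministically.
#' @export
build_vocabulary <- function(train_events, train_demographics,
                             min_count = 5) {
  if (nrow(train_events) == 0) stop("training arm has no events")
  patient_feature_dates(train_events, train_demographics) |>
    dplyr::group_by(.data$code_type, .data$code, .data$value_flag,
                    .data$feature_id) |>
    dplyr::summarise(n_train_patients = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_train_patients >= min_count) |>
    dplyr::arrange(.data$code_type, .data$code, .data$value_flag) |>
    dplyr::select("code_type", "code", "value_flag", "n_train_patients",
                  "feature_id")
}

#' Extract ever-coded binary features with first-occurrence dates
#'
#' Represents each patient as the set of feature keys ever observed in their
#' (already censored) record up to `as_of_date`, each with its
#' first-occurrence date. Repeat codings do not re-add a feature. Keys
#' absent from the vocabulary are retained (flagged `in_vocab = FALSE`) so
#' trajectories can log them at partial risk score 0, but they never enter
#' model fitting or scoring.
#'
#' @param events Censored event table for the patients to featurize.
#' @param demographics Matching demographics table.
#' @param vocabulary Vocabulary from [build_vocabulary()].
#' @param as_of_date Optional cutoff date; only features first occurring on
#'   or before it are present. `NULL` uses the full record.
#' @return A tibble `patient_id`, `feature_id`, `code_type`, `code`,
#'   `value_flag`, `first_date`, `in_vocab`.
#' @export
extract_features <- function(events, demographics, vocabulary,
                             as_of_date = NULL) {
  feats <- patient_feature_dates(events, demographics)
  if (!is.null(as_of_date)) {
    feats <- dplyr::filter(feats, .data$first_date <= as_of_date)
  }
  feats |>
    dplyr::mutate(in_vocab = .data$feature_id %in% vocabulary$feature_id) |>
    dplyr::select("patient_id", "feature_id", "code_type", "code",
                  "value_flag", "first_date", "in_vocab") |>
    dplyr::arrange(.data$patient_id, .data$first_date, .data$feature_id)
}

#' Export a vocabulary as TSV
#'
#' @param vocabulary Vocabulary tibble.
#' @param path File path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  readr::write_tsv(
    dplyr::select(vocabulary, "code_type", "code", "value_flag",
                  "n_train_patients"),
    path, na = "")
  invisible(path)
}
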