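#' Case definition by diagnosis-code prefix
#'
#' Outcome events are identified by string-prefix match on diagnosis codes,
#' after normalizing both codes and prefixes by stripping dots and
#' upper-casing (so `"E950.0"` and `"E9500"` both match prefix `"E95"`).
#' The default prefixes identify suicidal behavior (intentional
#' self-harm, poisonings, and forearm/wrist open wounds). An optional
#' external flag table emulates linkage to an outside source such as death
#' certificates: its patients are cases and its dates participate in the
#' first-event minimum.
#'
#' @param code_prefixes Character vector of diagnosis-code prefixes.
#' @param external_cases Optional tibble with columns `patient_id` and
#'   `event_date` (Date).
#' @return A `case_definition` object.
#' @export
case_definition <- function(code_prefixes = c("E95", "965", "967", "969",
                                              "881"),
                            external_cases = NULL) {
  stopifnot(is.character(code_prefixes), length(code_prefixes) > 0,
            all(nzchar(code_prefixes)))
  if (!is.null(external_cases)) {
    stopifnot(is.data.frame(external_cases),
              all(c("patient_id", "event_date") %in% names(external_cases)))
    external_cases <- tibble::as_tibble(external_cases) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(event_date = min(.data$event_date), .groups = "drop")
  }
  structure(
    list(code_prefixes = normalize_code(code_prefixes),
         external_cases = external_cases),
    class = "case_definition"
  )
}

normalize_code <- function(x) toupper(gsub(".", "", x, fixed = TRUE))

# Grouped minimum that stays warning-free and correctly typed when dplyr
# evaluates it on a zero-row prototype (empty input table).
min_typed <- function(x) {
  if (length(x) == 0) x[NA_integer_] else x[which.min(x)]
}

#' Identify cases and index dates in an event table
#'
#' Scans the event table for diagnosis codes matching the case definition
#' (and any external case flags) and for the subpopulation marker diagnosis,
#' and initializes the per-patient cohort label table.
#'
#' @param events Event table (see [read_event_table()] for the dialect).
#' @param case_def A [case_definition()].
#' @param marker_code Diagnosis code defining the subpopulation (dot-stripped
#'   match); `NULL` to skip marker detection.
#' @return A tibble with one row per patient: `patient_id`, `is_case`,
#'   `first_event_date`, `first_marker_date`, `included` (`NA` until
#'   [apply_inclusion()]), `exclusion_reason` (`"none"`).
#' @export
find_cases <- function(events, case_def = case_definition(),
                       marker_code = "340") {
  stopifnot(inherits(case_def, "case_definition"))
  events <- tibble::as_tibble(events)
  dx <- dplyr::filter(events, .data$code_type == "DX")
  norm <- normalize_code(dx$code)
  hit <- rep(FALSE, nrow(dx))
  for (p in case_def$code_prefixes) hit <- hit | startsWith(norm, p)

  coded <- dx[hit, c("patient_id", "date")] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(coded_date = min_typed(.data$date), .groups = "drop")

  patient_ids <- unique(events$patient_id)
  if (!is.null(case_def$external_cases)) {
    patient_ids <- union(patient_ids, case_def$external_cases$patient_id)
  }
  labels <- tibble::tibble(patient_id = sort(patient_ids)) |>
    dplyr::left_join(coded, by = "patient_id")
  if (!is.null(case_def$external_cases)) {
    labels <- labels |>
      dplyr::left_join(
        dplyr::rename(case_def$external_cases, external_date = "event_date"),
        by = "patient_id")
  } else {
    labels$external_date <- as.Date(NA)
  }
  labels <- labels |>
    dplyr::mutate(
      is_case = !is.na(.data$coded_date) | !is.na(.data$external_date),
      first_event_date = pmin(.data$coded_date, .data$external_date,
                              na.rm = TRUE)
    ) |>
    dplyr::select("patient_id", "is_case", "first_event_date")

  if (!is.null(marker_code)) {
    marker <- dx[normalize_code(dx$code) == normalize_code(marker_code),
                 c("patient_id", "date")] |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_marker_date = min_typed(.data$date),
                       .groups = "drop")
    labels <- dplyr::left_join(labels, marker, by = "patient_id")
  } else {
    labels$first_marker_date <- as.Date(NA)
  }
  labels$included <- NA
  labels$exclusion_reason <- "none"
  labels
}

#' Apply cohort inclusion criteria
#'
#' A patient is included when (1) they have at least `min_visits` visits,
#' where a visit is a distinct patient-date with at least one coded event,
#' (2) at least `min_span_days` days separate their first and last visits
#' (boundary inclusive: a span of exactly 30 days qualifies), and (3) at
#' least one event occurred at an age inside `age_range`, with age computed
#' as event year minus birth year. A missing birth year fails criterion (3)
#' closed.
#'
#' @param labels Label tibble from [find_cases()].
#' @param events Event table.
#' @param demographics Demographics table with `patient_id`, `birth_year`.
#' @param min_visits,min_span_days,age_range Criterion parameters.
#' @return The label tibble with `included` and `exclusion_reason`
#'   (`too_few_visits`, `span_too_short`, `age_out_of_range`, or `none`)
#'   filled in.
#' @export
apply_inclusion <- function(labels, events, demographics, min_visits = 3,
                            min_span_days = 30, age_range = c(10, 90)) {
  events <- tibble::as_tibble(events)
  per <- events |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(demographics), "patient_id",
                    "birth_year"),
      by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_visits = dplyr::n_distinct(.data$date),
      span_days = as.numeric(max(.data$date) - min(.data$date)),
      age_ok = any(!is.na(.data$birth_year) &
                     dplyr::between(
                       as.integer(format(.data$date, "%Y")) -
                         .data$birth_year,
                       .env$age_range[1], .env$age_range[2])),
      .groups = "drop"
    )
  labels |>
    dplyr::left_join(per, by = "patient_id") |>
    dplyr::mutate(
      n_visits = dplyr::coalesce(.data$n_visits, 0L),
      span_days = dplyr::coalesce(.data$span_days, 0),
      age_ok = dplyr::coalesce(.data$age_ok, FALSE),
      exclusion_reason = dplyr::case_when(
        .data$n_visits < min_visits ~ "too_few_visits",
        .data$span_days < min_span_days ~ "span_too_short",
        !.data$age_ok ~ "age_out_of_range",
        TRUE ~ "none"
      ),
      included = .data$exclusion_reason == "none"
    ) |>
    dplyr::select(-"n_visits", -"span_days", -"age_ok")
}

#' Apply case-specific exclusions
#'
#' Two exclusions apply to cases that passed the inclusion criteria: a case
#' with no event strictly before its first case-defining event has no usable
#' history (`no_prior_data`); a case whose first event precedes its first
#' marker diagnosis is excluded (`event_before_marker`). Cases with marker
#' and event on the same date are retained. In a marker-defined cohort
#' (`marker_required = TRUE`) a case with no observed marker at all is
#' treated as event-before-marker, since the record is censored at the event
#' and the cohort-defining marker can only postdate it.
#'
#' @param labels Label tibble with `included` populated.
#' @param events Event table (uncensored).
#' @param marker_required Whether every patient is known to carry the marker.
#' @return Updated label tibble.
#' @export
apply_case_exclusions <- function(labels, events, marker_required = TRUE) {
  stopifnot(!any(is.na(labels$included)))
  events <- tibble::as_tibble(events)
  prior <- events |>
    dplyr::inner_join(
      labels |>
        dplyr::filter(.data$is_case) |>
        dplyr::select("patient_id", "first_event_date"),
      by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_prior = any(.data$date < .data$first_event_date),
      .groups = "drop")
  labels |>
    dplyr::left_join(prior, by = "patient_id") |>
    dplyr::mutate(
      marker_missing = if (marker_required) is.na(.data$first_marker_date)
                       else FALSE,
      exclusion_reason = dplyr::case_when(
        !.data$included | !.data$is_case ~ .data$exclusion_reason,
        !dplyr::coalesce(.data$has_prior, FALSE) ~ "no_prior_data",
        .data$marker_missing ~ "event_before_marker",
        !is.na(.data$first_marker_date) &
          .data$first_event_date < .data$first_marker_date ~
          "event_before_marker",
        TRUE ~ .data$exclusion_reason
      ),
      included = .data$exclusion_reason == "none"
    ) |>
    dplyr::select(-"has_prior", -"marker_missing")
}

#' Censor case records at the first case-defining event
#'
#' Removes, for each case, every event dated on or after its first
#' case-defining event, so that no model or trajectory ever sees the event
#' itself or anything after it. Controls pass through untouched. The
#' operation is idempotent.
#'
#' @param events Event table.
#' @param labels Label tibble with `is_case` and `first_event_date`.
#' @return The censored event table.
#' @export
censor_case_records <- function(events, labels) {
  tibble::as_tibble(events) |>
    dplyr::left_join(
      labels |>
        dplyr::filter(.data$is_case) |>
        dplyr::select("patient_id", "first_event_date"),
      by = "patient_id") |>
    dplyr::filter(is.na(.data$first_event_date) |
                    .data$date < .data$first_event_date) |>
    dplyr::select(-"first_event_date")
}

#' Temporal order of marker diagnosis and case-defining event
#'
#' Counts, over all identified cases (before exclusions), whether the
#' subpopulation marker preceded the case-defining event, followed it, or
#' fell on the same date.
#'
#' @param labels Label tibble.
#' @param na_marker_as_event_first In a marker-defined cohort a case whose
#'   censored record shows no marker had its marker after the event; set
#'   `TRUE` to count those as `event_first` (otherwise they are dropped).
#' @return A one-row tibble with counts `marker_first`, `event_first`,
#'   `same_day`, `n_cases`, and the corresponding proportions.
#' @export
classify_temporal_order <- function(labels, na_marker_as_event_first = FALSE) {
  cases <- dplyr::filter(labels, .data$is_case)
  marker <- cases$first_marker_date
  event <- cases$first_event_date
  if (na_marker_as_event_first) {
    marker_first <- sum(!is.na(marker) & marker < event)
    event_first <- sum(is.na(marker) | event < marker)
    same_day <- sum(!is.na(marker) & marker == event)
  } else {
    ok <- !is.na(marker) & !is.na(event)
    marker_first <- sum(ok & marker < event)
    event_first <- sum(ok & event < marker)
    same_day <- sum(ok & marker == event)
  }
  n <- marker_first + event_first + same_day
  tibble::tibble(
    marker_first = marker_first, event_first = event_first,
    same_day = same_day, n_cases = n,
    prop_marker_first = if (n > 0) marker_first / n else NA_real_,
    prop_event_first = if (n > 0) event_first / n else NA_real_,
    prop_same_day = if (n > 0) same_day / n else NA_real_
  )
}

#' Exclusion accounting
#'
#' Tabulates included patients and each exclusion reason, overall and among
#' cases, so that the identity
#' `n identified cases = n included cases + sum of per-reason case
#' exclusions` can be read off directly.
#'
#' @param labels Final label tibble.
#' @return A tibble with one row per status (`included` plus each observed
#'   exclusion reason) and columns `n` and `n_cases`.
#' @export
exclusion_summary <- function(labels) {
  labels |>
    dplyr::mutate(status = ifelse(.data$included, "included",
                                  .data$exclusion_reason)) |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(n = dplyr::n(), n_cases = sum(.data$is_case),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$status == "included"), .data$status)
}

#' Randomly split included patients into training and testing arms
#'
#' Uniform random partition of the included patients into two arms whose
#' sizes differ by at most one; deterministic given `split_seed`. By default
#' the split is not stratified by case status; `stratify_by_case = TRUE`
#' balances cases across arms for synthetic experiments.
#'
#' @param labels Final label tibble.
#' @param split_seed Integer seed.
#' @param stratify_by_case Stratify the partition on `is_case`.
#' @return A tibble `patient_id`, `arm` (`"train"`/`"test"`) covering exactly
#'   the included patients.
#' @export
split_train_test <- function(labels, split_seed, stratify_by_case = FALSE) {
  inc <- dplyr::filter(labels, .data$included)
  if (nrow(inc) < 2) stop("need at least 2 included patients to split")
  withr::with_seed(split_seed, {
    if (stratify_by_case) {
      parts <- lapply(split(inc$patient_id, inc$is_case), assign_arms)
      out <- dplyr::bind_rows(parts)
    } else {
      out <- assign_arms(inc$patient_id)
    }
  })
  dplyr::arrange(out, .data$patient_id)
}

assign_arms <- function(ids) {
  shuffled <- sample(ids)
  n_train <- ceiling(length(ids) / 2)
  tibble::tibble(
    patient_id = shuffled,
    arm = rep(c("train", "test"),
              c(n_train, length(ids) - n_train))
  )
}

#' Demographic summary of a cohort
#'
#' Counts and percentages of each categorical demographic feature for the
#' whole cohort and for cases and controls separately, plus the women:men
#' ratio (as the numeric ratio; `Inf` when the cohort has no men).
#'
#' @param labels Label tibble (defines case status and the patient set).
#' @param demographics Demographics table.
#' @return A tibble `feature`, `category`, `n_all`, `pct_all`, `n_cases`,
#'   `pct_cases`, `n_controls`, `pct_controls`, with the women:men ratio in
#'   attribute `"sex_ratio"` (also via [sex_ratio()]).
#' @export
summarize_demographics <- function(labels, demographics) {
  demo <- dplyr::inner_join(
    dplyr::select(labels, "patient_id", "is_case"),
    tibble::as_tibble(demographics), by = "patient_id")
  if (nrow(demo) == 0) {
    out <- tibble::tibble(
      feature = character(), category = character(), n_all = integer(),
      pct_all = numeric(), n_cases = integer(), pct_cases = numeric(),
      n_controls = integer(), pct_controls = numeric())
    attr(out, "sex_ratio") <- NA_real_
    return(out)
  }
  long <- demo |>
    dplyr::select(-"birth_year") |>
    tidyr::pivot_longer(-c("patient_id", "is_case"), names_to = "feature",
                        values_to = "category")
  tot_all <- nrow(demo); tot_cases <- sum(demo$is_case)
  tot_controls <- tot_all - tot_cases
  out <- long |>
    dplyr::group_by(.data$feature, .data$category) |>
    dplyr::summarise(
      n_all = dplyr::n(), n_cases = sum(.data$is_case),
      n_controls = dplyr::n() - sum(.data$is_case), .groups = "drop") |>
    dplyr::mutate(
      pct_all = 100 * .data$n_all / tot_all,
      pct_cases = if (tot_cases > 0) 100 * .data$n_cases / tot_cases
                  else NA_real_,
      pct_controls = if (tot_controls > 0)
        100 * .data$n_controls / tot_controls else NA_real_
    ) |>
    dplyr::select("feature", "category", "n_all", "pct_all", "n_cases",
                  "pct_cases", "n_controls", "pct_controls")
  attr(out, "sex_ratio") <- sex_ratio(demo)
  out
}

#' @rdname summarize_demographics
#' @param x A demographics table with a `sex` column (`"F"`/`"M"`), or the
#'   output of `summarize_demographics()`.
#' @export
sex_ratio <- function(x) {
  if (!is.null(attr(x, "sex_ratio"))) return(attr(x, "sex_ratio"))
  stopifnot("sex" %in% names(x))
  women <- sum(x$sex == "F"); men <- sum(x$sex == "M")
  if (men == 0) return(Inf)
  women / men
}
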