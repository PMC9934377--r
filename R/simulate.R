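# Internal constants shared by the generator and the cohort builder defaults.
.marker_code <- "340"
.case_code <- "E9500"
.sim_origin <- as.Date("1998-01-01")

#' Simulate a longitudinal coded EHR cohort with planted risk structure
#'
#' Generates the three tables the downstream pipeline consumes: a long event
#' table (one row per patient-date-code), a per-patient demographics table,
#' and a per-patient truth table recording the planted case status.
#'
#' The generative model is the Naive Bayes factorization matched to the
#' scoring model the data are meant to exercise: case status is Bernoulli at
#' `baseline_prevalence`, and each code is then carried ever/never
#' independently given class, with exposure odds in cases equal to the
#' control odds (the code's base rate) times `exp(effect)`;
#' subpopulation-specific effects act only for marker patients. By Bayes'
#' rule this is exactly a logistic model for case status whose linear
#' predictor is the sum of the true log odds ratios of the carried codes,
#' with the intercept available in closed form, so the marginal prevalence
#' is the target by construction and every planted effect equals the
#' population 2x2 log odds ratio it induces. Cases receive the
#' case-defining diagnosis (`"E9500"`) on a day drawn uniformly from the
#' second half of their follow-up, their other events are dated uniformly
#' before that day, and nothing is generated after it. The subpopulation
#' marker (`"340"`) is dated uniformly over the full (untruncated) follow-up,
#' so a realistic minority of cases have their event precede any observed
#' marker.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `events` (`patient_id`, `date`, `code_type`,
#'   `code`, `value_flag`), `demographics` (`patient_id`, `sex`,
#'   `birth_year`, `race`, `marital_status`), `truth` (`patient_id`,
#'   `is_case`, `is_subpop`, `event_date`), and `code_truth` (the per-code
#'   planted base rates and effects).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 200, seed = 7))
#' dplyr::count(cohort$truth, is_case)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  if (n == 0) {
    return(list(
      events = empty_event_table(), demographics = empty_demographics(),
      truth = empty_truth(), code_truth = config$codes
    ))
  }
  codes <- config$codes
  patient_id <- sprintf("P%06d", seq_len(n))

  is_subpop <- runif(n) < config$subpop_fraction
  is_case <- runif(n) < config$baseline_prevalence

  # ever-carried indicator per patient x code: exposure odds multiplied by
  # exp(effect) for cases (subpop effects only inside the subpopulation)
  carried <- vapply(seq_len(nrow(codes)), function(j) {
    p0 <- codes$base_rate[j]
    if ((p0 == 0 || p0 == 1) && codes$effect[j] != 0) {
      stop("code ", codes$code[j], ": planted effect unrealizable at base ",
           "rate ", p0)
    }
    active <- is_case &
      (codes$role[j] == "shared" |
         (codes$role[j] == "subpop" & is_subpop))
    p <- ifelse(active, plogis(stats::qlogis(p0) + codes$effect[j]), p0)
    rbinom(n, 1L, p)
  }, integer(n))
  carried <- matrix(carried, nrow = n) # guards n == 1

  fu_years <- stats::rgamma(n, shape = config$followup_years_shape,
                            rate = config$followup_years_shape /
                              config$followup_years_mean)
  fu_years <- fu_years * ifelse(is_case, config$case_followup_multiplier, 1)
  fu_days <- pmax(1L, as.integer(round(fu_years * 365.25)))
  start_day <- sample.int(3653L, n, replace = TRUE) - 1L # 1998--2007 entry
  start_date <- .sim_origin + start_day

  # case-defining event day: uniform over the second half of follow-up so
  # pre-event history exists; optionally forced to day 0 to exercise the
  # no-prior-data exclusion
  event_day <- rep(NA_integer_, n)
  ncase <- sum(is_case)
  if (ncase > 0) {
    half <- fu_days[is_case] %/% 2L
    event_day[is_case] <- half +
      floor(runif(ncase) * (fu_days[is_case] - half + 1L))
    if (config$no_prior_fraction > 0) {
      forced <- runif(ncase) < config$no_prior_fraction
      event_day[is_case][forced] <- 0L
    }
  }
  # observed record window: truncated at the event for cases
  window <- ifelse(is_case, event_day, fu_days)

  events <- dplyr::bind_rows(
    carried_code_events(carried, codes, window, fu_years, config),
    marker_events(which(is_subpop), fu_days, window),
    case_events(which(is_case), event_day)
  )
  events$patient_id <- patient_id[events$idx]
  events$date <- start_date[events$idx] + events$day
  events <- events |>
    dplyr::select("patient_id", "date", "code_type", "code", "value_flag") |>
    dplyr::arrange(.data$patient_id, .data$date, .data$code_type, .data$code,
                   .data$value_flag)

  demographics <- tibble::tibble(
    patient_id = patient_id,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.73, 0.27)),
    birth_year = as.integer(format(start_date, "%Y")) -
      sample(18:85, n, replace = TRUE),
    race = sample(c("White", "Black", "Hispanic", "Asian", "Other"), n,
                  replace = TRUE, prob = c(0.80, 0.05, 0.026, 0.011, 0.113)),
    marital_status = sample(
      c("Married", "Single", "Divorced", "Widowed", "Separated", "Partner",
        "Other"), n, replace = TRUE,
      prob = c(0.558, 0.267, 0.078, 0.038, 0.012, 0.002, 0.045))
  )

  truth <- tibble::tibble(
    patient_id = patient_id,
    is_case = is_case,
    is_subpop = is_subpop,
    event_date = dplyr::if_else(is_case, start_date + event_day,
                                as.Date(NA))
  )

  list(events = events, demographics = demographics, truth = truth,
       code_truth = codes)
}

# Events for the carried codes: each carried code occurs >= 1 time, with
# repeat counts tuned so total coded-event density approximates
# events_per_year; all occurrence days are uniform over the observed window.
carried_code_events <- function(carried, codes, window, fu_years, config) {
  hit <- which(carried == 1L, arr.ind = TRUE)
  if (length(hit) == 0) return(empty_sim_events())
  idx <- hit[, 1]
  code_j <- hit[, 2]
  n_codes_per_patient <- tabulate(idx, nbins = nrow(carried))
  target <- config$events_per_year * fu_years
  lambda <- pmax(0, target / pmax(1, n_codes_per_patient) - 1)
  n_occ <- 1L + rpois(length(idx), lambda[idx])
  occ_idx <- rep(idx, n_occ)
  occ_code <- rep(code_j, n_occ)
  day <- floor(runif(length(occ_idx)) * (window[occ_idx] + 1L))
  code_type <- codes$code_type[occ_code]
  tibble::tibble(
    idx = occ_idx, day = as.integer(day),
    code_type = code_type, code = codes$code[occ_code],
    value_flag = ifelse(
      code_type == "LAB",
      sample(c("L", "N", "H"), length(occ_idx), replace = TRUE,
             prob = c(0.2, 0.6, 0.2)),
      NA_character_)
  )
}

marker_events <- function(idx, fu_days, window) {
  if (length(idx) == 0) return(empty_sim_events())
  day <- floor(runif(length(idx)) * (fu_days[idx] + 1L))
  keep <- day <= window[idx] # markers dated after a case's event are unseen
  tibble::tibble(
    idx = idx[keep], day = as.integer(day[keep]), code_type = "DX",
    code = .marker_code, value_flag = NA_character_
  )
}

case_events <- function(idx, event_day) {
  if (length(idx) == 0) return(empty_sim_events())
  tibble::tibble(
    idx = idx, day = event_day[idx], code_type = "DX", code = .case_code,
    value_flag = NA_character_
  )
}

empty_sim_events <- function() {
  tibble::tibble(idx = integer(), day = integer(), code_type = character(),
                 code = character(), value_flag = character())
}

empty_event_table <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 code_type = character(), code = character(),
                 value_flag = character())
}

empty_demographics <- function() {
  tibble::tibble(patient_id = character(), sex = character(),
                 birth_year = integer(), race = character(),
                 marital_status = character())
}

empty_truth <- function() {
  tibble::tibble(patient_id = character(), is_case = logical(),
                 is_subpop = logical(), event_date = as.Date(character()))
}
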