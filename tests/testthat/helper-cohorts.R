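# Shared fixtures, built in code and memoized so expensive cohorts are
# generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Planted-effect recovery conditions: effects span the adverse/protective
# range with base rates high enough that every code has ample exposed cases.
recovery_config <- function(n_patients, seed = 1L) {
  sim_config(
    n_patients = n_patients, subpop_fraction = 1,
    baseline_prevalence = 0.013,
    shared_effects = c(2.5, 2.0, 1.5, 1.0, 0.5),
    subpop_effects = c(-0.4, -0.8),
    risk_code_base_rate = c(0.1, 0.1, 0.1, 0.15, 0.2, 0.3, 0.3),
    n_noise_codes = 20, seed = seed
  )
}

recovery_cohort <- function() {
  memo("recovery50k", simulate_cohort(recovery_config(50000, seed = 1L)))
}

# Small default-conditions cohort for pipeline plumbing tests.
small_cohort <- function() {
  memo("small", simulate_cohort(sim_config(n_patients = 3000, seed = 11L)))
}

# Small cohort run through the full cohort-building pipeline.
small_labels <- function() {
  memo("small_labels", {
    co <- small_cohort()
    find_cases(co$events) |>
      apply_inclusion(co$events, co$demographics) |>
      apply_case_exclusions(co$events)
  })
}

# Hand-built event rows from integer day offsets.
day0 <- as.Date("2000-01-01")

empty_event_table_ <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 code_type = character(), code = character(),
                 value_flag = character())
}

toy_events <- function(patient_id, day, code, code_type = "DX",
                       value_flag = NA_character_) {
  tibble::tibble(
    patient_id = patient_id, date = day0 + day, code_type = code_type,
    code = code, value_flag = value_flag
  )
}

toy_demographics <- function(patient_ids, birth_year = 1960L) {
  tibble::tibble(
    patient_id = patient_ids, sex = "F", birth_year = birth_year,
    race = "White", marital_status = "Single"
  )
}

# Minimal scoring model for trajectory arithmetic tests.
toy_model <- function(prs) {
  structure(
    list(
      features = tibble::tibble(
        feature_id = names(prs), code_type = "DX", code = names(prs),
        value_flag = NA_character_, cases_with = 1L, cases_without = 1L,
        controls_with = 1L, controls_without = 1L, or = exp(unname(prs)),
        smoothed = FALSE, prs = unname(prs)),
      n_cases = 1L, n_controls = 1L),
    class = "prs_model")
}

toy_features <- function(patient_id, feature_id, day) {
  tibble::tibble(
    patient_id = patient_id, feature_id = feature_id, code_type = "DX",
    code = feature_id, value_flag = NA_character_, first_date = day0 + day,
    in_vocab = TRUE
  )
}

# Empirical 2x2 log odds ratio of a code from generated events + truth:
# the independent oracle for planted-effect recovery.
empirical_log_or <- function(cohort, code) {
  carriers <- unique(
    cohort$events$patient_id[cohort$events$code == code])
  a <- sum(cohort$truth$is_case & cohort$truth$patient_id %in% carriers)
  c <- sum(!cohort$truth$is_case & cohort$truth$patient_id %in% carriers)
  n1 <- sum(cohort$truth$is_case)
  n0 <- sum(!cohort$truth$is_case)
  odds_ratio(a, n1 - a, c, n0 - c)$log_or
}

# Brute-force pairwise-concordance AUC: the independent oracle for roc_auc.
brute_force_auc <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  total <- 0
  for (x in cs) total <- total + sum(x > ct) + 0.5 * sum(x == ct)
  total / (length(cs) * length(ct))
}
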