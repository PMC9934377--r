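#' Configuration for the synthetic EHR cohort generator
#'
#' Describes a longitudinal coded-EHR cohort with planted risk structure:
#' a set of *shared* risk codes whose effects act on every patient, a set of
#' *subpopulation-specific* risk codes whose effects act only on patients
#' carrying the subpopulation marker diagnosis (code `"340"`), and inert
#' noise codes. Case status is drawn per patient from a logistic model whose
#' linear predictor is the sum of the true log odds ratios of the codes the
#' patient ever carries; the intercept is solved numerically so that the
#' realized marginal prevalence matches `baseline_prevalence`.
#'
#' Defaults emulate a single-marker clinical cohort of ~15,000 patients with
#' ~1.3% outcome prevalence, mean follow-up 8.4 years, and planted odds
#' ratios spanning the 0.7--13 range typical of coded suicide-risk factors,
#' including one protective (negative log-OR) code.
#'
#' @param n_patients Number of patients to simulate.
#' @param subpop_fraction Probability that a patient belongs to the marked
#'   subpopulation (receives the marker diagnosis code `"340"`). The default
#'   `1` generates a pure subpopulation cohort; use a value below 1 to embed
#'   the subpopulation inside a general cohort.
#' @param baseline_prevalence Target marginal prevalence of the case-defining
#'   outcome.
#' @param shared_effects Numeric vector of true log odds ratios (natural log)
#'   for the shared risk codes; its length sets the number of shared codes.
#' @param subpop_effects True log odds ratios for the subpopulation-specific
#'   risk codes; these contribute to a patient's linear predictor only when
#'   the patient is in the subpopulation.
#' @param n_noise_codes Number of codes with no effect on case status.
#' @param risk_code_base_rate Probability that a control ever carries each
#'   risk code. Either a scalar or a vector of length
#'   `length(shared_effects) + length(subpop_effects)`.
#' @param noise_code_base_rates Per-code carry probabilities for the noise
#'   codes; recycled to `n_noise_codes`. The default spreads rates
#'   log-uniformly between 0.005 and 0.2.
#' @param followup_years_mean,followup_years_shape Mean and gamma shape of
#'   the per-patient follow-up length in years (shape 2 gives a realistic
#'   right-skewed mix of short and long records).
#' @param events_per_year Approximate density of coded events per patient
#'   per year of follow-up.
#' @param no_prior_fraction Fraction of cases whose case-defining event is
#'   forced onto the first day of their record, leaving no prior
#'   documentation. Default 0; raise it to exercise the no-prior-data
#'   exclusion filter downstream.
#' @param case_followup_multiplier Multiplier applied to the follow-up
#'   length of cases before truncation at the event date. Default 1 plants
#'   no follow-up/case-status correlation.
#' @param seed Integer seed; the same configuration always generates
#'   byte-identical tables.
#'
#' @return A `sim_config` object (a validated list) with a `codes` tibble
#'   holding one row per plantable code: `code`, `code_type`, `role`
#'   (`shared`/`subpop`/`noise`), `base_rate`, `effect`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 42)
#' cfg$codes
sim_config <- function(n_patients = 15000,
                       subpop_fraction = 1,
                       baseline_prevalence = 0.013,
                       shared_effects = c(2.6, 2.0, 1.5, 1.2, -0.4),
                       subpop_effects = c(1.5, 1.4, 1.3, 1.2, 1.1),
                       n_noise_codes = 40,
                       risk_code_base_rate = 0.05,
                       noise_code_base_rates = NULL,
                       followup_years_mean = 8.4,
                       followup_years_shape = 2,
                       events_per_year = 5,
                       no_prior_fraction = 0,
                       case_followup_multiplier = 1,
                       seed = 1L) {
  stopifnot(
    length(n_patients) == 1, n_patients >= 0, n_patients == floor(n_patients),
    is_probability(subpop_fraction),
    is_probability(baseline_prevalence),
    all(is.finite(shared_effects)), all(is.finite(subpop_effects)),
    n_noise_codes >= 0,
    followup_years_mean > 0, followup_years_shape > 0,
    events_per_year > 0,
    is_probability(no_prior_fraction),
    case_followup_multiplier > 0,
    length(seed) == 1, is.finite(seed)
  )

  n_shared <- length(shared_effects)
  n_subpop <- length(subpop_effects)
  n_risk <- n_shared + n_subpop
  risk_rates <- rep_len(risk_code_base_rate, n_risk)
  if (is.null(noise_code_base_rates)) {
    noise_code_base_rates <- if (n_noise_codes > 0) {
      exp(seq(log(0.005), log(0.2), length.out = n_noise_codes))
    } else {
      numeric(0)
    }
  }
  noise_rates <- rep_len(noise_code_base_rates, n_noise_codes)
  stopifnot(all(is_probability(c(risk_rates, noise_rates))))

  # noise codes cycle through the three source systems so the feature space
  # exercises DX, RX and LAB (with L/N/H flags) keys
  noise_types <- if (n_noise_codes > 0) {
    rep_len(c("DX", "RX", "LAB"), n_noise_codes)
  } else {
    character(0)
  }
  codes <- dplyr::bind_rows(
    tibble::tibble(
      code = sprintf("S%02d", seq_len(n_shared)), code_type = "DX",
      role = "shared", base_rate = risk_rates[seq_len(n_shared)],
      effect = as.numeric(shared_effects)
    ),
    tibble::tibble(
      code = sprintf("M%02d", seq_len(n_subpop)), code_type = "DX",
      role = "subpop", base_rate = risk_rates[n_shared + seq_len(n_subpop)],
      effect = as.numeric(subpop_effects)
    ),
    tibble::tibble(
      code = sprintf("N%02d", seq_len(n_noise_codes)), code_type = noise_types,
      role = "noise", base_rate = noise_rates, effect = 0
    )
  )

  structure(
    list(
      n_patients = as.integer(n_patients),
      subpop_fraction = subpop_fraction,
      baseline_prevalence = baseline_prevalence,
      codes = codes,
      followup_years_mean = followup_years_mean,
      followup_years_shape = followup_years_shape,
      events_per_year = events_per_year,
      no_prior_fraction = no_prior_fraction,
      case_followup_multiplier = case_followup_multiplier,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

is_probability <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  patients:", x$n_patients,
      " subpop fraction:", x$subpop_fraction,
      " target prevalence:", x$baseline_prevalence, "\n")
  cat("  codes:", nrow(x$codes),
      sprintf("(%d shared, %d subpop, %d noise)",
              sum(x$codes$role == "shared"), sum(x$codes$role == "subpop"),
              sum(x$codes$role == "noise")), "\n")
  cat("  follow-up: gamma mean", x$followup_years_mean, "y, shape",
      x$followup_years_shape, "; events/year", x$events_per_year, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
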