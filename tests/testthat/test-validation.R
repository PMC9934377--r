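test_that("trajectories accumulate PRS at first occurrence with day-level aggregation", {
  m <- toy_model(c(A = 1, B = -2, C = 3))

  tr <- build_trajectories(toy_features("P1", c("A", "B", "C"), day = 1:3), m)
  expect_equal(tr$risk_t, c(1, -1, 2))
  ors <- overall_risk_scores(tr)
  expect_equal(ors$ors, 2)

  same_day <- build_trajectories(
    toy_features("P1", c("A", "B", "C"), day = c(1, 1, 1)), m)
  expect_equal(nrow(same_day), 1)
  expect_equal(same_day$risk_t, 2)

  rep_fx <- dplyr::bind_rows(toy_features("P1", "A", day = 1),
                             toy_features("P1", "A", day = 5))
  rep_tr <- build_trajectories(rep_fx, m)
  expect_equal(rep_tr$risk_t[rep_tr$date == day0 + 5],
               rep_tr$risk_t[rep_tr$date == day0 + 1])

  # out-of-vocabulary features are logged at PRS 0
  with_unknown <- dplyr::bind_rows(
    toy_features("P2", "A", day = 1),
    dplyr::mutate(toy_features("P2", "ZZ", day = 2), in_vocab = FALSE))
  tr2 <- build_trajectories(with_unknown, m)
  expect_equal(tr2$risk_t, c(1, 1))
})

test_that("ORS is within-day order invariant and final risk equals total score", {
  co <- small_cohort()
  labs <- small_labels()
  cens <- censor_case_records(co$events, labs)
  inc <- labs[labs$included, ][1:200, ]
  ev <- cens[cens$patient_id %in% inc$patient_id, ]
  demo <- co$demographics[co$demographics$patient_id %in% inc$patient_id, ]
  vocab <- build_vocabulary(ev, demo, min_count = 3)
  fx <- extract_features(ev, demo, vocab)
  m <- fit_prs(fx, inc, vocab)
  tr <- build_trajectories(fx, m)
  last <- tr |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(final = dplyr::last(risk_t))
  ts <- total_score(fx, m)
  expect_equal(last$final, ts$score[match(last$patient_id, ts$patient_id)])

  shuffled <- withr::with_seed(1, fx[sample(nrow(fx)), ])
  expect_equal(overall_risk_scores(build_trajectories(shuffled, m)),
               overall_risk_scores(tr))
})

test_that("classification against cutoffs is strictly greater-than", {
  th <- select_thresholds(1:100, 0.9) # cutoff 90
  scores <- tibble::tibble(patient_id = c("a", "b", "c"),
                           ors = c(90, 90 + 1e-9, 0))
  cl <- classify_scores(scores, th)
  expect_equal(cl$positive, c(FALSE, TRUE, FALSE))
})

test_that("AUC matches the brute-force pairwise oracle exactly", {
  # worked toy instance: 9 case-control pairs enumerated by hand
  scores <- c(2, 3, 3, 1, 3, 4)
  is_case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(scores, is_case), 4 / 9)
  expect_equal(brute_force_auc(scores, is_case), 4 / 9)

  for (seed in 1:100) {
    inst <- withr::with_seed(seed, {
      n <- sample(5:200, 1)
      list(s = sample(round(rnorm(n), sample(0:2, 1)), n, replace = TRUE),
           y = c(TRUE, FALSE, runif(n - 2) < 0.3))
    })
    expect_equal(roc_auc(inst$s, inst$y), brute_force_auc(inst$s, inst$y),
                 tolerance = 1e-14)
  }
})

test_that("AUC agrees with an independent ROC library and is antisymmetric", {
  inst <- withr::with_seed(42, list(s = rnorm(300),
                                    y = runif(300) < 0.25))
  ours <- roc_auc(inst$s, inst$y)
  ref <- as.numeric(pROC::auc(pROC::roc(response = inst$y,
                                        predictor = inst$s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
  expect_equal(roc_auc(-inst$s, inst$y), 1 - ours)

  expect_equal(roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(3, 10), c(TRUE, rep(FALSE, 9))), 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "at least one")
})

test_that("confusion metrics handle undefined ratios and conserve totals", {
  cm <- confusion_metrics(0, 10, 0, 5)
  expect_true(is.na(cm$ppv))
  expect_equal(cm$specificity, 1)
  expect_equal(cm$lr_neg, 1)

  co <- small_cohort()
  labs <- small_labels()
  inc <- labs[labs$included, ]
  scores <- tibble::tibble(patient_id = inc$patient_id,
                           ors = withr::with_seed(8, rnorm(nrow(inc))))
  th <- select_thresholds(scores$ors[!inc$is_case], c(0.8, 0.9, 0.95))
  panel <- metric_panel(scores, inc, th)
  expect_true(all(panel$tp + panel$fn == sum(inc$is_case)))
  expect_true(all(panel$tn + panel$fp == sum(!inc$is_case)))
  expect_equal(panel$sensitivity, panel$tp / (panel$tp + panel$fn))
  expect_equal(glance(panel)$auc, roc_auc(scores$ors, inc$is_case))
})

test_that("ROC points trace the empirical curve", {
  s <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(FALSE, TRUE, FALSE, TRUE)
  pts <- roc_points(s, y)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("lead times measure crossing-to-event intervals for detected cases", {
  m <- toy_model(c(A = 5, B = 1))
  # case detected at day 0, event two years later
  fx <- dplyr::bind_rows(toy_features("C1", "A", day = 0),
                         toy_features("C2", "B", day = 10))
  tr <- build_trajectories(fx, m)
  labs <- tibble::tibble(
    patient_id = c("C1", "C2"), is_case = TRUE,
    first_event_date = day0 + c(round(365.25 * 2), 400))
  th <- tibble::tibble(target = 0.9, cutoff = 2) # only C1 crosses
  lt <- lead_times(tr, labs, th)
  expect_equal(lt$n_detected, 1)
  expect_equal(lt$mean_lead_years, 2, tolerance = 1e-3)

  # on a simulated cohort, every lead time is positive by construction
  co <- small_cohort()
  labsim <- small_labels()
  cens <- censor_case_records(co$events, labsim)
  inc <- labsim[labsim$included, ]
  ev <- cens[cens$patient_id %in% inc$patient_id, ]
  demo <- co$demographics[co$demographics$patient_id %in% inc$patient_id, ]
  vocab <- build_vocabulary(ev, demo)
  fx2 <- extract_features(ev, demo, vocab)
  m2 <- fit_prs(fx2, inc, vocab)
  tr2 <- build_trajectories(fx2, m2)
  ctrl_ors <- overall_risk_scores(tr2, patients = inc$patient_id)
  th2 <- select_thresholds(
    ctrl_ors$ors[ctrl_ors$patient_id %in% inc$patient_id[!inc$is_case]])
  lt2 <- lead_times(tr2, inc, th2)
  expect_true(all(lt2$mean_lead_years > 0, na.rm = TRUE))
})
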