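test_that("case-defining codes are matched by dot-stripped prefix", {
  ev <- dplyr::bind_rows(
    toy_events("P1", c(0, 200), c("340", "E950.0")),
    toy_events("P2", c(0, 10), c("9650", "965.0")),
    toy_events("P3", 5, "8450"),
    toy_events("P4", 5, "96", code_type = "RX") # RX never case-defining
  )
  labs <- find_cases(ev)
  expect_equal(labs$is_case, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(labs$first_event_date[1], day0 + 200)
  # both dialects of the same code match prefix 965, oracle: regex on the
  # normalized forms; the earliest match (day 0, code "9650") wins
  norm <- gsub(".", "", c("9650", "965.0"), fixed = TRUE)
  expect_true(all(grepl("^965", norm)))
  expect_equal(labs$first_event_date[2], day0)
  expect_equal(labs$first_marker_date[1], day0)
})

test_that("external case flags participate in the first-event minimum", {
  ev <- toy_events("P1", c(0, 300), c("340", "E9500"))
  cd <- case_definition(
    external_cases = tibble::tibble(patient_id = "P1",
                                    event_date = day0 + 100))
  labs <- find_cases(ev, cd)
  expect_true(labs$is_case)
  expect_equal(labs$first_event_date, day0 + 100)
  # an external-only patient is a case too
  cd2 <- case_definition(
    external_cases = tibble::tibble(patient_id = "PX",
                                    event_date = day0 + 7))
  labs2 <- find_cases(ev, cd2)
  expect_true(labs2$is_case[labs2$patient_id == "PX"])
})

test_that("inclusion criteria follow the visit/span/age rules", {
  ev <- dplyr::bind_rows(
    toy_events("A", c(0, 15, 31), paste0("X", 1:3)),   # 3 visits, span 31
    toy_events("B", rep(10, 5), paste0("X", 1:5)),     # one visit date
    toy_events("C", c(0, 10, 29), paste0("X", 1:3)),   # span 29
    toy_events("D", c(0, 15, 30), paste0("X", 1:3)),   # span exactly 30
    toy_events("E", c(0, 15, 31), paste0("X", 1:3))    # missing birth year
  )
  demo <- toy_demographics(c("A", "B", "C", "D"))
  demo <- dplyr::bind_rows(
    demo, tibble::tibble(patient_id = "E", sex = "F", birth_year = NA,
                         race = "White", marital_status = "Single"))
  labs <- find_cases(ev) |> apply_inclusion(ev, demo)
  expect_equal(labs$included,
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(labs$exclusion_reason[labs$patient_id == "B"],
               "too_few_visits")
  expect_equal(labs$exclusion_reason[labs$patient_id == "C"],
               "span_too_short")
  expect_equal(labs$exclusion_reason[labs$patient_id == "E"],
               "age_out_of_range")
})

test_that("case exclusions keep same-day marker/event and drop the rest", {
  ev <- dplyr::bind_rows(
    # no documentation before the event
    toy_events("NP", c(50, 60, 90), c("E9500", "X1", "X2")),
    # event before marker
    toy_events("EB", c(0, 5, 50, 100), c("X1", "X2", "E9500", "340")),
    # same-day marker and event, with history
    toy_events("SD", c(0, 30, 60, 60), c("X1", "X2", "340", "E9500")),
    # marker first, with history
    toy_events("MF", c(0, 10, 400), c("340", "X1", "E9500"))
  )
  labs <- find_cases(ev) |>
    apply_inclusion(ev, toy_demographics(c("NP", "EB", "SD", "MF"))) |>
    apply_case_exclusions(ev)
  get <- function(id, col) labs[[col]][labs$patient_id == id]
  expect_equal(get("NP", "exclusion_reason"), "no_prior_data")
  expect_equal(get("EB", "exclusion_reason"), "event_before_marker")
  expect_true(get("SD", "included"))
  expect_true(get("MF", "included"))
})

test_that("a marker-cohort case with no observed marker is event-first", {
  ev <- toy_events("Q", c(0, 10, 50), c("X1", "X2", "E9500"))
  labs <- find_cases(ev) |>
    apply_inclusion(ev, toy_demographics("Q"))
  strict <- apply_case_exclusions(labs, ev, marker_required = TRUE)
  lax <- apply_case_exclusions(labs, ev, marker_required = FALSE)
  expect_equal(strict$exclusion_reason, "event_before_marker")
  expect_true(lax$included)
})

test_that("censoring keeps only strictly pre-event case records", {
  ev <- dplyr::bind_rows(
    toy_events("CA", c(10, 50, 50, 60), c("X1", "E9500", "X2", "X3")),
    toy_events("CO", c(10, 50, 60), paste0("Y", 1:3))
  )
  labs <- find_cases(ev)
  cens <- censor_case_records(ev, labs)
  expect_equal(cens$date[cens$patient_id == "CA"], day0 + 10)
  expect_equal(cens[cens$patient_id == "CO", ], ev[ev$patient_id == "CO", ])
  # idempotence
  expect_equal(censor_case_records(cens, labs), cens)
})

test_that("temporal ordering counts are exhaustive and exclusive", {
  expect_equal(classify_temporal_order(find_cases(empty_event_table_()))
               $n_cases, 0)
  ev <- toy_events("S", c(0, 60, 60), c("X1", "340", "E9500"))
  ord <- classify_temporal_order(find_cases(ev))
  expect_equal(ord$same_day, 1)
  expect_equal(ord$marker_first + ord$event_first, 0)
})

test_that("train/test split is an even, seed-deterministic partition", {
  labs <- small_labels()
  sp1 <- split_train_test(labs, split_seed = 99)
  sp2 <- split_train_test(labs, split_seed = 99)
  expect_identical(sp1, sp2)
  inc <- labs$patient_id[labs$included]
  expect_setequal(sp1$patient_id, inc)
  expect_lte(abs(sum(sp1$arm == "train") - sum(sp1$arm == "test")), 1)

  ten <- tibble::tibble(patient_id = paste0("P", 1:10), is_case = FALSE,
                        included = TRUE, exclusion_reason = "none")
  sp <- split_train_test(ten, split_seed = 1)
  expect_equal(sort(table(sp$arm)), sort(c(train = 5, test = 5)),
               ignore_attr = TRUE)
  eleven <- dplyr::bind_rows(
    ten, tibble::tibble(patient_id = "P11", is_case = FALSE, included = TRUE,
                        exclusion_reason = "none"))
  sp11 <- split_train_test(eleven, split_seed = 1)
  expect_lte(abs(sum(sp11$arm == "train") - sum(sp11$arm == "test")), 1)

  strat <- split_train_test(small_labels(), split_seed = 3,
                            stratify_by_case = TRUE)
  by_arm <- table(strat$arm,
                  small_labels()$is_case[match(strat$patient_id,
                                               small_labels()$patient_id)])
  expect_lte(abs(by_arm["train", "TRUE"] - by_arm["test", "TRUE"]), 1)
})

test_that("exclusion accounting balances on a simulated cohort", {
  cfg <- sim_config(n_patients = 5000, baseline_prevalence = 0.03,
                    no_prior_fraction = 0.2, seed = 21)
  co <- simulate_cohort(cfg)
  labs <- find_cases(co$events) |>
    apply_inclusion(co$events, co$demographics) |>
    apply_case_exclusions(co$events)
  summ <- exclusion_summary(labs)
  n_cases_identified <- sum(labs$is_case)
  expect_equal(sum(summ$n_cases), n_cases_identified)
  # marker-after-event cases occur naturally and are excluded
  expect_gt(summ$n_cases[summ$status == "event_before_marker"], 0)
  # forced history-free cases collapse to a single-day record, so they are
  # caught by the visit-count criterion in a pre-censored event table
  first_day <- co$events |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(first = min(date)) |>
    dplyr::inner_join(co$truth[co$truth$is_case, ], by = "patient_id")
  no_history <- first_day$patient_id[first_day$first >= first_day$event_date]
  expect_gt(length(no_history), 0)
  expect_true(all(!labs$included[labs$patient_id %in% no_history]))
})

test_that("demographic summaries report counts, percentages and sex ratio", {
  demo <- toy_demographics(paste0("P", 1:4))
  demo$sex <- c("F", "F", "F", "M")
  labs <- tibble::tibble(patient_id = paste0("P", 1:4),
                         is_case = c(TRUE, FALSE, FALSE, FALSE))
  summ <- summarize_demographics(labs, demo)
  expect_equal(summ$n_all[summ$feature == "sex" & summ$category == "F"], 3)
  expect_equal(sex_ratio(summ), 3)
  demo$sex <- "F"
  expect_equal(sex_ratio(summarize_demographics(labs, demo)), Inf)
  empty <- summarize_demographics(labs[0, ], demo)
  expect_equal(nrow(empty), 0)
})
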