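# helper: hand-made interval rows for direct fitting
iv_row <- function(person_id, status, days, events,
                   month = "2009-10", mid = as.Date("2009-10-15"),
                   age = 40) {
  data.table::data.table(person_id = person_id, status = status,
                         month = month, days = as.numeric(days),
                         mid_date = mid, age_years = age,
                         events = as.integer(events))
}

test_that("interval construction gives the documented SCRI-pre lengths", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(1, cfg)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = data.table::data.table(
                       person_id = 1L, date = as.Date("2010-01-15"),
                       dose_number = 1L),
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1",
                       date = as.Date("2010-01-20")), cfg = cfg)
  iv <- build_intervals(tabs, "o1", "scri_pre")
  expect_equal(iv[status == "control", sum(days)], 29)  # days -43..-15
  expect_equal(iv[status == "risk", sum(days)], 28)     # days +1..+28
  iv_post <- build_intervals(tabs, "o1", "scri_post")
  expect_equal(iv_post[status == "control", sum(days)], 29)  # days +43..+71
})

test_that("vaccination on the observation start leaves nothing to exclude", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(1, cfg)
  pp$observation_period[, start := cfg$study_start]
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = data.table::data.table(
                       person_id = 1L, date = cfg$study_start,
                       dose_number = 1L),
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1",
                       date = cfg$study_start + 40L), cfg = cfg)
  iv <- build_intervals(tabs, "o1", "sccs_pre30")
  total_days <- as.numeric(cfg$study_end - cfg$study_start) + 1
  # only day 0 (vaccination day) is excluded; 28 risk days; rest control
  expect_equal(iv[status == "risk", sum(days)], 28)
  expect_equal(iv[, sum(days)], total_days - 1)
})

test_that("overlapping windows from two doses resolve risk > excluded > control", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(1, cfg)
  d1 <- as.Date("2009-11-01")
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = data.table::data.table(
                       person_id = 1L, date = c(d1, d1 + 28L),
                       dose_number = 1:2),
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1",
                       date = d1 + 10L), cfg = cfg)
  # dose 2 at day 28: its pre-exclusion window (days -30..0 rel. dose 2)
  # overlaps dose 1's risk window (days 1..28); risk must win
  iv <- build_intervals(tabs, "o1", "sccs_pre30")
  expect_equal(iv[status == "risk", sum(days)], 56)  # days 1..56 after dose 1
  # and in SCRI-post, dose 2's risk window truncates dose 1's control overlap
  ivp <- build_intervals(tabs, "o1", "scri_post")
  # dose-1 control 43..71 rel d1 = days 43..71; dose-2 risk = days 29..56
  # overlap 43..56 goes to risk; dose-2 control 71..99 adds 43..71 rel d2
  expect_equal(ivp[status == "risk", sum(days)], 56 - 28 + 28)
  ctl_days <- ivp[status == "control", sum(days)]
  expect_equal(ctl_days, 43)  # union of days 57..71 and 71..99 rel dose 1
})

test_that("two-interval SCCS matches the closed-form conditional MLE", {
  # one person: 28 risk days with 2 events, 280 control days with 2 events
  iv <- rbind(iv_row(1, "risk", 28, 2), iv_row(1, "control", 280, 2))
  rec <- fit_sccs(iv)
  expect_equal(exp(rec$log_estimate), (2 / 28) / (2 / 280), tolerance = 1e-6)
  # symmetric case: equal lengths and counts
  iv2 <- rbind(iv_row(1, "risk", 28, 2), iv_row(1, "control", 28, 2))
  expect_equal(exp(fit_sccs(iv2)$log_estimate), 1, tolerance = 1e-9)
  # closed-form conditional SE for the two-interval multinomial: sqrt(1/a+1/b)
  expect_equal(rec$se, sqrt(1 / 2 + 1 / 2), tolerance = 1e-6)
})

test_that("SCRI matches the closed-form rate ratio and symmetry", {
  iv <- rbind(iv_row(1, "risk", 28, 2), iv_row(1, "control", 29, 2))
  rec <- fit_scri(iv)
  expect_equal(exp(rec$log_estimate), (2 / 28) / (2 / 29), tolerance = 1e-10)
  # swapping labels inverts the estimate
  iv_sw <- rbind(iv_row(1, "risk", 29, 2), iv_row(1, "control", 28, 2))
  expect_equal(fit_scri(iv_sw)$log_estimate, -rec$log_estimate,
               tolerance = 1e-10)
  # boundary: no risk events -> flagged, finite upper CI
  iv0 <- rbind(iv_row(1, "risk", 28, 0), iv_row(1, "control", 29, 3))
  rec0 <- fit_scri(iv0)
  expect_false(rec0$estimable)
  expect_equal(rec0$ci_lower, 0)
  expect_true(is.finite(rec0$ci_upper))
})

test_that("SCRI estimates ignore events outside both intervals", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(2, cfg)
  d1 <- as.Date("2010-01-15")
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = data.table::data.table(
                       person_id = 1:2, date = d1, dose_number = 1L),
                     outcome = data.table::data.table(
                       person_id = 1:2, outcome_id = "o1",
                       date = c(d1 + 10L, d1 + 100L)), cfg = cfg)
  iv <- build_intervals(tabs, "o1", "scri_pre")
  rec <- fit_scri(iv)
  # person 2's event at day +100 is outside risk and control: contributes 0
  expect_equal(rec$events_exposed + rec$events_comparator, 1)
})

test_that("frailty leaves self-controlled estimates unbiased while rates shift", {
  # same event pattern, per-person rate multipliers do not enter the
  # conditional likelihood: scaling events per person is absorbed
  iv <- rbind(iv_row(1, "risk", 28, 1), iv_row(1, "control", 280, 3),
              iv_row(2, "risk", 28, 2), iv_row(2, "control", 280, 6))
  rec <- fit_sccs(iv)
  # person 2 is a "frail" copy (2x events): estimate equals the shared ratio
  expect_equal(exp(rec$log_estimate), (3 / 28) / (9 / 280), tolerance = 1e-6)
})

test_that("season adjustment is inert when rates carry no seasonality", {
  cfg <- sim_config(n_persons = 10000, seasonal_amplitude = 0,
                    n_negative_controls = 2,
                    baseline_rates = c(0.12, 0.12), seed = 77)
  tabs <- simulate_tables(cfg)
  un <- run_self_controlled(tabs, variant = "sccs_pre30", look_month = 9)
  ad <- run_self_controlled(tabs, variant = "sccs_adj", look_month = 9)
  ok <- un$estimable & ad$estimable
  expect_true(any(ok))
  # with no seasonal signal the spline terms absorb only noise: the adjusted
  # estimate stays within one standard error of the unadjusted one
  expect_lt(max(abs(un$log_estimate[ok] - ad$log_estimate[ok]) / un$se[ok]), 1)
})

test_that("the conditional fit flags boundary and empty configurations", {
  expect_false(fit_sccs(iv_row(1, "risk", 28, 0)[0])$estimable)
  one_side <- rbind(iv_row(1, "risk", 28, 2), iv_row(1, "control", 280, 0))
  rec <- fit_sccs(one_side)
  expect_false(rec$estimable)
  expect_match(rec$note, "boundary")
})
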