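test_that("historic rates follow the events-per-person-time definition", {
  cfg <- sim_config(n_persons = 2)
  # two persons observed through the whole historic period (273 days each)
  pp <- toy_persons(1000, cfg)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1",
                       date = as.Date("2008-10-15")), cfg = cfg)
  r <- historic_rate(tabs, "o1")
  hist_days <- as.numeric(cfg$historic_end - cfg$historic_start) + 1
  py <- 1000 * hist_days / 365.25
  expect_equal(r$events, 1L)
  expect_equal(r$rate, 1000 * 1 / py)
  # zero events, positive person-time -> rate 0, not NA
  tabs0 <- toy_tables(person = pp$person,
                      observation_period = pp$observation_period,
                      outcome = data.table::data.table(
                        person_id = 1L, outcome_id = "o1",
                        date = as.Date("2009-12-01")), cfg = cfg)
  r0 <- historic_rate(tabs0, "o1")
  expect_equal(r0$rate, 0)
})

test_that("stratified rates recombine to the overall rate with person-time weights", {
  tabs <- small_tables()
  overall <- historic_rate(tabs, "neg_003", strata = "none")
  strat <- historic_rate(tabs, "neg_003", strata = "age_sex")
  recombined <- 1000 * sum(strat$events) / sum(strat$person_years)
  expect_equal(recombined, overall$rate, tolerance = 1e-10)
  expect_equal(sum(strat$person_years), overall$person_years,
               tolerance = 1e-8)
})

test_that("post-visit anchor uses only TaR-length windows after one visit per person", {
  cfg <- sim_config(n_persons = 2)
  pp <- toy_persons(10, cfg)
  visits <- data.table::data.table(person_id = c(1L, 1L, 2L),
                                   date = as.Date(c("2008-10-01", "2008-12-01",
                                                    "2009-01-10")))
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     visit_occurrence = visits,
                     outcome = data.table::data.table(
                       person_id = 3L, outcome_id = "o1",
                       date = as.Date("2008-11-01")), cfg = cfg)
  r <- historic_rate(tabs, "o1", anchor = "post_visit", seed = 1)
  # two persons with visits, 28 days each
  expect_equal(r$person_years, 2 * 28 / 365.25, tolerance = 1e-10)
  expect_equal(r$events, 0L)  # person 3 has no visit, contributes nothing
})

test_that("expected counts are person-time-weighted sums of stratum rates", {
  # worked arithmetic: 0.29 / 1,000 py over 156,467 vaccinations x 28 days
  py <- 156467 * 28 / 365.25
  expect_equal(0.29 / 1000 * py, 3.4786, tolerance = 1e-3)

  cfg <- sim_config(n_persons = 2)
  pp <- toy_persons(200, cfg)
  vax <- data.table::data.table(person_id = 1:100,
                                date = as.Date("2009-10-01"),
                                dose_number = 1L)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = vax,
                     outcome = data.table::data.table(
                       person_id = 150L, outcome_id = "o1",
                       date = as.Date("2008-10-01")), cfg = cfg)
  rates <- data.table::data.table(outcome_id = "o1", stratum = "all",
                                  events = 10L, person_years = 1000,
                                  rate = 10)  # 10 per 1,000 py = 0.01/py
  u <- expected_count(rates, tabs)
  expect_equal(u$expected, 0.01 * 100 * 28 / 365.25, tolerance = 1e-10)
  # doubling the rate doubles the expected count (linearity)
  rates2 <- data.table::copy(rates)[, rate := rate * 2]
  expect_equal(expected_count(rates2, tabs)$expected, 2 * u$expected)
})

test_that("TaR person-time is truncated at observation-period end", {
  cfg <- sim_config(n_persons = 2)
  pp <- toy_persons(1, cfg)
  pp$observation_period[, end := as.Date("2009-10-10")]
  vax <- data.table::data.table(person_id = 1L, date = as.Date("2009-10-01"),
                                dose_number = 1L)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = vax,
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1",
                       date = as.Date("2008-10-01")), cfg = cfg)
  rates <- data.table::data.table(outcome_id = "o1", stratum = "all",
                                  events = 1L, person_years = 100, rate = 10)
  u <- expected_count(rates, tabs)
  expect_equal(u$tar_person_years, 9 / 365.25, tolerance = 1e-10)  # days 1..9
})

test_that("IRR estimates match the worked example and exact Poisson machinery", {
  rec <- estimate_irr(14, 3.4)
  expect_equal(exp(rec$log_estimate), 14 / 3.4, tolerance = 1e-10)  # 4.118
  expect_equal(exp(rec$log_estimate), 4.118, tolerance = 1e-3)
  # Garwood interval for c = 14 scaled by u
  expect_equal(rec$ci_lower, qgamma(0.025, 14) / 3.4, tolerance = 1e-10)
  expect_equal(rec$ci_upper, qgamma(0.975, 15) / 3.4, tolerance = 1e-10)
  expect_equal(rec$p_one_sided, ppois(13, 3.4, lower.tail = FALSE))
  expect_equal(rec$llr, poisson_llr(14, 3.4))
  expect_true(rec$estimable)

  expect_equal(exp(estimate_irr(5, 5)$log_estimate), 1.0)
  rec0 <- estimate_irr(0, 3)
  expect_false(rec0$estimable)
  expect_equal(rec0$ci_lower, 0)
  expect_equal(rec0$p_one_sided, 1)  # upper tail P(X >= 0)
})

test_that("instability filter drops >50% rate shifts in either direction", {
  expect_true(instability_filter(1.0, 1.4))    # +40%: keep
  expect_false(instability_filter(1.0, 1.51))  # +51%: drop
  expect_false(instability_filter(2.0, 0.9))   # -55%: drop
  expect_true(instability_filter(2.0, 1.0))    # -50% exactly: keep
  expect_false(instability_filter(0, 0.1))     # rate appeared from nothing
  expect_true(instability_filter(0, 0))
})

test_that("the historical comparator runs across variants on simulated data", {
  tabs <- small_tables()
  for (adj in c(FALSE, TRUE)) {
    est <- run_historical(tabs, adjusted = adj, anchor = "whole_period",
                          look_month = 9, seed = 1)
    expect_equal(nrow(est), 6)
    expect_true(any(est$estimable))
    ok <- est[estimable == TRUE]
    expect_true(all(exp(ok$log_estimate) >= ok$ci_lower &
                    exp(ok$log_estimate) <= ok$ci_upper))
  }
  # filtered variant never yields more estimable rows than unfiltered
  f <- run_historical(tabs, filtered = TRUE, look_month = 9, seed = 1)
  u <- run_historical(tabs, filtered = FALSE, look_month = 9, seed = 1)
  expect_lte(sum(f$estimable), sum(u$estimable))
})
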