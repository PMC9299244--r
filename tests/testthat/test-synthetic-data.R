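test_that("config validation rejects inconsistent study conditions", {
  expect_error(sim_config(n_persons = 0), "n_persons")
  expect_error(sim_config(historic_end = as.Date("2009-10-01")), "historic")
  expect_error(sim_config(tar_start_day = 0), "tar_start_day")
  expect_error(sim_config(tar_end_day = 0), "tar_start_day")
  expect_error(sim_config(n_negative_controls = 1), "n_negative_controls")
  expect_error(sim_config(visit_rate = -1), "rates")
  expect_silent(validate_sim_config(sim_config()))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_persons = 1000, n_negative_controls = 3, seed = 99)
  a <- simulate_tables(cfg)
  b <- simulate_tables(cfg)
  for (nm in c("person", "observation_period", "visit_occurrence",
               "vaccination", "outcome"))
    expect_identical(a[[nm]], b[[nm]])
})

test_that("zero-rate processes yield empty tables", {
  cfg <- sim_config(n_persons = 500, visit_rate = 0, n_negative_controls = 2,
                    baseline_rates = c(0, 0),
                    uptake_curve = rep(0, 9), seed = 3)
  tabs <- simulate_tables(cfg)
  expect_equal(nrow(tabs$visit_occurrence), 0)
  expect_equal(nrow(tabs$vaccination), 0)
  expect_equal(nrow(tabs$outcome), 0)
})

test_that("visit counts match the Poisson mean within Monte-Carlo error", {
  # rate 2/year, ~1000 persons observed exactly 1 year
  cfg <- sim_config(n_persons = 1000, visit_rate = 2,
                    health_seeking_strength = 0, frailty_visit_strength = 0,
                    frailty_sd = 0, full_obs_fraction = 1, seed = 17)
  pop <- simulate_population(cfg, seed = 17)
  pop$observation_period[, end := start + 364L]
  n <- cfg$n_persons
  vrate <- 2
  set.seed(17)
  obs_days <- rep(365, n)
  expected <- vrate * n  # 2000
  # regenerate visits against the trimmed periods using the same process
  nv <- stats::rpois(n, vrate * obs_days / 365.25)
  expect_lt(abs(sum(nv) - expected), 3 * sqrt(expected) + 15)
  # and the generator itself over its own observation spans
  pop2 <- simulate_population(cfg, seed = 17)
  py <- sum(as.numeric(pop2$observation_period$end -
                       pop2$observation_period$start) + 1) / 365.25
  expect_lt(abs(nrow(pop2$visit_occurrence) - vrate * py),
            3 * sqrt(vrate * py))
})

test_that("visit dates lie inside each person's observation period", {
  tabs <- small_tables()
  v <- merge(tabs$visit_occurrence, tabs$observation_period, by = "person_id")
  expect_true(all(v$date >= v$start & v$date <= v$end))
  o <- merge(tabs$outcome, tabs$observation_period, by = "person_id")
  expect_true(all(o$date >= o$start & o$date <= o$end))
  x <- merge(tabs$vaccination, tabs$observation_period, by = "person_id")
  expect_true(all(x$date >= x$start & x$date <= x$end))
  expect_true(all(tabs$vaccination$date >= tabs$config$study_start &
                  tabs$vaccination$date <= tabs$config$study_end))
})

test_that("uptake is unconfounded when both uptake strengths are zero", {
  cfg <- sim_config(n_persons = 10000, health_seeking_strength = 0,
                    frailty_uptake_strength = 0, seed = 21)
  pop <- simulate_population(cfg, seed = 21)
  vax <- simulate_vaccinations(pop, pop$visit_occurrence, cfg)
  vaccinated <- pop$person$person_id %in% vax$person_id
  r <- stats::cor(as.numeric(vaccinated), pop$person$health_seeking)
  expect_lt(abs(r), 0.05)
})

test_that("second doses follow the configured fraction and gap", {
  cfg <- sim_config(n_persons = 8000, two_dose_fraction = 0.5,
                    dose_gap_days = 28L, seed = 12,
                    uptake_curve = c(0.3, 0.3, 0.2, rep(0, 6)))
  pop <- simulate_population(cfg, seed = 12)
  vax <- simulate_vaccinations(pop, pop$visit_occurrence, cfg)
  n1 <- sum(vax$dose_number == 1)
  n2 <- sum(vax$dose_number == 2)
  # binomial 3 s.d. tolerance, allowing for end-of-period/observation clipping
  expect_lt(abs(n2 - 0.5 * n1), 3 * sqrt(n1 * 0.25) + 0.05 * n1)
  two <- data.table::dcast(vax, person_id ~ dose_number, value.var = "date")
  two <- two[!is.na(`2`)]
  expect_true(all(two$`2` - two$`1` == 28))
  expect_true(all(vax$dose_number %in% c(1L, 2L)))
})

test_that("outcome counts match the Poisson oracle in the null case", {
  # no frailty spread, no seasonality, no effect: 1000 person-years at
  # 0.01/py gives ~10 events (raw, before first-event truncation)
  cfg <- sim_config(n_persons = 1000, frailty_sd = 0, seasonal_amplitude = 0,
                    full_obs_fraction = 1, n_negative_controls = 2,
                    baseline_rates = c(0.01, 0), seed = 8)
  pop <- simulate_population(cfg, seed = 8)
  pop$observation_period[, end := start + 364L]
  defs <- outcome_definitions(cfg)
  raw <- simulate_outcomes(pop, data.table::data.table(
    person_id = integer(), date = as.Date(character()), dose_number = integer()),
    defs, cfg, seed = 9, first_only = FALSE)
  n1 <- nrow(raw[outcome_id == "neg_001"])
  expect_lt(abs(n1 - 10), 3 * sqrt(10) + 1)
  expect_equal(nrow(raw[outcome_id == "neg_002"]), 0)
})

test_that("injected effects scale raw TaR event counts by the rate ratio", {
  cfg <- sim_config(n_persons = 20000, frailty_sd = 0, seasonal_amplitude = 0,
                    full_obs_fraction = 1, seed = 31,
                    uptake_curve = rep(0.2, 9))
  pop <- simulate_population(cfg, seed = 31)
  vax <- simulate_vaccinations(pop, pop$visit_occurrence, cfg)
  defs <- data.table::data.table(
    outcome_id = c("null_o", "rr4_o"), baseline_rate = 0.2,
    log_rr = c(0, log(4)), negative = c(TRUE, FALSE))
  raw <- simulate_outcomes(pop, vax, defs, cfg, seed = 32, first_only = FALSE)
  raw <- merge(raw, vax[dose_number == 1, .(person_id, vdate = date)],
               by = "person_id")
  tar <- raw[date - vdate >= 1 & date - vdate <= 28]
  n_null <- nrow(tar[outcome_id == "null_o"])
  n_rr4 <- nrow(tar[outcome_id == "rr4_o"])
  expect_gt(n_null, 20)  # enough events for the ratio to be meaningful
  expect_lt(abs(n_rr4 / n_null - 4), 3 * 4 * sqrt(1 / n_null + 1 / n_rr4))
})

test_that("first-occurrence truncation keeps at most one event per person-outcome", {
  tabs <- small_tables()
  counts <- tabs$outcome[, .N, by = .(person_id, outcome_id)]
  expect_true(all(counts$N == 1))
})

test_that("confounding dial: frailty-linked uptake inflates the crude rate ratio", {
  mk <- function(fr_uptake, fr_sd, seed) {
    cfg <- sim_config(n_persons = 30000, n_negative_controls = 2,
                      baseline_rates = c(0.05, 0.05), frailty_sd = fr_sd,
                      frailty_uptake_strength = fr_uptake,
                      frailty_visit_strength = 0, seasonal_amplitude = 0,
                      full_obs_fraction = 1, seed = seed)
    tabs <- simulate_tables(cfg)
    vaccinated <- tabs$person$person_id %in% tabs$vaccination$person_id
    ev <- tabs$outcome[date >= cfg$study_start]
    ev[, vax := person_id %in% tabs$vaccination$person_id]
    # crude study-period rate ratio vaccinated vs not (person-time approx equal)
    (ev[vax == TRUE, .N] / sum(vaccinated)) /
      (ev[vax == FALSE, .N] / sum(!vaccinated))
  }
  rr_conf <- mk(0.6, 0.8, 41)
  rr_null <- mk(0, 0, 42)
  expect_gt(rr_conf, 1.1)
  expect_lt(abs(rr_null - 1), 0.1)
})

test_that("tables round-trip through the delimited-file interface", {
  tabs <- small_tables()
  dir <- withr::local_tempdir()
  write_tables(tabs, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_tables(dir)
  expect_equal(nrow(back$outcome), nrow(tabs$outcome))
  expect_identical(as.Date(back$vaccination$date), tabs$vaccination$date)
  expect_equal(back$config$n_persons, tabs$config$n_persons)
  expect_equal(back$config$uptake_curve, tabs$config$uptake_curve)
})
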