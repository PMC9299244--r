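test_that("comparator sampling honours anchors, exclusions and the look cutoff", {
  tabs <- small_tables()
  cutoff <- as.Date("2010-01-31")
  now <- vaxeval:::truncate_tables(tabs, cutoff)
  trt <- vaccinated_cohort(now, cutoff)
  expect_true(all(trt$index_date <= cutoff))

  cmp_v <- sample_comparator(now, n = nrow(trt), anchor = "visit",
                             cutoff = cutoff, seed = 2)
  # every visit-anchored comparator has a visit on the index date
  hit <- merge(cmp_v, tabs$visit_occurrence,
               by.x = c("person_id", "index_date"),
               by.y = c("person_id", "date"))
  expect_equal(nrow(unique(hit[, .(person_id, index_date)])), nrow(cmp_v))

  cmp_r <- sample_comparator(now, n = nrow(trt), anchor = "random_day",
                             cutoff = cutoff, seed = 2)
  for (cmp in list(cmp_v, cmp_r)) {
    expect_true(all(cmp$index_date >= tabs$config$study_start &
                    cmp$index_date <= cutoff))
    first_vax <- tabs$vaccination[, .(vax1 = min(date)), by = person_id]
    x <- merge(cmp, first_vax, by = "person_id")
    expect_true(nrow(x) == 0 || all(x$vax1 > x$index_date))
  }
})

test_that("an all-vaccinated candidate pool yields an empty, flagged sample", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(10, cfg)
  vax <- data.table::data.table(person_id = 1:10,
                                date = cfg$study_start,
                                dose_number = 1L)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     vaccination = vax, cfg = cfg)
  cmp <- sample_comparator(tabs, n = 5, anchor = "random_day",
                           cutoff = cfg$study_start, seed = 1)
  expect_equal(nrow(cmp), 0)
  expect_true(attr(cmp, "shortfall"))
})

test_that("covariates are pre-index only and counted by the feature dictionary", {
  tabs <- small_tables()
  cohort <- data.table::data.table(
    person_id = tabs$person$person_id[1:50],
    index_date = as.Date("2010-02-01"), treated = rep(0:1, 25))
  X <- build_covariates(tabs, cohort)
  n_feats <- nrow(tabs$outcome_definitions)
  bands <- data.table::uniqueN(age_band(tabs$person$birth_date[1:50],
                                        as.Date("2010-02-01")))
  # outcome-history dictionary + age + sex + visits + bands + 1 index month
  expect_equal(ncol(X), n_feats + 3 + bands + 1)
  # temporality: an outcome is a covariate only for post-outcome index dates
  ev <- tabs$outcome[date >= as.Date("2009-06-01") & date <= as.Date("2009-12-01")][1]
  one <- data.table::data.table(person_id = rep(ev$person_id, 2),
                                index_date = c(ev$date - 30L, ev$date + 30L),
                                treated = 0:1)
  X1 <- build_covariates(tabs, one)
  col <- paste0("hx_", ev$outcome_id)
  expect_equal(unname(X1[, col]), c(0, 1))
  # a person with no pre-index events has an all-zero history block
  hx <- grep("^hx_", colnames(X))
  expect_true(any(rowSums(X[, hx]) == 0))
})

test_that("propensity scores are null when treatment is random and bounded under separation", {
  set.seed(3)
  n <- 4000
  X <- cbind(matrix(rbinom(n * 5, 1, 0.2), n), age = runif(n, 20, 80))
  colnames(X) <- c(paste0("f", 1:5), "age")
  y <- rbinom(n, 1, 0.5)
  ps <- fit_propensity(X, y, seed = 1)
  expect_lt(abs(ps$auc - 0.5), 0.03)
  expect_true(all(ps$score > 0 & ps$score < 1))
  # perfectly separating covariate: regularisation keeps scores in (0,1)
  Xs <- cbind(X, sep = y)
  ps2 <- fit_propensity(Xs, y, seed = 1)
  expect_true(all(ps2$score > 0 & ps2$score < 1))
  expect_error(fit_propensity(X, rep(1, n)), "comparator")
})

test_that("confounded uptake is detectable in the propensity score", {
  tabs <- small_tables()
  cutoff <- tabs$config$study_end
  trt <- vaccinated_cohort(tabs, cutoff)
  cmp <- sample_comparator(tabs, n = nrow(trt), anchor = "visit",
                           cutoff = cutoff, seed = 9)
  cohort <- rbind(trt, cmp)
  X <- build_covariates(tabs, cohort)
  ps <- fit_propensity(X, cohort$treated, seed = 9)
  expect_gt(ps$auc, 0.52)
})

test_that("matching balances measured covariates and weighting follows ATT", {
  set.seed(8)
  n <- 10000
  x1 <- rnorm(n)
  p <- plogis(-0.5 + 0.6 * x1)
  treated <- rbinom(n, 1, p)
  X <- cbind(x1 = x1, x2 = rnorm(n))
  ps <- fit_propensity(X, treated, seed = 8)
  smd_before <- covariate_balance(X, treated)
  cohort <- data.table::data.table(person_id = 1:n,
                                   index_date = as.Date("2010-01-01"),
                                   treated = treated)
  m <- adjust_cohort(cohort, ps$score, "match")
  idx <- m$person_id
  smd_after <- covariate_balance(X[idx, ], m$treated)
  expect_gt(smd_before["x1"], 0.3)
  expect_lt(smd_after["x1"], 0.1)
  # ATT weights: PS 0.5 comparator weight = 1
  w <- adjust_cohort(cohort, rep(0.5, n), "weight")
  expect_true(all(w$weight == 1))
  # stratification yields five populated strata
  s <- adjust_cohort(cohort, ps$score, "stratify")
  expect_equal(data.table::uniqueN(s$stratum), 5)
})

test_that("identical PS distributions keep essentially all vaccinated in matching", {
  set.seed(12)
  n <- 1000
  cohort <- data.table::data.table(person_id = 1:n,
                                   index_date = as.Date("2010-01-01"),
                                   treated = rep(0:1, n / 2))
  score <- rep(seq(0.2, 0.8, length.out = n / 2), each = 2)
  m <- adjust_cohort(cohort, score, "match")
  expect_gte(sum(m$treated), 0.95 * n / 2)
})

test_that("the hazard ratio matches a hand-built partial likelihood on 3 persons", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(4, cfg)
  idx <- as.Date("2010-01-01")
  # two treated, two comparators; treated 1 fails day 3 (risk set: all four),
  # comparator 1 fails day 8 (risk set: treated 2 and both comparators);
  # the rest are censored at day 28
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     outcome = data.table::data.table(
                       person_id = c(1L, 3L), outcome_id = "o1",
                       date = c(idx + 3L, idx + 8L)), cfg = cfg)
  cohort <- data.table::data.table(person_id = 1:4, index_date = idx,
                                   treated = c(1L, 1L, 0L, 0L),
                                   stratum = 1L, weight = 1)
  rec <- estimate_hr(tabs, cohort, "o1")
  # hand-written Breslow partial likelihood, maximised independently
  pl <- function(b) (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2))
  b_hat <- stats::optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(rec$log_estimate, b_hat, tolerance = 1e-6)
  expect_true(rec$estimable)
  # rank invariance: doubling all event-time offsets leaves the HR unchanged
  tabs2 <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                      outcome = data.table::data.table(
                        person_id = c(1L, 3L), outcome_id = "o1",
                        date = c(idx + 6L, idx + 16L)), cfg = cfg)
  rec2 <- estimate_hr(tabs2, cohort, "o1")
  expect_equal(rec2$log_estimate, rec$log_estimate, tolerance = 1e-8)
})

test_that("identical arms with identical event times give HR 1", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(40, cfg)
  idx <- as.Date("2010-01-01")
  ev_persons <- c(1:5, 21:25)
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     outcome = data.table::data.table(
                       person_id = ev_persons, outcome_id = "o1",
                       date = rep(idx + c(3L, 7L, 11L, 15L, 19L), 2)),
                     cfg = cfg)
  cohort <- data.table::data.table(person_id = 1:40, index_date = idx,
                                   treated = rep(c(1L, 0L), each = 20),
                                   stratum = 1L, weight = 1)
  rec <- estimate_hr(tabs, cohort, "o1")
  expect_equal(rec$log_estimate, 0, tolerance = 1e-8)
})

test_that("zero outcomes in an arm are flagged rather than estimated", {
  cfg <- sim_config(n_persons = 1)
  pp <- toy_persons(10, cfg)
  idx <- as.Date("2010-01-01")
  tabs <- toy_tables(person = pp$person, observation_period = pp$observation_period,
                     outcome = data.table::data.table(
                       person_id = 1L, outcome_id = "o1", date = idx + 5L),
                     cfg = cfg)
  cohort <- data.table::data.table(person_id = 1:10, index_date = idx,
                                   treated = rep(c(1L, 0L), each = 5),
                                   stratum = 1L, weight = 1)
  rec <- estimate_hr(tabs, cohort, "o1")
  expect_false(rec$estimable)
  expect_match(rec$note, "zero outcomes")
})

test_that("per-month matching freezes pairs across subsequent looks", {
  tabs <- small_tables()
  looks <- look_dates(tabs$config)[1:3]
  est <- run_cohort_per_month(tabs, looks, anchor = "visit",
                              outcome_ids = "neg_006", seed = 5)
  expect_equal(nrow(est), 3)
  expect_equal(est$look_month, 1:3)
  # supporting counts accumulate (cumulative data, frozen matches)
  ev <- est$events_exposed + est$events_comparator
  expect_true(all(diff(ev[!is.na(ev)]) >= 0))
})
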