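#' @import data.table
#' @importFrom stats rpois rnorm rbinom runif median qgamma ppois pnorm qnorm
#'   quantile optim sd var binom.test coef vcov glm predict as.formula
#' @importFrom survival coxph clogit strata Surv
NULL

#' Seasonal rate multiplier
#'
#' Sinusoidal modulation of outcome rates over the calendar year:
#' `1 + amplitude * cos(2 * pi * (doy - peak) / 365.25)`.
#'
#' @param dates Date vector.
#' @param cfg A [sim_config()].
#' @return Numeric multiplier, mean 1 over a full year.
#' @export
seasonal_multiplier <- function(dates, cfg) {
  if (cfg$seasonal_amplitude == 0) return(rep(1, length(dates)))
  doy <- as.integer(format(dates, "%j"))
  1 + cfg$seasonal_amplitude *
    cos(2 * pi * (doy - cfg$seasonal_peak_doy) / 365.25)
}

#' Simulate the population: persons, observation periods, outpatient visits
#'
#' Persons carry two latent confounders: a lognormal `frailty` multiplier on
#' outcome rates (mean 1) and a standard-normal `health_seeking` score.
#' Observation periods span from the historic-period start (for
#' `full_obs_fraction` of persons; one year before the study, so those
#' persons always satisfy the 365-day prior-observation rule) or a random
#' later entry date, through the study end (a small fraction leaves early). Outpatient visits follow a per-person
#' homogeneous Poisson process whose rate increases with both latent scores.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return A list with `data.table`s `person` (person_id, sex, birth_date,
#'   frailty, health_seeking, z_frailty), `observation_period` (person_id,
#'   start, end) and `visit_occurrence` (person_id, date).
#' @export
simulate_population <- function(cfg, seed = NULL) {
  validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_persons

  z_f <- rnorm(n)
  person <- data.table(
    person_id = seq_len(n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    birth_date = cfg$study_start -
      as.integer(floor(runif(n, 0, 80) * 365.25)),
    z_frailty = z_f,
    frailty = exp(cfg$frailty_sd * z_f - cfg$frailty_sd^2 / 2),
    health_seeking = rnorm(n)
  )

  full <- runif(n) < cfg$full_obs_fraction
  span <- as.integer(cfg$study_end - cfg$historic_start)
  start <- fifelse(full, cfg$historic_start,
                   cfg$historic_start + as.integer(floor(runif(n, 0, span))))
  end <- rep(cfg$study_end, n)
  early <- runif(n) < 0.05
  gap <- as.integer(cfg$study_end - cfg$study_start)
  end[early] <- cfg$study_start +
    as.integer(floor(runif(sum(early), 0, gap + 1)))
  end <- pmax(end, start + 1L)
  obs <- data.table(person_id = person$person_id, start = start, end = end)

  vrate <- cfg$visit_rate * exp(cfg$health_seeking_strength * person$health_seeking +
                                cfg$frailty_visit_strength * z_f)
  obs_days <- as.numeric(obs$end - obs$start) + 1
  n_visits <- rpois(n, vrate * obs_days / 365.25)
  idx <- rep.int(seq_len(n), n_visits)
  visits <- data.table(
    person_id = person$person_id[idx],
    date = obs$start[idx] +
      as.integer(floor(runif(sum(n_visits)) * obs_days[idx]))
  )
  setkey(visits, person_id, date)

  list(person = person, observation_period = obs, visit_occurrence = visits)
}

#' Simulate confounded vaccination uptake
#'
#' Each study month, unvaccinated persons under observation receive a first
#' dose with probability `uptake_curve[month] * exp(health_seeking_strength *
#' health_seeking + frailty_uptake_strength * z_frailty)` (capped at 1), on a
#' uniform day within the month. A `two_dose_fraction` of vaccinees receives
#' a second dose `dose_gap_days` later when that date is still inside both
#' the study period and their observation period. Dates are restricted to
#' `[study_start, study_end]`.
#'
#' @param persons,visits Tables from [simulate_population()] (`visits` is
#'   part of the generator interface but uptake is driven by the latent
#'   scores, not by realised visit dates).
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `data.table` with columns `person_id`, `date`, `dose_number`.
#' @export
simulate_vaccinations <- function(persons, visits, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  person <- persons$person
  obs <- persons$observation_period
  n <- nrow(person)
  mult <- exp(cfg$health_seeking_strength * person$health_seeking +
              cfg$frailty_uptake_strength * person$z_frailty)

  month_starts <- seq(as.Date(format(cfg$study_start, "%Y-%m-01")),
                      cfg$study_end, by = "month")
  month_starts[1] <- cfg$study_start
  month_ends <- c(month_starts[-1] - 1L, cfg$study_end)
  curve <- rep_len(cfg$uptake_curve, length(month_starts))

  vaccinated <- rep(FALSE, n)
  vax_date <- rep(as.Date(NA), n)
  for (m in seq_along(month_starts)) {
    p <- pmin(curve[m] * mult, 1)
    at_risk <- !vaccinated & obs$start <= month_starts[m] &
      obs$end >= month_starts[m]
    draw <- at_risk & runif(n) < p
    if (any(draw)) {
      width <- as.integer(month_ends[m] - month_starts[m]) + 1L
      d <- month_starts[m] +
        as.integer(floor(runif(sum(draw)) * width))
      d <- pmin(d, obs$end[draw])      # stay inside observation
      vax_date[draw] <- d
      vaccinated <- vaccinated | draw
    }
  }
  first <- data.table(person_id = person$person_id[vaccinated],
                      date = vax_date[vaccinated], dose_number = 1L)
  if (nrow(first) && cfg$two_dose_fraction > 0) {
    gets2 <- runif(nrow(first)) < cfg$two_dose_fraction
    second <- first[gets2]
    second[, date := date + cfg$dose_gap_days]
    second[, dose_number := 2L]
    second <- merge(second, obs, by = "person_id")
    second <- second[date <= pmin(end, cfg$study_end)][, .(person_id, date, dose_number)]
    first <- rbind(first, second)
  }
  setkey(first, person_id, date)
  first[]
}

# Inclusive TaR membership: is event day d in [vax + tar_start, vax + tar_end]
# for any of the person's doses?
.in_tar <- function(event_person, event_date, vaccinations, cfg) {
  if (nrow(vaccinations) == 0L) return(rep(FALSE, length(event_date)))
  ev <- data.table(i = seq_along(event_date), person_id = event_person,
                   date = event_date)
  vx <- vaccinations[, .(person_id, vdate = date)]
  hit <- merge(ev, vx, by = "person_id", allow.cartesian = TRUE)
  hit <- hit[date - vdate >= cfg$tar_start_day & date - vdate <= cfg$tar_end_day]
  out <- rep(FALSE, length(event_date))
  out[unique(hit$i)] <- TRUE
  out
}

#' Simulate outcome occurrences
#'
#' For each person and outcome, event times are drawn from an inhomogeneous
#' Poisson process with rate `baseline_rate * frailty * seasonal *
#' exp(log_rr)` per year inside the person's time-at-risk windows and
#' `baseline_rate * frailty * seasonal` elsewhere, over the whole observation
#' period (historic plus study time). Sampling is by thinning against the
#' constant envelope `baseline * frailty * (1 + amplitude) * exp(max(log_rr,
#' 0))`. By default only the first occurrence per (person, outcome) is
#' retained, matching a first-occurrence outcome definition.
#'
#' @param persons Output of [simulate_population()].
#' @param vaccinations Output of [simulate_vaccinations()].
#' @param outcome_defs Definitions from [outcome_definitions()] (or any
#'   subset with the same columns).
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @param first_only Keep only the first event per (person, outcome)
#'   (default). `FALSE` returns all raw events (useful for rate checks).
#' @return A `data.table` with columns `person_id`, `outcome_id`, `date`.
#' @export
simulate_outcomes <- function(persons, vaccinations, outcome_defs, cfg,
                              seed = NULL, first_only = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(c("outcome_id", "baseline_rate", "log_rr") %in% names(outcome_defs)))
    stop("outcome_defs must have outcome_id, baseline_rate, log_rr", call. = FALSE)
  person <- persons$person
  obs <- persons$observation_period
  obs_days <- as.numeric(obs$end - obs$start) + 1
  amp <- cfg$seasonal_amplitude

  out <- vector("list", nrow(outcome_defs))
  for (j in seq_len(nrow(outcome_defs))) {
    def <- outcome_defs[j]
    envelope <- def$baseline_rate / 365.25 * person$frailty * (1 + amp) *
      exp(max(def$log_rr, 0))
    n_ev <- rpois(nrow(person), envelope * obs_days)
    if (sum(n_ev) == 0L) next
    idx <- rep.int(seq_len(nrow(person)), n_ev)
    d <- obs$start[idx] + as.integer(floor(runif(sum(n_ev)) * obs_days[idx]))
    accept_p <- seasonal_multiplier(d, cfg) / (1 + amp)
    if (def$log_rr != 0) {
      tar <- .in_tar(person$person_id[idx], d, vaccinations, cfg)
      accept_p <- accept_p * exp(def$log_rr * tar) / exp(max(def$log_rr, 0))
    }
    keep <- runif(length(d)) < accept_p
    if (!any(keep)) next
    out[[j]] <- data.table(person_id = person$person_id[idx][keep],
                           outcome_id = def$outcome_id, date = d[keep])
  }
  events <- rbindlist(out)
  if (nrow(events) == 0L)
    return(data.table(person_id = integer(), outcome_id = character(),
                      date = as.Date(character())))
  setorder(events, outcome_id, person_id, date)
  if (first_only)
    events <- events[, .SD[1L], by = .(outcome_id, person_id)]
  setcolorder(events, c("person_id", "outcome_id", "date"))
  setkey(events, outcome_id, person_id)
  events[]
}

#' Simulate a full synthetic database
#'
#' Runs [simulate_population()], [simulate_vaccinations()] and
#' [simulate_outcomes()] under a single seed and returns the five event
#' tables plus the outcome definitions and the config.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param outcome_defs Optional outcome definitions (defaults to
#'   [outcome_definitions()] of `cfg`).
#' @return A list of class `sim_tables`: `person`, `observation_period`,
#'   `visit_occurrence`, `vaccination`, `outcome`, `outcome_definitions`,
#'   `config`.
#' @export
simulate_tables <- function(cfg, seed = cfg$seed, outcome_defs = NULL) {
  set.seed(seed)
  if (is.null(outcome_defs)) outcome_defs <- outcome_definitions(cfg)
  pop <- simulate_population(cfg)
  vax <- simulate_vaccinations(pop, pop$visit_occurrence, cfg)
  outc <- simulate_outcomes(pop, vax, outcome_defs, cfg)
  tabs <- list(person = pop$person,
               observation_period = pop$observation_period,
               visit_occurrence = pop$visit_occurrence,
               vaccination = vax,
               outcome = outc,
               outcome_definitions = outcome_defs,
               config = cfg)
  class(tabs) <- c("sim_tables", "list")
  tabs
}

#' Write or read simulated tables as delimited files
#'
#' Writes the five event tables as CSV with ISO-8601 dates, the outcome
#' definitions, the config as JSON, and a manifest recording the seed and a
#' hash of the serialised config.
#'
#' @param tables A `sim_tables` list from [simulate_tables()].
#' @param dir Output directory (created if needed).
#' @return `write_tables` returns `dir` invisibly; `read_tables` returns a
#'   `sim_tables` list.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("person", "observation_period", "visit_occurrence",
               "vaccination", "outcome", "outcome_definitions"))
    data.table::fwrite(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  write_config(tables$config, file.path(dir, "config.json"))
  cfg_json <- jsonlite::toJSON(unclass(tables$config), auto_unbox = TRUE,
                               digits = NA, Date = "ISO8601")
  manifest <- list(seed = tables$config$seed,
                   config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                                     seq_along(utf8ToInt(as.character(cfg_json)))) %% 0xFFFFFFFF))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_tables
#' @export
read_tables <- function(dir) {
  rd <- function(nm) data.table::fread(file.path(dir, paste0(nm, ".csv")))
  tabs <- list(person = rd("person"),
               observation_period = rd("observation_period"),
               visit_occurrence = rd("visit_occurrence"),
               vaccination = rd("vaccination"),
               outcome = rd("outcome"),
               outcome_definitions = rd("outcome_definitions"),
               config = read_config(file.path(dir, "config.json")))
  for (nm in c("person", "observation_period", "visit_occurrence",
               "vaccination", "outcome")) {
    for (col in intersect(c("date", "start", "end", "birth_date"), names(tabs[[nm]])))
      data.table::set(tabs[[nm]], j = col, value = as.Date(tabs[[nm]][[col]]))
  }
  class(tabs) <- c("sim_tables", "list")
  tabs
}
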