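#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' health-data generator. The defaults describe the default surveillance
#' scenario used throughout the package: a 9-month vaccination campaign
#' (September 2009 through May 2010) with a matching historic period one year
#' earlier, a time-at-risk (TaR) of days 1-28 after vaccination, and 93
#' negative-control outcomes whose true rate ratio is 1.
#'
#' Confounding is controlled by two latent per-person scalars:
#' * `frailty` — a positive multiplier on all outcome rates (lognormal with
#'   log-scale s.d. `frailty_sd`, normalised to mean 1);
#' * `health_seeking` — a standard-normal score raising both the outpatient
#'   visit rate and the vaccination hazard through
#'   `health_seeking_strength`.
#'
#' Frailty can additionally raise the vaccination hazard
#' (`frailty_uptake_strength`; vaccinated persons are then frailer than
#' average, biasing between-person comparisons upward) and the visit rate
#' (`frailty_visit_strength`; persons in care on a given day are then frailer
#' than average, biasing visit-anchored comparators downward).
#'
#' @param n_persons Number of simulated persons.
#' @param study_start,study_end Calendar bounds of the surveillance
#'   (vaccination) period.
#' @param historic_start,historic_end Calendar bounds of the historic period
#'   used by the historical comparator; must precede the study period.
#' @param tar_start_day,tar_end_day Integer day offsets of the time-at-risk
#'   window relative to vaccination, inclusive (defaults 1 and 28).
#' @param n_negative_controls Number of negative-control outcomes (true log
#'   rate ratio 0). At least 2 (the systematic-error fit needs two points).
#' @param baseline_rates Optional numeric vector of per-outcome baseline
#'   rates (events per person-year) for the negative controls; defaults to a
#'   log-spaced grid between `rate_min` and `rate_max`.
#' @param rate_min,rate_max Bounds of the default baseline-rate grid.
#' @param frailty_sd Log-scale s.d. of the per-person frailty multiplier.
#' @param health_seeking_strength Log-linear effect of the health-seeking
#'   score on both the visit rate and the monthly vaccination hazard.
#' @param frailty_uptake_strength Log-linear effect of log-frailty (in s.d.
#'   units) on the vaccination hazard.
#' @param frailty_visit_strength Log-linear effect of log-frailty (in s.d.
#'   units) on the outpatient visit rate.
#' @param visit_rate Baseline outpatient visit rate (visits per person-year).
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal modulation
#'   of outcome rates (0 disables seasonality; must be < 1).
#' @param seasonal_peak_doy Day of year at which the seasonal multiplier
#'   peaks (default 15, mid-January: winter-peaking outcomes).
#' @param uptake_curve Per-calendar-month baseline vaccination probability
#'   over the study period, recycled/truncated to the number of study
#'   months. The default is a campaign peaking two-three months in.
#' @param two_dose_fraction Fraction of vaccinees receiving a second dose.
#' @param dose_gap_days Days between first and second dose.
#' @param true_log_rr_positive Log effect sizes available for injected
#'   positive-control outcomes (defaults `log(c(1.5, 2, 4))`).
#' @param n_injected_per_effect Number of injected positive-control outcomes
#'   per effect size in `true_log_rr_positive` (default 0: the evaluation
#'   pipeline imputes positives from negatives instead).
#' @param full_obs_fraction Fraction of persons observed from
#'   `historic_start` through `study_end` (hence always eligible
#'   on the 365-day prior-observation rule); the rest enter at a uniform
#'   date between `historic_start` and `study_end`.
#' @param seed Integer seed recorded in the config and used by
#'   [simulate_tables()] unless overridden.
#'
#' @return An object of class `sim_config` (a named list, validated).
#' @export
sim_config <- function(n_persons = 20000,
                       study_start = as.Date("2009-09-01"),
                       study_end = as.Date("2010-05-31"),
                       historic_start = as.Date("2008-09-01"),
                       historic_end = as.Date("2009-05-31"),
                       tar_start_day = 1L,
                       tar_end_day = 28L,
                       n_negative_controls = 93L,
                       baseline_rates = NULL,
                       rate_min = 0.008,
                       rate_max = 0.05,
                       frailty_sd = 0.7,
                       health_seeking_strength = 0.5,
                       frailty_uptake_strength = 0.4,
                       frailty_visit_strength = 1.2,
                       visit_rate = 3,
                       seasonal_amplitude = 0.3,
                       seasonal_peak_doy = 15,
                       uptake_curve = c(0.01, 0.04, 0.05, 0.03, 0.02,
                                        0.01, 0.01, 0.005, 0.005),
                       two_dose_fraction = 0,
                       dose_gap_days = 42L,
                       true_log_rr_positive = log(c(1.5, 2, 4)),
                       n_injected_per_effect = 0L,
                       full_obs_fraction = 0.9,
                       seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    historic_start = as.Date(historic_start),
    historic_end = as.Date(historic_end),
    tar_start_day = as.integer(tar_start_day),
    tar_end_day = as.integer(tar_end_day),
    n_negative_controls = as.integer(n_negative_controls),
    baseline_rates = baseline_rates,
    rate_min = rate_min,
    rate_max = rate_max,
    frailty_sd = frailty_sd,
    health_seeking_strength = health_seeking_strength,
    frailty_uptake_strength = frailty_uptake_strength,
    frailty_visit_strength = frailty_visit_strength,
    visit_rate = visit_rate,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_doy = seasonal_peak_doy,
    uptake_curve = uptake_curve,
    two_dose_fraction = two_dose_fraction,
    dose_gap_days = as.integer(dose_gap_days),
    true_log_rr_positive = true_log_rr_positive,
    n_injected_per_effect = as.integer(n_injected_per_effect),
    full_obs_fraction = full_obs_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_persons) || cfg$n_persons < 1)
    stop("n_persons must be a positive integer", call. = FALSE)
  if (cfg$historic_end >= cfg$study_start)
    stop("historic period must precede and not overlap the study period",
         call. = FALSE)
  if (cfg$historic_start >= cfg$historic_end || cfg$study_start >= cfg$study_end)
    stop("period start must precede period end", call. = FALSE)
  if (cfg$tar_start_day < 1L || cfg$tar_end_day < cfg$tar_start_day)
    stop("need tar_start_day >= 1 and tar_end_day >= tar_start_day",
         call. = FALSE)
  if (cfg$n_negative_controls < 2L)
    stop("n_negative_controls must be >= 2", call. = FALSE)
  rates <- c(cfg$baseline_rates, cfg$rate_min, cfg$rate_max, cfg$visit_rate,
             cfg$uptake_curve)
  if (any(rates < 0))
    stop("all rates must be >= 0", call. = FALSE)
  if (cfg$frailty_sd < 0 || cfg$seasonal_amplitude < 0 ||
      cfg$seasonal_amplitude >= 1)
    stop("frailty_sd must be >= 0 and seasonal_amplitude in [0, 1)",
         call. = FALSE)
  if (cfg$two_dose_fraction < 0 || cfg$two_dose_fraction > 1)
    stop("two_dose_fraction must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Outcome definitions for a configuration
#'
#' Expands a `sim_config` into one row per simulated outcome: the negative
#' controls (true log rate ratio 0) followed by any injected positive
#' controls. Baseline rates for negatives default to a log-spaced grid;
#' injected positives reuse the median negative baseline rate.
#'
#' @param cfg A `sim_config`.
#' @return A `data.table` with columns `outcome_id`, `baseline_rate`
#'   (events per person-year), `log_rr` (true log rate ratio during TaR)
#'   and `negative` (logical).
#' @export
outcome_definitions <- function(cfg) {
  n_neg <- cfg$n_negative_controls
  rates <- cfg$baseline_rates
  if (is.null(rates)) {
    rates <- exp(seq(log(cfg$rate_min), log(cfg$rate_max), length.out = n_neg))
  } else {
    rates <- rep_len(rates, n_neg)
  }
  defs <- data.table::data.table(
    outcome_id = sprintf("neg_%03d", seq_len(n_neg)),
    baseline_rate = rates,
    log_rr = 0,
    negative = TRUE
  )
  if (cfg$n_injected_per_effect > 0L) {
    pos <- data.table::CJ(effect = cfg$true_log_rr_positive,
                          rep = seq_len(cfg$n_injected_per_effect))
    pos <- data.table::data.table(
      outcome_id = sprintf("pos_rr%.2g_%02d", exp(pos$effect), pos$rep),
      baseline_rate = stats::median(rates),
      log_rr = pos$effect,
      negative = FALSE
    )
    defs <- rbind(defs, pos)
  }
  defs[]
}

#' Month-end look schedule of a configuration
#'
#' @param cfg A `sim_config`.
#' @return A `Date` vector of calendar month ends covering the study period
#'   (the monthly interim-analysis "looks").
#' @export
look_dates <- function(cfg) {
  first <- as.Date(format(cfg$study_start, "%Y-%m-01"))
  months <- seq(first, cfg$study_end, by = "month")
  ends <- seq(first, by = "month", length.out = length(months) + 1L)[-1L] - 1L
  ends[ends <= cfg$study_end | format(ends, "%Y-%m") == format(cfg$study_end, "%Y-%m")]
}

#' Read or write a configuration as JSON
#'
#' Dates are serialised in ISO-8601. A manifest of the seed and a hash of the
#' serialised config accompanies written simulation tables (see
#' [write_tables()]).
#'
#' @param cfg A `sim_config`.
#' @param path File path of the JSON document.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `sim_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", Date = "ISO8601")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  date_fields <- c("study_start", "study_end", "historic_start", "historic_end")
  for (f in date_fields) raw[[f]] <- as.Date(raw[[f]])
  raw$baseline_rates <- if (length(raw$baseline_rates)) raw$baseline_rates else NULL
  do.call(sim_config, raw[setdiff(names(raw), character())])
}
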