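# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A small but estimable synthetic database used by several design tests.
small_tables <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_persons = 4000, n_negative_controls = 6,
                      rate_min = 0.02, rate_max = 0.08, seed = 2024)
    .fixture_env$small <- simulate_tables(cfg)
  }
  .fixture_env$small
}

# Hand-built sim_tables with fully controlled content, for unit tests of the
# design modules (dates chosen inside the default study period).
toy_tables <- function(person = NULL, observation_period = NULL,
                       visit_occurrence = NULL, vaccination = NULL,
                       outcome = NULL, cfg = sim_config(n_persons = 1)) {
  tabs <- list(
    person = data.table::data.table(person_id = integer(), sex = character(),
                                    birth_date = as.Date(character()),
                                    z_frailty = numeric(), frailty = numeric(),
                                    health_seeking = numeric()),
    observation_period = data.table::data.table(person_id = integer(),
                                                start = as.Date(character()),
                                                end = as.Date(character())),
    visit_occurrence = data.table::data.table(person_id = integer(),
                                              date = as.Date(character())),
    vaccination = data.table::data.table(person_id = integer(),
                                         date = as.Date(character()),
                                         dose_number = integer()),
    outcome = data.table::data.table(person_id = integer(),
                                     outcome_id = character(),
                                     date = as.Date(character())))
  for (nm in names(tabs)) {
    supplied <- get(nm)
    if (!is.null(supplied)) tabs[[nm]] <- data.table::as.data.table(supplied)
  }
  ids <- unique(tabs$outcome$outcome_id)
  tabs$outcome_definitions <- data.table::data.table(
    outcome_id = if (length(ids)) ids else "o1",
    baseline_rate = 0.01, log_rr = 0, negative = TRUE)
  tabs$config <- cfg
  class(tabs) <- c("sim_tables", "list")
  tabs
}

# Simple persons block: n persons, fixed demographics, full observation.
toy_persons <- function(n, cfg = sim_config(n_persons = n),
                        birth = as.Date("1970-06-15"), sex = "F") {
  list(
    person = data.table::data.table(
      person_id = seq_len(n), sex = rep_len(sex, n),
      birth_date = rep(birth, n), z_frailty = 0, frailty = 1,
      health_seeking = 0),
    observation_period = data.table::data.table(
      person_id = seq_len(n), start = cfg$historic_start - 365L,
      end = cfg$study_end))
}
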