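#' Select cases for the case-control design
#'
#' One case per person per outcome: the first outcome occurrence inside the
#' study period up to the look cutoff, with at least 365 days of prior
#' observation. Persons whose first-ever occurrence predates the study
#' period are not cases (the outcome tables hold first occurrences only).
#'
#' @param tables A `sim_tables` list.
#' @param outcome_id Outcome of interest.
#' @param cutoff Look cutoff date.
#' @return A `data.table` with `person_id`, `index_date`.
#' @export
select_cases <- function(tables, outcome_id, cutoff = tables$config$study_end) {
  cfg <- tables$config
  oid <- outcome_id
  ev <- tables$outcome[outcome_id == oid & date >= cfg$study_start &
                       date <= cutoff]
  ev <- merge(ev, tables$observation_period, by = "person_id")
  ev <- ev[start <= date - 365 & end >= date]
  ev[, .(person_id, index_date = date)]
}

#' Sample controls for a set of cases
#'
#' * `matched` — up to 4 controls per case, drawn without replacement within
#'   a set from persons sharing the case's 5-year age band and sex at the
#'   case's index date; the case's outcome date becomes the controls' index.
#' * `random` — up to 4 controls per case drawn from all eligible persons,
#'   with index dates sampled (with replacement) from the empirical
#'   distribution of the cases' outcome dates.
#'
#' Controls must be outcome-free through their index date, observed at
#' index with 365 days of prior observation, and may serve for multiple
#' cases (across sets, not within one).
#'
#' @param tables A `sim_tables` list.
#' @param cases From [select_cases()].
#' @param outcome_id Outcome of interest (controls must be free of it).
#' @param variant `"matched"` or `"random"`.
#' @param controls_per_case Maximum controls per case (default 4).
#' @param seed Optional seed.
#' @return A `data.table` with `set_id`, `person_id`, `index_date`, `case`
#'   (0/1). Cases with zero eligible controls keep their row (dropped later
#'   by the conditional likelihood).
#' @export
sample_controls <- function(tables, cases, outcome_id,
                            variant = c("matched", "random"),
                            controls_per_case = 4L, seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  oid <- outcome_id
  person <- tables$person
  obs <- tables$observation_period
  first_ev <- tables$outcome[outcome_id == oid, .(person_id, ev_date = date)]

  pool <- merge(person[, .(person_id, sex, birth_date)], obs, by = "person_id")
  pool <- merge(pool, first_ev, by = "person_id", all.x = TRUE)
  # numeric working copies (day counts) for fast per-case screening
  p_id <- pool$person_id
  p_birth <- as.numeric(pool$birth_date)
  p_start <- as.numeric(pool$start)
  p_end <- as.numeric(pool$end)
  p_ev <- as.numeric(pool$ev_date)
  p_ev[is.na(p_ev)] <- Inf
  p_male <- pool$sex == "M"

  sets <- vector("list", nrow(cases))
  case_info <- merge(cases, person[, .(person_id, sex, birth_date)],
                     by = "person_id")
  case_dates <- as.numeric(cases$index_date)
  for (i in seq_len(nrow(case_info))) {
    cs <- case_info[i]
    idx <- if (variant == "matched") rep(as.numeric(cs$index_date), length(p_id))
      else sample(case_dates, length(p_id), replace = TRUE)
    ok <- p_id != cs$person_id &
      p_start <= idx - 365 & p_end >= idx & p_ev > idx
    if (variant == "matched") {
      band <- floor((idx - p_birth) / 365.25 / 5)
      cs_band <- floor(as.numeric(cs$index_date - cs$birth_date) / 365.25 / 5)
      ok <- ok & (p_male == (cs$sex == "M")) & band == cs_band
    }
    cand <- which(ok)
    take <- min(controls_per_case, length(cand))
    picked <- if (take > 0) sample(cand, take) else integer()
    sets[[i]] <- data.table::data.table(
      set_id = i,
      person_id = c(cs$person_id, p_id[picked]),
      index_date = as.Date(c(as.numeric(cs$index_date), idx[picked]),
                           origin = "1970-01-01"),
      case = c(1L, rep(0L, take)))
  }
  data.table::rbindlist(sets)
}

#' Vaccine-exposure assessment at the index date
#'
#' A subject is exposed iff any vaccination occurred in the window
#' `[index - tar_end, index - tar_start]` (the mirror image of the TaR;
#' with the defaults, days -28..-1, so a vaccination on the index date
#' itself does not count). Either dose qualifies.
#'
#' @param tables A `sim_tables` list.
#' @param sets From [sample_controls()].
#' @return `sets` with an `exposed` (0/1) column appended.
#' @export
assess_exposure <- function(tables, sets) {
  cfg <- tables$config
  st <- data.table::copy(data.table::as.data.table(sets))
  st[, row := .I]
  hit <- merge(st, tables$vaccination[, .(person_id, vdate = date)],
               by = "person_id", allow.cartesian = TRUE)
  hit <- hit[index_date - vdate >= cfg$tar_start_day &
             index_date - vdate <= cfg$tar_end_day]
  st[, exposed := 0L]
  st[row %in% hit$row, exposed := 1L]
  st[, row := NULL]
  st[]
}

#' Odds-ratio estimate from case-control sets
#'
#' * `matched` — conditional logistic likelihood over the matched sets.
#' * `random` — unconditional logistic regression with 5-year age-band and
#'   sex terms.
#'
#' @param tables A `sim_tables` list (demographics for the adjusted model).
#' @param sets Output of [assess_exposure()].
#' @param variant `"matched"` or `"random"`.
#' @param design,outcome_id,look_month Labels for the estimate row.
#' @return A one-row estimates `data.table` with the log odds ratio;
#'   `estimable = FALSE` with a note when there is no exposure variation or
#'   the conditional likelihood is monotone.
#' @export
estimate_or <- function(tables, sets, variant = c("matched", "random"),
                        design = "case_control", outcome_id = NA_character_,
                        look_month = NA_integer_) {
  variant <- match.arg(variant)
  st <- data.table::as.data.table(sets)
  base <- estimate_record(design, paste0(variant, "_controls"), outcome_id,
                          look_month)
  n_exp_case <- st[case == 1, sum(exposed)]
  n_case <- st[case == 1, .N]
  n_exp_ctl <- st[case == 0, sum(exposed)]
  n_ctl <- st[case == 0, .N]
  base[, `:=`(events_exposed = n_exp_case, events_comparator = n_exp_ctl,
              time_exposed = n_case, time_comparator = n_ctl)]
  if (nrow(st) == 0L || length(unique(st$exposed)) < 2L) {
    base[, note := "no exposure variation"]; return(base)
  }
  if (variant == "matched") {
    fit <- tryCatch(suppressWarnings(
      clogit(case ~ exposed + strata(set_id), data = st)),
      error = function(e) NULL)
  } else {
    st <- merge(st, tables$person[, .(person_id, sex, birth_date)],
                by = "person_id")
    st[, band := age_band(birth_date, index_date)]
    terms <- c("exposed",
               if (data.table::uniqueN(st$band) > 1L) "band",
               if (data.table::uniqueN(st$sex) > 1L) "sex")
    fit <- tryCatch(suppressWarnings(
      stats::glm(as.formula(paste("case ~", paste(terms, collapse = " + "))),
                 family = stats::binomial(), data = st)),
      error = function(e) NULL)
  }
  if (is.null(fit) || !"exposed" %in% names(coef(fit)) ||
      !is.finite(coef(fit)["exposed"])) {
    base[, note := "fit failed"]; return(base)
  }
  b <- coef(fit)["exposed"]
  se_b <- sqrt(vcov(fit)["exposed", "exposed"])
  if (!is.finite(se_b) || se_b > 10 || abs(b) > 10) {
    base[, note := "monotone likelihood"]; return(base)
  }
  base[, `:=`(log_estimate = b, se = se_b,
              ci_lower = exp(b - 1.96 * se_b), ci_upper = exp(b + 1.96 * se_b),
              p_one_sided = one_sided_p(b, se_b), llr = normal_llr(b, se_b),
              estimable = TRUE)]
  base[]
}

#' Run one case-control variant over outcomes at one look
#'
#' @param tables Full `sim_tables`.
#' @param cutoff Look cutoff date.
#' @param variant `"matched"` or `"random"`.
#' @param look_month Look index stored on the rows.
#' @param outcome_ids Outcomes to estimate (default all).
#' @param seed Optional seed.
#' @return Estimates table, one row per outcome.
#' @export
run_case_control <- function(tables, cutoff = tables$config$study_end,
                             variant = c("matched", "random"),
                             look_month = NA_integer_, outcome_ids = NULL,
                             seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  now <- truncate_tables(tables, cutoff)
  out <- vector("list", length(outcome_ids))
  for (i in seq_along(outcome_ids)) {
    oid <- outcome_ids[i]
    cases <- select_cases(now, oid, cutoff)
    if (nrow(cases) == 0L) {
      out[[i]] <- estimate_record("case_control", paste0(variant, "_controls"),
                                  oid, look_month, note = "no cases")
      next
    }
    sets <- sample_controls(now, cases, oid, variant)
    sets <- assess_exposure(now, sets)
    out[[i]] <- estimate_or(now, sets, variant, outcome_id = oid,
                            look_month = look_month)
  }
  data.table::rbindlist(out)
}
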