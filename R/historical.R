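#' Historic incidence rates
#'
#' Estimates the background incidence rate of each outcome during the
#' historic window, either from all observed person-time in the window
#' (`anchor = "whole_period"`) or from TaR-length windows after one random
#' outpatient visit per person (`anchor = "post_visit"`, emulating the
#' visit-anchored background-rate variant). Optionally stratified by 5-year
#' age band and sex.
#'
#' @param tables A `sim_tables` list.
#' @param outcome_ids Outcomes to rate (default: all defined).
#' @param anchor `"whole_period"` or `"post_visit"`.
#' @param strata `"none"` or `"age_sex"`.
#' @param seed Optional seed for the random-visit draw.
#' @return A `data.table` with columns `outcome_id`, `stratum` (`"all"` when
#'   unstratified), `events`, `person_years`, `rate` (events per 1,000
#'   person-years; `NA` where person-time is zero).
#' @export
historic_rate <- function(tables, outcome_ids = NULL,
                          anchor = c("whole_period", "post_visit"),
                          strata = c("none", "age_sex"), seed = NULL) {
  anchor <- match.arg(anchor)
  strata <- match.arg(strata)
  if (!is.null(seed)) set.seed(seed)
  cfg <- tables$config
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  obs <- tables$observation_period
  person <- tables$person

  if (anchor == "whole_period") {
    win <- data.table::data.table(
      person_id = obs$person_id,
      win_start = pmax(obs$start, cfg$historic_start),
      win_end = pmin(obs$end, cfg$historic_end))
    win <- win[win_end >= win_start]
  } else {
    v <- tables$visit_occurrence[date >= cfg$historic_start &
                                 date <= cfg$historic_end]
    v <- merge(v, obs, by = "person_id")
    v <- v[date >= start & date <= end]
    if (nrow(v) == 0L) {
      win <- data.table::data.table(person_id = integer(),
                                    win_start = as.Date(character()),
                                    win_end = as.Date(character()))
    } else {
      # one random outpatient visit per person
      v <- v[sample(.N)][, .SD[1L], by = person_id]
      win <- v[, .(person_id,
                   win_start = date + cfg$tar_start_day,
                   win_end = pmin(date + cfg$tar_end_day, end, cfg$historic_end))]
      win <- win[win_end >= win_start]
    }
  }

  win <- merge(win, person[, .(person_id, sex, birth_date)], by = "person_id")
  win[, stratum := if (strata == "none") "all" else
        paste(age_band(birth_date, win_start), sex, sep = "|")]
  pt <- win[, .(person_years = sum(as.numeric(win_end - win_start) + 1) / 365.25),
            by = stratum]

  ev <- merge(tables$outcome[outcome_id %in% outcome_ids], win,
              by = "person_id", allow.cartesian = TRUE)
  ev <- ev[date >= win_start & date <= win_end]
  counts <- ev[, .(events = .N), by = .(outcome_id, stratum)]

  grid <- data.table::CJ(outcome_id = outcome_ids, stratum = pt$stratum,
                         unique = TRUE)
  out <- merge(grid, counts, by = c("outcome_id", "stratum"), all.x = TRUE)
  out[is.na(events), events := 0L]
  out <- merge(out, pt, by = "stratum")
  out[, rate := data.table::fifelse(person_years > 0,
                                    1000 * events / person_years, NA_real_)]
  data.table::setcolorder(out, c("outcome_id", "stratum", "events",
                                 "person_years", "rate"))
  out[]
}

#' Expected TaR event count among vaccinees
#'
#' `expected = sum over strata of rate_s x TaR person-time of vaccinees in
#' stratum s`, with TaR person-time truncated at observation-period end (and
#' at the look cutoff, since `tables` should already be truncated via the
#' evaluation pipeline). The unstratified variant uses the single overall
#' rate.
#'
#' @param rates Output of [historic_rate()] for one outcome (or several:
#'   expected counts are returned per outcome).
#' @param tables A `sim_tables` list (truncated to the look, if sequential).
#' @param on_missing What to do when vaccinees fall in a stratum with no
#'   historic rate: `"error"` (default; lists the strata) or `"nearest"`
#'   (borrow the rate of the nearest age band with the same sex — used for
#'   vaccinees who aged past the oldest band observed historically).
#' @return A `data.table` with `outcome_id`, `expected`, `tar_person_years`.
#' @export
expected_count <- function(rates, tables, on_missing = c("error", "nearest")) {
  on_missing <- match.arg(on_missing)
  cfg <- tables$config
  vx <- merge(tables$vaccination,
              tables$observation_period, by = "person_id")
  vx <- merge(vx, tables$person[, .(person_id, sex, birth_date)],
              by = "person_id")
  stratified <- !identical(unique(rates$stratum), "all")
  vx[, stratum := if (stratified)
        paste(age_band(birth_date, date), sex, sep = "|") else "all"]
  vx[, py := tar_days(date, end, cfg) / 365.25]
  pt <- vx[, .(py = sum(py)), by = stratum]

  if (stratified && on_missing == "nearest") {
    have <- unique(rates$stratum)
    need <- setdiff(pt$stratum, have)
    if (length(need)) {
      parse_lo <- function(s) as.integer(sub("-.*", "", s))
      parse_sex <- function(s) sub(".*\\|", "", s)
      remap <- vapply(need, function(s) {
        cand <- have[parse_sex(have) == parse_sex(s)]
        if (!length(cand)) cand <- have
        cand[which.min(abs(parse_lo(cand) - parse_lo(s)))]
      }, character(1))
      pt[, stratum := data.table::fifelse(stratum %in% need,
                                          remap[stratum], stratum)]
      pt <- pt[, .(py = sum(py)), by = stratum]
    }
  }
  out <- merge(rates, pt, by = "stratum", all.y = TRUE)
  missing <- out[is.na(rate) & py > 0, unique(stratum)]
  if (length(missing))
    stop("no historic rate defined for strata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- out[, .(expected = sum(rate / 1000 * py), tar_person_years = sum(py)),
             by = outcome_id]
  out[]
}

#' Incidence rate ratio from observed and expected counts
#'
#' Point estimate `c / u` with an exact Poisson (Garwood, gamma-quantile)
#' 95% interval for `c` scaled by `1 / u`; the log-scale SE is the log CI
#' width over `2 * 1.96`; the one-sided p is the Poisson upper tail
#' `P(X >= c | u)`; the LLR is the Poisson MaxSPRT statistic.
#'
#' @param c Observed TaR count.
#' @param u Expected count (> 0).
#' @param design,variant,outcome_id,look_month Labels carried into the
#'   estimate row.
#' @return A one-row estimates `data.table` (see package schema); `c = 0`
#'   yields `estimable = FALSE` with the one-sided p still reported.
#' @export
estimate_irr <- function(c, u, design = "historical_comparator",
                         variant = "unadjusted", outcome_id = NA_character_,
                         look_month = NA_integer_) {
  if (u <= 0) stop("expected count must be > 0", call. = FALSE)
  p <- stats::ppois(c - 1, u, lower.tail = FALSE)
  llr <- poisson_llr(c, u)
  if (c == 0) {
    return(estimate_record(design, variant, outcome_id, look_month,
                           ci_lower = 0,
                           ci_upper = stats::qgamma(0.975, c + 1) / u,
                           p_one_sided = p, llr = llr, estimable = FALSE,
                           events_exposed = c, time_exposed = u,
                           note = "zero observed events"))
  }
  lo <- stats::qgamma(0.025, c) / u
  hi <- stats::qgamma(0.975, c + 1) / u
  se <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  estimate_record(design, variant, outcome_id, look_month,
                  log_estimate = log(c / u), se = se,
                  ci_lower = lo, ci_upper = hi,
                  p_one_sided = p, llr = llr, estimable = TRUE,
                  events_exposed = c, time_exposed = u)
}

#' Rate-instability filter
#'
#' Drops an outcome from the historical comparator when the overall
#' incidence rate has shifted by more than `threshold` (relative) between
#' the historic period and the surveillance period so far.
#'
#' @param r_hist Historic overall rate.
#' @param r_now Surveillance-so-far overall rate.
#' @param threshold Relative change threshold (default 0.5).
#' @return `TRUE` to keep, `FALSE` to drop. A zero historic rate with a
#'   positive current rate drops; both zero keeps.
#' @export
instability_filter <- function(r_hist, r_now, threshold = 0.5) {
  if (r_hist == 0) return(r_now == 0)
  abs(r_now - r_hist) / r_hist <= threshold
}

#' Run one historical-comparator variant over outcomes at one look
#'
#' @param tables Full `sim_tables`.
#' @param cutoff Look cutoff date (data after it is unseen).
#' @param adjusted Age-sex stratified background rate?
#' @param anchor Background-rate anchor (see [historic_rate()]).
#' @param filtered Apply the [instability_filter()]?
#' @param look_month Look index stored on the rows.
#' @param outcome_ids Outcomes to estimate (default all).
#' @param seed Seed for the post-visit anchor draw.
#' @return Estimates table, one row per outcome.
#' @export
run_historical <- function(tables, cutoff = tables$config$study_end,
                           adjusted = FALSE,
                           anchor = c("whole_period", "post_visit"),
                           filtered = FALSE, look_month = NA_integer_,
                           outcome_ids = NULL, seed = NULL) {
  anchor <- match.arg(anchor)
  cfg <- tables$config
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  variant <- paste0(if (adjusted) "age_sex_adj" else "unadjusted",
                    "_", anchor, if (filtered) "_filtered" else "")
  now <- truncate_tables(tables, cutoff)
  rates <- historic_rate(tables, outcome_ids, anchor = anchor,
                         strata = if (adjusted) "age_sex" else "none",
                         seed = seed)
  expected <- expected_count(rates, now, on_missing = "nearest")

  # observed TaR counts up to the cutoff
  vx <- merge(now$vaccination, now$observation_period, by = "person_id")
  ev <- merge(now$outcome[outcome_id %in% outcome_ids],
              vx[, .(person_id, vdate = date, end)],
              by = "person_id", allow.cartesian = TRUE)
  ev <- ev[date - vdate >= cfg$tar_start_day & date - vdate <= cfg$tar_end_day &
           date <= end]
  obs_counts <- ev[, .(c = data.table::uniqueN(person_id)), by = outcome_id]

  if (filtered) {
    overall_hist <- historic_rate(tables, outcome_ids, anchor = "whole_period",
                                  strata = "none")
    win_now <- now$observation_period[, .(person_id,
      win_start = pmax(start, cfg$study_start), win_end = pmin(end, cutoff))]
    win_now <- win_now[win_end >= win_start]
    py_now <- sum(as.numeric(win_now$win_end - win_now$win_start) + 1) / 365.25
    evn <- merge(now$outcome[outcome_id %in% outcome_ids], win_now,
                 by = "person_id")
    evn <- evn[date >= win_start & date <= win_end]
    n_now <- evn[, .(events_now = .N), by = outcome_id]
  }

  out <- vector("list", length(outcome_ids))
  for (i in seq_along(outcome_ids)) {
    oid <- outcome_ids[i]
    u <- expected[outcome_id == oid, expected]
    c_obs <- obs_counts[outcome_id == oid, c]
    if (length(c_obs) == 0L) c_obs <- 0L
    if (length(u) == 0L || is.na(u) || u <= 0) {
      out[[i]] <- estimate_record("historical_comparator", variant, oid,
                                  look_month, note = "no expected count")
      next
    }
    if (filtered) {
      r_h <- overall_hist[outcome_id == oid, rate]
      e_now <- n_now[outcome_id == oid, events_now]
      if (length(e_now) == 0L) e_now <- 0L
      r_n <- if (py_now > 0) 1000 * e_now / py_now else NA_real_
      if (!is.na(r_h) && !is.na(r_n) && !instability_filter(r_h, r_n)) {
        out[[i]] <- estimate_record("historical_comparator", variant, oid,
                                    look_month, note = "instability filtered")
        next
      }
    }
    rec <- estimate_irr(c_obs, u, variant = variant, outcome_id = oid,
                        look_month = look_month)
    out[[i]] <- rec
  }
  data.table::rbindlist(out)
}
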