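# Shared helpers for the design modules.

#' Five-year age bands
#'
#' @param birth_date,at_date Date vectors (recycled).
#' @param width Band width in years (default 5).
#' @return Character band labels such as `"35-39"`.
#' @export
age_band <- function(birth_date, at_date, width = 5) {
  age <- floor(as.numeric(at_date - birth_date) / 365.25)
  lo <- floor(age / width) * width
  sprintf("%d-%d", lo, lo + width - 1)
}

# Days of TaR contributed by each index date, truncated at an end-of-follow-up
# date (observation end and/or look cutoff). Inclusive day offsets.
tar_days <- function(index_date, follow_up_end, cfg) {
  pmax(0, pmin(as.numeric(follow_up_end - index_date), cfg$tar_end_day) -
         cfg$tar_start_day + 1)
}

# One-sided (upper-tail) p-value from a log estimate and its SE.
one_sided_p <- function(log_estimate, se) {
  stats::pnorm(log_estimate / se, lower.tail = FALSE)
}

# Canonical EstimateRecord row. Every design variant funnels its result
# through this constructor so the estimates table has a single schema.
estimate_record <- function(design, variant, outcome_id, look_month = NA_integer_,
                            log_estimate = NA_real_, se = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p_one_sided = NA_real_, llr = NA_real_,
                            estimable = FALSE, true_effect_size = 1,
                            events_exposed = NA_real_, events_comparator = NA_real_,
                            time_exposed = NA_real_, time_comparator = NA_real_,
                            note = NA_character_) {
  data.table::data.table(
    design = design, variant = variant, outcome_id = outcome_id,
    look_month = look_month, true_effect_size = true_effect_size,
    log_estimate = log_estimate, se = se,
    ci_lower = ci_lower, ci_upper = ci_upper,
    p_one_sided = p_one_sided, llr = llr,
    estimable = estimable,
    events_exposed = events_exposed, events_comparator = events_comparator,
    time_exposed = time_exposed, time_comparator = time_comparator,
    note = note
  )
}

# Overlap in days of [s1, e1] and [s2, e2], inclusive; 0 when disjoint.
overlap_days <- function(s1, e1, s2, e2) {
  pmax(0, as.numeric(pmin(e1, e2) - pmax(s1, s2)) + 1)
}

# Restrict a sim_tables list to data observable at a look cutoff: events and
# vaccinations on or before the cutoff, observation periods truncated there.
truncate_tables <- function(tables, cutoff) {
  out <- tables
  out$visit_occurrence <- tables$visit_occurrence[date <= cutoff]
  out$vaccination <- tables$vaccination[date <= cutoff]
  out$outcome <- tables$outcome[date <= cutoff]
  obs <- data.table::copy(tables$observation_period)
  obs[, end := pmin(end, cutoff)]
  out$observation_period <- obs[start <= end]
  out
}
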