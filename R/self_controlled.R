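#' Build person-interval sets for self-controlled designs
#'
#' Partitions each vaccinated case's in-study observed time into `risk`,
#' `control` and `excluded` day sets, per variant:
#'
#' * `sccs_pre30` — risk is days `tar_start..tar_end` after each dose;
#'   days -30..0 around each dose are excluded; all remaining observed
#'   in-study time is control. (Used by both the unadjusted and the
#'   age+season-adjusted SCCS.)
#' * `sccs_allpost` — all time before day `tar_start` of the first dose is
#'   excluded; control is observed time after the TaR.
#' * `scri_pre` — control is exactly days -43..-15 before each dose.
#' * `scri_post` — control is exactly days +43..+71 after each dose.
#'
#' Overlaps (e.g. from two doses) are resolved with precedence
#' risk > excluded > control. Day 0 (the vaccination day) is never risk or
#' control time.
#'
#' @param tables A `sim_tables` list (already truncated to a look where
#'   applicable).
#' @param outcome_id The outcome whose cases define the person set.
#' @param variant One of `"sccs_pre30"`, `"sccs_allpost"`, `"scri_pre"`,
#'   `"scri_post"`.
#' @param person_ids Optional explicit person set; defaults to vaccinated
#'   persons with an event for `outcome_id`.
#' @return A `data.table` with one row per (person, interval): `person_id`,
#'   `status` (`"risk"`/`"control"`), `month` (calendar month of the
#'   sub-interval), `days`, `mid_date`, `age_years`, `events`. Excluded time
#'   is dropped. Persons lacking risk or control time, or whose event fell
#'   in excluded time, contribute rows that [fit_sccs()]/[fit_scri()]
#'   handle via the conditional likelihood.
#' @export
build_intervals <- function(tables, outcome_id,
                            variant = c("sccs_pre30", "sccs_allpost",
                                        "scri_pre", "scri_post"),
                            person_ids = NULL) {
  variant <- match.arg(variant)
  cfg <- tables$config
  oid <- outcome_id
  vax <- tables$vaccination
  ev <- tables$outcome[outcome_id == oid]
  if (is.null(person_ids))
    person_ids <- intersect(unique(vax$person_id), unique(ev$person_id))
  if (length(person_ids) == 0L)
    return(data.table::data.table(person_id = integer(), status = character(),
                                  month = character(), days = numeric(),
                                  mid_date = as.Date(character()),
                                  age_years = numeric(), events = integer()))
  obs <- tables$observation_period[person_id %in% person_ids]
  person <- tables$person[person_id %in% person_ids, .(person_id, birth_date)]
  vax <- vax[person_id %in% person_ids]
  ev <- ev[person_id %in% person_ids]

  # one row per observed in-study day per person (day painting, vectorised)
  win <- obs[, .(person_id, w0 = pmax(start, cfg$study_start),
                 w1 = pmin(end, cfg$study_end))][w1 >= w0]
  if (nrow(win) == 0L)
    return(data.table::data.table(person_id = integer(), status = character(),
                                  month = character(), days = numeric(),
                                  mid_date = as.Date(character()),
                                  age_years = numeric(), events = integer()))
  len <- as.integer(win$w1 - win$w0) + 1L
  dt <- data.table::data.table(
    person_id = rep.int(win$person_id, len),
    date = win$w0[rep.int(seq_len(nrow(win)), len)] +
      (sequence(len) - 1L))
  # status priority: 0 none, 1 control, 2 excluded, 3 risk
  dt[, status_code := if (startsWith(variant, "scri")) 0L else 1L]

  doses <- vax[, .(person_id, vdate = date)]
  dd <- merge(dt[, .(person_id, date)], doses, by = "person_id",
              allow.cartesian = TRUE)
  dd[, rel := as.numeric(date - vdate)]
  paint <- function(cond, code) {
    hit <- dd[cond, .(person_id, date)]
    if (nrow(hit))
      dt[unique(hit), on = c("person_id", "date"),
         status_code := pmax(status_code, code)]
  }
  if (variant == "sccs_pre30") {
    paint(dd$rel >= -30 & dd$rel <= 0, 2L)
  } else if (variant == "sccs_allpost") {
    d1 <- doses[, .(d1 = min(vdate)), by = person_id]
    dt[d1, on = "person_id",
       status_code := fifelse(date < d1 + cfg$tar_start_day,
                              pmax(status_code, 2L), status_code)]
  } else if (variant == "scri_pre") {
    paint(dd$rel >= -43 & dd$rel <= -15, 1L)
  } else {
    paint(dd$rel >= 43 & dd$rel <= 71, 1L)
  }
  paint(dd$rel >= cfg$tar_start_day & dd$rel <= cfg$tar_end_day, 3L)

  dt <- dt[status_code %in% c(1L, 3L)]
  dt[, status := data.table::fifelse(status_code == 3L, "risk", "control")]
  dt[, event := 0L]
  if (nrow(ev))
    dt[ev[, .(person_id, date)], on = c("person_id", "date"), event := 1L]
  dt[, month := format(date, "%Y-%m")]
  res <- dt[, .(days = as.numeric(.N), mid_date = date[ceiling(.N / 2)],
                events = sum(event)),
            by = .(person_id, status, month)]
  if (nrow(res) == 0L)
    return(data.table::data.table(person_id = integer(), status = character(),
                                  month = character(), days = numeric(),
                                  mid_date = as.Date(character()),
                                  age_years = numeric(), events = integer()))
  res <- merge(res, person, by = "person_id")
  res[, age_years := as.numeric(mid_date - birth_date) / 365.25]
  res[, birth_date := NULL]
  res[]
}

# Cubic B-spline basis with 5 equally spaced interior knots over the
# in-sample range; degenerate (near-constant) inputs collapse to nothing.
.spline5 <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-8) return(NULL)
  knots <- seq(r[1], r[2], length.out = 7)[2:6]
  splines::bs(x, knots = knots, degree = 3, Boundary.knots = r)
}

#' Fit the SCCS conditional Poisson model
#'
#' Conditional on each person's total event count, events are multinomial
#' across that person's intervals with rates proportional to
#' `interval length * exp(beta * risk + spline terms)`. The model is fitted
#' as a Poisson regression with person fixed effects and a log-length
#' offset, which profiles to the same conditional estimates. The adjusted
#' variant adds cubic B-spline bases (5 interior knots) over age and over
#' calendar time (season), shared across persons.
#'
#' @param intervals Output of [build_intervals()].
#' @param adjust `"none"` or `"age_season"`.
#' @param design,variant,outcome_id,look_month Labels for the estimate row.
#' @return A one-row estimates `data.table` with the log incidence rate
#'   ratio for risk vs. control time, SE, 95% CI, one-sided p, binomial
#'   MaxSPRT LLR, and audit counts (events and days in/out of TaR).
#' @export
fit_sccs <- function(intervals, adjust = c("none", "age_season"),
                     design = "sccs", variant = "sccs_pre30",
                     outcome_id = NA_character_, look_month = NA_integer_) {
  adjust <- match.arg(adjust)
  iv <- data.table::as.data.table(intervals)
  # informative persons: >= 1 event in included time and both interval types
  iv <- iv[, if (sum(events) > 0 &&
                 all(c("risk", "control") %in% status)) .SD,
           by = person_id]
  base <- estimate_record(design, variant, outcome_id, look_month)
  if (nrow(iv) == 0L) { base[, note := "no informative cases"]; return(base) }

  counts <- iv[, .(ev = sum(events), d = sum(days)), by = status]
  c_risk <- counts[status == "risk", sum(ev)]
  c_ctl <- counts[status == "control", sum(ev)]
  d_risk <- counts[status == "risk", sum(d)]
  d_ctl <- counts[status == "control", sum(d)]
  fill_counts <- function(rec) {
    rec[, `:=`(events_exposed = c_risk, events_comparator = c_ctl,
               time_exposed = d_risk, time_comparator = d_ctl,
               llr = binomial_llr(c_risk, c_risk + c_ctl, d_ctl / d_risk))]
    rec
  }
  if (c_risk == 0 || c_ctl == 0) {
    base <- fill_counts(base)
    base[, note := "boundary: all events on one side"]
    return(base)
  }

  if (adjust == "none") {
    dat <- iv[, .(events = sum(events), days = sum(days)),
              by = .(person_id, status)]
  } else dat <- iv
  dat[, risk := as.integer(status == "risk")]
  dat[, pid := factor(person_id)]
  pid_term <- if (data.table::uniqueN(dat$pid) > 1L) "pid" else NULL
  sp_terms <- NULL
  if (adjust == "age_season") {
    sa <- .spline5(dat$age_years)
    ss <- .spline5(as.numeric(dat$mid_date))
    X <- cbind(sa, ss)
    if (!is.null(X)) {
      for (j in seq_len(ncol(X))) dat[[paste0("sp", j)]] <- X[, j]
      sp_terms <- paste0("sp", seq_len(ncol(X)))
    }
  }
  form <- as.formula(paste("events ~",
                           paste(c("risk", sp_terms, pid_term,
                                   "offset(log(days))"), collapse = " + ")))
  fit <- tryCatch(stats::glm(form, family = stats::poisson(), data = dat),
                  error = function(e) NULL, warning = function(w)
                    suppressWarnings(stats::glm(form, family = stats::poisson(),
                                                data = dat)))
  if (is.null(fit) || !is.finite(coef(fit)["risk"])) {
    base <- fill_counts(base); base[, note := "fit failed"]; return(base)
  }
  b <- coef(fit)["risk"]
  se_b <- sqrt(vcov(fit)["risk", "risk"])
  if (!is.finite(se_b) || se_b > 10 || abs(b) > 10) {
    base <- fill_counts(base); base[, note := "monotone likelihood"]; return(base)
  }
  rec <- estimate_record(design, variant, outcome_id, look_month,
                         log_estimate = b, se = se_b,
                         ci_lower = exp(b - 1.96 * se_b),
                         ci_upper = exp(b + 1.96 * se_b),
                         p_one_sided = one_sided_p(b, se_b), estimable = TRUE)
  fill_counts(rec)
}

#' Fit the SCRI conditional binomial model
#'
#' Conditional on the total number of events in the risk plus control
#' intervals, risk-interval events are binomial with null proportion
#' `L_risk / (L_risk + L_ctl)`. The point estimate is
#' `log[(c_risk / L_risk) / (c_ctl / L_ctl)]`; the CI is the exact
#' (Clopper-Pearson) binomial interval for the risk proportion mapped to the
#' rate-ratio scale; the one-sided p is the exact binomial upper tail.
#'
#' @param intervals Output of [build_intervals()] for an SCRI variant.
#' @inheritParams fit_sccs
#' @return A one-row estimates `data.table`.
#' @export
fit_scri <- function(intervals, design = "scri", variant = "scri_pre",
                     outcome_id = NA_character_, look_month = NA_integer_) {
  iv <- data.table::as.data.table(intervals)
  iv <- iv[, if (sum(events) > 0 &&
                 all(c("risk", "control") %in% status)) .SD,
           by = person_id]
  base <- estimate_record(design, variant, outcome_id, look_month)
  if (nrow(iv) == 0L) { base[, note := "no informative cases"]; return(base) }
  c_r <- iv[status == "risk", sum(events)]
  c_c <- iv[status == "control", sum(events)]
  L_r <- iv[status == "risk", sum(days)]
  L_c <- iv[status == "control", sum(days)]
  n <- c_r + c_c
  p0 <- L_r / (L_r + L_c)
  z <- L_c / L_r
  llr <- binomial_llr(c_r, n, z)
  p_one <- stats::pbinom(c_r - 1, n, p0, lower.tail = FALSE)
  base[, `:=`(events_exposed = c_r, events_comparator = c_c,
              time_exposed = L_r, time_comparator = L_c,
              llr = llr, p_one_sided = p_one)]
  bt <- stats::binom.test(c_r, n, p = p0)
  ci_p <- bt$conf.int
  to_irr <- function(p) (p / (1 - p)) * z   # proportion -> rate ratio
  if (c_r == 0 || c_c == 0) {
    base[, `:=`(ci_lower = if (c_r == 0) 0 else to_irr(ci_p[1]),
                ci_upper = if (c_c == 0) Inf else to_irr(ci_p[2]),
                note = "boundary: all events on one side")]
    return(base)
  }
  b <- log((c_r / L_r) / (c_c / L_c))
  lo <- to_irr(ci_p[1]); hi <- to_irr(ci_p[2])
  se_b <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  base[, `:=`(log_estimate = b, se = se_b, ci_lower = lo, ci_upper = hi,
              estimable = TRUE)]
  base[]
}

#' Run one self-controlled variant over outcomes at one look
#'
#' Variants: `sccs_pre30` (unadjusted), `sccs_adj` (age+season-adjusted,
#' same intervals as `sccs_pre30`), `scri_pre`, `scri_post`,
#' `sccs_allpost`.
#'
#' @param tables Full `sim_tables`.
#' @param cutoff Look cutoff date.
#' @param variant Variant name (above).
#' @param look_month Look index stored on the rows.
#' @param outcome_ids Outcomes to estimate (default all).
#' @return Estimates table, one row per outcome.
#' @export
run_self_controlled <- function(tables, cutoff = tables$config$study_end,
                                variant = c("sccs_pre30", "sccs_adj",
                                            "scri_pre", "scri_post",
                                            "sccs_allpost"),
                                look_month = NA_integer_, outcome_ids = NULL) {
  variant <- match.arg(variant)
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  now <- truncate_tables(tables, cutoff)
  iv_variant <- if (variant == "sccs_adj") "sccs_pre30" else variant
  design <- if (startsWith(variant, "scri")) "scri" else "sccs"
  out <- vector("list", length(outcome_ids))
  for (i in seq_along(outcome_ids)) {
    iv <- build_intervals(now, outcome_ids[i], iv_variant)
    out[[i]] <- if (design == "scri") {
      fit_scri(iv, variant = variant, outcome_id = outcome_ids[i],
               look_month = look_month)
    } else {
      fit_sccs(iv, adjust = if (variant == "sccs_adj") "age_season" else "none",
               variant = variant, outcome_id = outcome_ids[i],
               look_month = look_month)
    }
  }
  data.table::rbindlist(out)
}
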