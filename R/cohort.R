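#' Assemble the vaccinated cohort at a look
#'
#' One index date per vaccination (first and second doses are separate index
#' dates), restricted to vaccinations on or before the cutoff with at least
#' 365 days of prior continuous observation.
#'
#' @param tables A `sim_tables` list.
#' @param cutoff Look cutoff date.
#' @return A `data.table` with `person_id`, `index_date`, `treated = 1`.
#' @export
vaccinated_cohort <- function(tables, cutoff = tables$config$study_end) {
  vx <- merge(tables$vaccination[date <= cutoff],
              tables$observation_period, by = "person_id")
  vx <- vx[start <= date - 365 & end >= date]
  vx[, .(person_id, index_date = date, treated = 1L)]
}

#' Sample a comparator cohort
#'
#' Draws non-vaccinated comparator index dates either from outpatient visit
#' dates (`anchor = "visit"`) or uniformly within each candidate's
#' observation period intersected with the study period and the look cutoff
#' (`anchor = "random_day"`). Persons with a vaccination on or before the
#' candidate index date are excluded; all comparators need 365 days of
#' prior observation. At most one index date per comparator person is
#' sampled.
#'
#' @param tables A `sim_tables` list.
#' @param n Target comparator count (typically `ratio * n_vaccinated`).
#' @param anchor `"visit"` or `"random_day"`.
#' @param cutoff Look cutoff date.
#' @param window Optional `c(start, end)` restriction on comparator index
#'   dates (used by per-month matching); defaults to study start through the
#'   cutoff.
#' @param seed Optional seed.
#' @return A `data.table` with `person_id`, `index_date`, `treated = 0`, and
#'   attribute `shortfall` (TRUE when fewer than `n` eligible comparators
#'   existed).
#' @export
sample_comparator <- function(tables, n, anchor = c("visit", "random_day"),
                              cutoff = tables$config$study_end,
                              window = NULL, seed = NULL) {
  anchor <- match.arg(anchor)
  if (!is.null(seed)) set.seed(seed)
  cfg <- tables$config
  if (is.null(window)) window <- c(cfg$study_start, cutoff)
  win_lo <- pmax(as.Date(window[1]), cfg$study_start)
  win_hi <- pmin(as.Date(window[2]), cutoff)
  obs <- tables$observation_period
  first_vax <- if (nrow(tables$vaccination))
    tables$vaccination[, .(vax1 = min(date)), by = person_id]
  else data.table::data.table(person_id = integer(), vax1 = as.Date(character()))

  if (anchor == "visit") {
    pool <- tables$visit_occurrence[date >= win_lo & date <= win_hi]
    pool <- merge(pool, obs, by = "person_id")
    pool <- pool[start <= date - 365 & end >= date]
    pool <- merge(pool, first_vax, by = "person_id", all.x = TRUE)
    pool <- pool[is.na(vax1) | vax1 > date]
    if (nrow(pool) == 0L) {
      out <- data.table::data.table(person_id = integer(),
                                    index_date = as.Date(character()),
                                    treated = integer())
      data.table::setattr(out, "shortfall", TRUE)
      return(out)
    }
    # sample visit-days (persons enter proportionally to their visit
    # frequency, as for an on-the-day-of-a-visit index); at most one index
    # date per person
    pool <- pool[sample(.N)][!duplicated(person_id)]
    take <- min(n, nrow(pool))
    out <- pool[seq_len(take), .(person_id, index_date = date, treated = 0L)]
  } else {
    cand <- merge(obs, first_vax, by = "person_id", all.x = TRUE)
    cand[, lo := pmax(start + 365L, win_lo)]
    cand[, hi := pmin(end, win_hi,
                      data.table::fifelse(is.na(vax1), as.Date("9999-01-01"),
                                          vax1 - 1L))]
    cand <- cand[hi >= lo]
    if (nrow(cand) == 0L) {
      out <- data.table::data.table(person_id = integer(),
                                    index_date = as.Date(character()),
                                    treated = integer())
      data.table::setattr(out, "shortfall", TRUE)
      return(out)
    }
    take <- min(n, nrow(cand))
    cand <- cand[sample(.N, take)]
    cand[, index_date := lo + as.integer(floor(runif(.N) *
                                               (as.numeric(hi - lo) + 1)))]
    out <- cand[, .(person_id, index_date, treated = 0L)]
  }
  data.table::setattr(out, "shortfall", nrow(out) < n)
  out
}

#' Build the covariate matrix for a cohort
#'
#' Binary indicators for the presence of each simulated outcome concept in
#' the 365-day pre-index lookback window, plus demographics (continuous age,
#' 5-year age-band dummies, sex), the calendar month of index, and the
#' prior-year outpatient visit count. Strictly pre-index information only.
#'
#' @param tables A `sim_tables` list.
#' @param cohort Rows with `person_id`, `index_date` (as from
#'   [vaccinated_cohort()] / [sample_comparator()]).
#' @return A numeric matrix, one row per cohort row.
#' @export
build_covariates <- function(tables, cohort) {
  ch <- data.table::as.data.table(cohort)[, .(person_id, index_date)]
  ch[, row := .I]
  feats <- tables$outcome_definitions$outcome_id

  hist <- merge(ch, tables$outcome, by = "person_id", allow.cartesian = TRUE)
  hist <- hist[date >= index_date - 365 & date <= index_date - 1]
  M <- matrix(0, nrow(ch), length(feats),
              dimnames = list(NULL, paste0("hx_", feats)))
  if (nrow(hist))
    M[cbind(hist$row, match(hist$outcome_id, feats))] <- 1

  vis <- merge(ch, tables$visit_occurrence, by = "person_id",
               allow.cartesian = TRUE)
  vis <- vis[date >= index_date - 365 & date <= index_date - 1,
             .(n_visits = .N), by = row]
  nv <- numeric(nrow(ch)); nv[vis$row] <- vis$n_visits

  demo <- merge(ch, tables$person[, .(person_id, sex, birth_date)],
                by = "person_id", sort = FALSE)
  data.table::setorder(demo, row)
  age <- as.numeric(demo$index_date - demo$birth_date) / 365.25
  dummies <- function(x, prefix) {   # one column per level, any level count
    lv <- sort(unique(x))
    m <- matrix(0, length(x), length(lv),
                dimnames = list(NULL, paste0(prefix, lv)))
    m[cbind(seq_along(x), match(x, lv))] <- 1
    m
  }
  demo_m <- cbind(age = age,
                  sex_m = as.numeric(demo$sex == "M"),
                  n_visits = nv,
                  dummies(age_band(demo$birth_date, demo$index_date), "band"),
                  dummies(format(demo$index_date, "%Y-%m"), "month"))
  cbind(M, demo_m)
}

#' Fit a regularised propensity model
#'
#' L1-penalised (lasso) logistic regression of treatment on the covariates,
#' with the penalty chosen by cross-validation and an unpenalised intercept.
#'
#' @param covariates Matrix from [build_covariates()].
#' @param treated 0/1 treatment labels.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Optional seed (fold assignment).
#' @return A list: `score` (propensity in (0,1)), `model` (the fitted
#'   `cv.glmnet`), `auc` (in-sample concordance of score vs. label).
#' @export
fit_propensity <- function(covariates, treated, nfolds = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(treated)) < 2L)
    stop("both treated and comparator subjects are required", call. = FALSE)
  keep <- apply(covariates, 2, function(x) stats::sd(x) > 0)
  x <- covariates[, keep, drop = FALSE]
  fit <- glmnet::cv.glmnet(x, treated, family = "binomial", alpha = 1,
                           nfolds = nfolds)
  score <- as.numeric(predict(fit, newx = x, s = "lambda.min",
                              type = "response"))
  score <- pmin(pmax(score, 1e-6), 1 - 1e-6)
  r <- rank(score)
  n1 <- sum(treated == 1); n0 <- sum(treated == 0)
  auc <- (sum(r[treated == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(score = score, model = fit, auc = auc)
}

# Greedy 1:1 nearest-neighbour matching on logit(PS) without replacement,
# caliper in s.d. units of logit(PS). Returns integer pair ids (NA =
# unmatched), aligned with the input rows.
match_ps <- function(score, treated, caliper_sd = 0.2) {
  lg <- log(score / (1 - score))
  cal <- caliper_sd * stats::sd(lg)
  trt <- which(treated == 1)
  cmp <- which(treated == 0)
  pair <- rep(NA_integer_, length(score))
  if (length(trt) == 0L || length(cmp) == 0L) return(pair)
  cmp <- cmp[order(lg[cmp])]
  cl <- lg[cmp]
  avail <- rep(TRUE, length(cmp))
  pid <- 0L
  for (t in trt[order(-lg[trt])]) {   # hardest-to-match (highest PS) first
    pos <- findInterval(lg[t], cl)
    best <- NA_integer_; bestd <- cal
    lo <- pos; hi <- pos + 1L
    repeat {
      dl <- if (lo >= 1L) lg[t] - cl[lo] else Inf
      dh <- if (hi <= length(cl)) cl[hi] - lg[t] else Inf
      if (dl > bestd && dh > bestd) break
      if (dl <= dh) {
        if (avail[lo] && dl <= bestd) { best <- lo; bestd <- dl }
        lo <- lo - 1L
      } else {
        if (avail[hi] && dh <= bestd) { best <- hi; bestd <- dh }
        hi <- hi + 1L
      }
      if (!is.na(best)) break  # nearest available within caliper found
    }
    if (!is.na(best)) {
      pid <- pid + 1L
      pair[t] <- pid
      pair[cmp[best]] <- pid
      avail[best] <- FALSE
    }
  }
  pair
}

#' Propensity-score adjustment of a cohort
#'
#' * `match` — greedy 1:1 nearest-neighbour matching on logit(PS) with a
#'   caliper of 0.2 s.d. of logit(PS); unmatched subjects are dropped and
#'   pairs become strata.
#' * `stratify` — PS quintiles (within the current data) become strata.
#' * `weight` — ATT weights: 1 for the vaccinated, `PS / (1 - PS)` for
#'   comparators, truncated at the 99th percentile of the comparator
#'   weights.
#'
#' @param cohort Combined cohort rows (`person_id`, `index_date`,
#'   `treated`).
#' @param score Propensity scores aligned with `cohort`.
#' @param method `"match"`, `"stratify"` or `"weight"`.
#' @return The cohort with columns `stratum` (match/stratify) and/or
#'   `weight` added; matched variants contain only matched rows.
#' @export
adjust_cohort <- function(cohort, score, method = c("match", "stratify", "weight")) {
  method <- match.arg(method)
  ch <- data.table::copy(data.table::as.data.table(cohort))
  ch[, weight := 1]
  if (method == "match") {
    pair <- match_ps(score, ch$treated)
    ch[, stratum := pair]
    ch <- ch[!is.na(stratum)]
  } else if (method == "stratify") {
    q <- stats::quantile(score, probs = seq(0.2, 0.8, 0.2), type = 7)
    ch[, stratum := findInterval(score, unique(q)) + 1L]
  } else {
    w <- ifelse(ch$treated == 1, 1, score / (1 - score))
    cap <- stats::quantile(w[ch$treated == 0], 0.99)
    ch[, weight := pmin(w, cap)]
    ch[, stratum := 1L]
  }
  ch[]
}

#' Standardised mean differences of covariates between arms
#'
#' @param covariates Covariate matrix.
#' @param treated 0/1 labels.
#' @param weight Optional weights.
#' @return Named vector of |SMD| per covariate.
#' @export
covariate_balance <- function(covariates, treated, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(treated))
  wm <- function(x, w) sum(x * w) / sum(w)
  wv <- function(x, w) { m <- wm(x, w); sum(w * (x - m)^2) / sum(w) }
  apply(covariates, 2, function(x) {
    m1 <- wm(x[treated == 1], weight[treated == 1])
    m0 <- wm(x[treated == 0], weight[treated == 0])
    v <- (wv(x[treated == 1], weight[treated == 1]) +
          wv(x[treated == 0], weight[treated == 0])) / 2
    if (v < 1e-12) 0 else abs(m1 - m0) / sqrt(v)
  })
}

#' Hazard-ratio estimate for one outcome on an adjusted cohort
#'
#' Time to first outcome within the TaR (days `tar_start..tar_end` after
#' index), censored at TaR end, observation end, the look cutoff, and — for
#' comparators — the day before any later vaccination. A Cox proportional
#' hazards model (Breslow ties) is fitted, stratified by matched pair or PS
#' stratum where present and weighted (with robust SE) for the weighting
#' variant.
#'
#' @param tables A `sim_tables` list (truncated to the look).
#' @param cohort Adjusted cohort from [adjust_cohort()] (or unadjusted rows
#'   with `treated`; missing `stratum`/`weight` are treated as single
#'   stratum, unit weight).
#' @param outcome_id Outcome to estimate.
#' @param design,variant,look_month Labels for the estimate row.
#' @return A one-row estimates `data.table` with the log hazard ratio.
#' @export
estimate_hr <- function(tables, cohort, outcome_id, design = "cohort",
                        variant = "unadjusted", look_month = NA_integer_) {
  cfg <- tables$config
  oid <- outcome_id
  ch <- data.table::as.data.table(cohort)
  if (!"stratum" %in% names(ch)) ch <- data.table::copy(ch)[, stratum := 1L]
  if (!"weight" %in% names(ch)) ch[, weight := 1]
  base <- estimate_record(design, variant, oid, look_month)
  if (nrow(ch) == 0L || length(unique(ch$treated)) < 2L) {
    base[, note := "empty arm"]; return(base)
  }

  ch <- merge(ch, tables$observation_period, by = "person_id", sort = FALSE)
  first_vax <- if (nrow(tables$vaccination))
    tables$vaccination[, .(vax1 = min(date)), by = person_id]
  else data.table::data.table(person_id = integer(), vax1 = as.Date(character()))
  ch <- merge(ch, first_vax, by = "person_id", all.x = TRUE, sort = FALSE)
  # follow-up end: TaR end, observation end, or (comparators) vaccination - 1
  fu_end <- pmin(ch$index_date + cfg$tar_end_day, ch$end)
  later_vax <- ch$treated == 0 & !is.na(ch$vax1)
  fu_end[later_vax] <- pmin(fu_end[later_vax], ch$vax1[later_vax] - 1L)
  ev <- merge(ch[, .(person_id, index_date, row = .I)],
              tables$outcome[outcome_id == oid, .(person_id, edate = date)],
              by = "person_id", sort = FALSE)
  ev <- ev[edate >= index_date + cfg$tar_start_day]
  edate <- rep(as.Date(NA), nrow(ch))
  if (nrow(ev)) edate[ev$row] <- ev$edate
  has_event <- !is.na(edate) & edate <= fu_end
  t_end <- data.table::fifelse(has_event, as.numeric(edate - ch$index_date),
                               as.numeric(fu_end - ch$index_date))
  keep <- t_end >= cfg$tar_start_day
  ch2 <- ch[keep]
  t2 <- t_end[keep] - cfg$tar_start_day + 1
  e2 <- as.integer(has_event[keep])

  n_ev_t <- sum(e2[ch2$treated == 1]); n_ev_c <- sum(e2[ch2$treated == 0])
  base[, `:=`(events_exposed = n_ev_t, events_comparator = n_ev_c,
              time_exposed = sum(t2[ch2$treated == 1]) / 365.25,
              time_comparator = sum(t2[ch2$treated == 0]) / 365.25)]
  if (n_ev_t == 0 || n_ev_c == 0) {
    base[, note := "zero outcomes in an arm"]; return(base)
  }

  weighted <- any(ch2$weight != 1)
  dat <- data.frame(t = t2, e = e2, treated = ch2$treated,
                    stratum = ch2$stratum, w = ch2$weight,
                    id = ch2$person_id)
  fit <- tryCatch(suppressWarnings(
    coxph(Surv(t, e) ~ treated + strata(stratum),
                    data = dat, weights = w, ties = "breslow",
                    robust = weighted, id = if (weighted) dat$id else NULL)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(coef(fit)[1])) {
    base[, note := "fit failed"]; return(base)
  }
  b <- coef(fit)[1]
  se_b <- sqrt(diag(vcov(fit)))[1]
  if (!is.finite(se_b) || se_b > 10 || abs(b) > 10) {
    base[, note := "monotone likelihood"]; return(base)
  }
  base[, `:=`(log_estimate = b, se = se_b,
              ci_lower = exp(b - 1.96 * se_b), ci_upper = exp(b + 1.96 * se_b),
              p_one_sided = one_sided_p(b, se_b), llr = normal_llr(b, se_b),
              estimable = TRUE)]
  base[]
}

#' Run one cohort-method variant over outcomes at one look
#'
#' Crosses the comparator anchor (`visit` / `random_day`) with the
#' adjustment (`none`, `ps_match`, `ps_stratify`, `ps_weight`). Unadjusted
#' variants sample a comparator of equal size; adjusted variants sample
#' `ratio` times the vaccinated cohort (default 2, the pandemic-scenario
#' ratio). One propensity model is fitted per look and anchor and shared by
#' all outcomes.
#'
#' @param tables Full `sim_tables`.
#' @param cutoff Look cutoff date.
#' @param anchor `"visit"` or `"random_day"`.
#' @param adjustment `"none"`, `"ps_match"`, `"ps_stratify"`, `"ps_weight"`.
#' @param ratio Comparator:vaccinated sampling ratio (default 1 unadjusted,
#'   2 adjusted).
#' @param look_month Look index stored on the rows.
#' @param outcome_ids Outcomes to estimate (default all).
#' @param seed Optional seed.
#' @return Estimates table, one row per outcome.
#' @export
run_cohort <- function(tables, cutoff = tables$config$study_end,
                       anchor = c("visit", "random_day"),
                       adjustment = c("none", "ps_match", "ps_stratify",
                                      "ps_weight"),
                       ratio = NULL, look_month = NA_integer_,
                       outcome_ids = NULL, seed = NULL) {
  anchor <- match.arg(anchor)
  adjustment <- match.arg(adjustment)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ratio)) ratio <- if (adjustment == "none") 1L else 2L
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  variant <- paste0(adjustment, "_", anchor)
  now <- truncate_tables(tables, cutoff)

  trt <- vaccinated_cohort(now, cutoff)
  if (nrow(trt) == 0L)
    return(data.table::rbindlist(lapply(outcome_ids, function(o)
      estimate_record("cohort", variant, o, look_month,
                      note = "empty vaccinated cohort"))))
  cmp <- sample_comparator(now, n = ratio * nrow(trt), anchor = anchor,
                           cutoff = cutoff)
  cohort <- rbind(trt, cmp)

  if (adjustment == "none") {
    adj <- data.table::copy(cohort)[, `:=`(stratum = 1L, weight = 1)]
  } else {
    X <- build_covariates(now, cohort)
    ps <- fit_propensity(X, cohort$treated)
    adj <- adjust_cohort(cohort, ps$score,
                         method = sub("ps_", "", adjustment))
    if (adjustment == "ps_match") adj <- adj[, .(person_id, index_date,
                                                 treated, stratum, weight)]
  }
  data.table::rbindlist(lapply(outcome_ids, function(o)
    estimate_hr(now, adj, o, variant = variant, look_month = look_month)))
}
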