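#' Calendar month number of a look date
#'
#' Months of data accumulated at each look: 1 for a look in the first study
#' month, and so on.
#'
#' @param dates Look cutoff dates.
#' @param cfg A [sim_config()].
#' @return Integer month numbers.
#' @export
month_number <- function(dates, cfg) {
  y0 <- as.integer(format(cfg$study_start, "%Y"))
  m0 <- as.integer(format(cfg$study_start, "%m"))
  12L * (as.integer(format(dates, "%Y")) - y0) +
    (as.integer(format(dates, "%m")) - m0) + 1L
}

#' The full grid of evaluated design variants
#'
#' @return A `data.table` with columns `design`, `variant` listing all 25
#'   method variations: 2 case-control, 10 cohort, 8 historical comparator,
#'   5 self-controlled.
#' @export
design_grid <- function() {
  data.table::rbindlist(list(
    data.table::data.table(design = "case_control",
                           variant = c("matched_controls", "random_controls")),
    data.table::data.table(design = "cohort", variant = c(
      "none_visit", "ps_match_visit", "ps_stratify_visit", "ps_weight_visit",
      "none_random_day", "ps_match_random_day", "ps_stratify_random_day",
      "ps_weight_random_day",
      "per_month_match_visit", "per_month_match_random_day")),
    data.table::data.table(design = "historical_comparator", variant = c(
      "unadjusted_whole_period", "age_sex_adj_whole_period",
      "unadjusted_post_visit", "age_sex_adj_post_visit",
      "unadjusted_whole_period_filtered", "age_sex_adj_whole_period_filtered",
      "unadjusted_post_visit_filtered", "age_sex_adj_post_visit_filtered")),
    data.table::data.table(design = "sccs",
                           variant = c("sccs_pre30", "sccs_adj", "sccs_allpost")),
    data.table::data.table(design = "scri", variant = c("scri_pre", "scri_post"))
  ))
}

#' Run one design variant at one look
#'
#' Dispatcher used by [run_grid()]; see the per-design `run_*` functions.
#'
#' @param tables Full `sim_tables`.
#' @param design,variant Row of [design_grid()] (per-month cohort variants
#'   are handled by [run_cohort_per_month()] instead).
#' @param cutoff,look_month Look cutoff date and index.
#' @param outcome_ids Outcomes to estimate.
#' @param seed Optional seed.
#' @return Estimates table.
#' @export
run_design <- function(tables, design, variant,
                       cutoff = tables$config$study_end,
                       look_month = NA_integer_, outcome_ids = NULL,
                       seed = NULL) {
  switch(design,
    case_control = run_case_control(
      tables, cutoff, variant = sub("_controls$", "", variant),
      look_month = look_month, outcome_ids = outcome_ids, seed = seed),
    cohort = {
      anchor <- if (grepl("random_day$", variant)) "random_day" else "visit"
      adjustment <- sub("_(visit|random_day)$", "", variant)
      run_cohort(tables, cutoff, anchor = anchor, adjustment = adjustment,
                 look_month = look_month, outcome_ids = outcome_ids,
                 seed = seed)
    },
    historical_comparator = run_historical(
      tables, cutoff,
      adjusted = grepl("age_sex_adj", variant),
      anchor = if (grepl("post_visit", variant)) "post_visit" else "whole_period",
      filtered = grepl("filtered", variant),
      look_month = look_month, outcome_ids = outcome_ids, seed = seed),
    sccs = ,
    scri = run_self_controlled(tables, cutoff, variant = variant,
                               look_month = look_month,
                               outcome_ids = outcome_ids),
    stop("unknown design: ", design, call. = FALSE))
}

#' Per-month PS matching across the look schedule
#'
#' Each calendar month's vaccinated and a comparator sample drawn from that
#' month are used to fit a month-specific propensity model and perform 1:1
#' matching; the matching is frozen and carried into all subsequent looks.
#' Estimates at each look use the accumulated matched population.
#'
#' @param tables Full `sim_tables`.
#' @param looks Look cutoff dates (month ends).
#' @param anchor Comparator anchor (`"visit"` / `"random_day"`).
#' @param ratio Comparator sampling ratio per month (default 2).
#' @param outcome_ids Outcomes to estimate (default all).
#' @param seed Optional seed.
#' @return Estimates table across all looks.
#' @export
run_cohort_per_month <- function(tables, looks, anchor = c("visit", "random_day"),
                                 ratio = 2L, outcome_ids = NULL, seed = NULL) {
  anchor <- match.arg(anchor)
  if (!is.null(seed)) set.seed(seed)
  cfg <- tables$config
  months <- month_number(looks, cfg)
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  variant <- paste0("per_month_match_", anchor)
  matched <- NULL
  stratum_offset <- 0L
  out <- vector("list", length(looks))
  for (k in seq_along(looks)) {
    cutoff <- looks[k]
    now <- truncate_tables(tables, cutoff)
    m_start <- as.Date(format(cutoff, "%Y-%m-01"))
    trt_m <- vaccinated_cohort(now, cutoff)
    trt_m <- trt_m[index_date >= m_start]
    if (nrow(trt_m) > 0L) {
      cmp_m <- sample_comparator(now, n = ratio * nrow(trt_m), anchor = anchor,
                                 cutoff = cutoff, window = c(m_start, cutoff))
      month_cohort <- rbind(trt_m, cmp_m)
      if (nrow(cmp_m) > 0L && length(unique(month_cohort$treated)) == 2L) {
        X <- build_covariates(now, month_cohort)
        adj <- tryCatch({
          ps <- fit_propensity(X, month_cohort$treated)
          adjust_cohort(month_cohort, ps$score, method = "match")
        }, error = function(e) NULL)
        if (!is.null(adj) && nrow(adj)) {
          adj[, stratum := stratum + stratum_offset]
          stratum_offset <- max(adj$stratum)
          matched <- rbind(matched,
                           adj[, .(person_id, index_date, treated, stratum,
                                   weight)])
        }
      }
    }
    out[[k]] <- if (is.null(matched) || nrow(matched) == 0L) {
      data.table::rbindlist(lapply(outcome_ids, function(o)
        estimate_record("cohort", variant, o, months[k],
                        note = "no matched pairs")))
    } else {
      data.table::rbindlist(lapply(outcome_ids, function(o)
        estimate_hr(now, matched, o, variant = variant,
                    look_month = months[k])))
    }
  }
  data.table::rbindlist(out)
}

#' Run the full evaluation grid
#'
#' For every look month and every design variant, estimates every outcome on
#' the data accumulated through that month; imputes positive controls from
#' each look's estimable negative-control estimates (factors `k`); computes
#' per-(variant, outcome) MaxSPRT critical values from the observed look
#' schedule; and applies leave-one-out empirical calibration per (design,
#' variant, look). Any estimation failure yields an explicit
#' `estimable = FALSE` row, never an aborted grid.
#'
#' @param tables Full `sim_tables` from [simulate_tables()].
#' @param designs Subset of [design_grid()] (default: all 25 variants).
#' @param looks Look cutoff dates (default [look_dates()] of the config).
#' @param outcome_ids Outcomes (default all defined).
#' @param k Positive-control imputation factors.
#' @param alpha MaxSPRT alpha.
#' @param cv_reps Monte-Carlo replicates per critical value.
#' @param seed Seed for all grid-level randomness.
#' @param verbose Log progress to stderr.
#' @return An estimates `data.table`: one row per (design, variant, outcome,
#'   look, true effect size) with uncalibrated and calibrated p-values and
#'   LLRs and the critical value (`cv`) column.
#' @export
run_grid <- function(tables, designs = design_grid(), looks = NULL,
                     outcome_ids = NULL, k = c(1.5, 2, 4), alpha = 0.05,
                     cv_reps = 2e4, seed = 1L, verbose = FALSE) {
  cfg <- tables$config
  if (is.null(looks)) looks <- look_dates(cfg)
  if (is.null(outcome_ids)) outcome_ids <- tables$outcome_definitions$outcome_id
  months <- month_number(looks, cfg)
  set.seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  res <- vector("list", nrow(designs))
  for (d in seq_len(nrow(designs))) {
    des <- designs$design[d]; var <- designs$variant[d]
    say("running %s / %s", des, var)
    if (des == "cohort" && grepl("^per_month_match", var)) {
      rows <- tryCatch(
        run_cohort_per_month(tables, looks,
                             anchor = if (grepl("random_day$", var))
                               "random_day" else "visit",
                             outcome_ids = outcome_ids,
                             seed = seed + d),
        error = function(e) NULL)
    } else {
      rows <- data.table::rbindlist(lapply(seq_along(looks), function(i)
        tryCatch(run_design(tables, des, var, cutoff = looks[i],
                            look_month = months[i], outcome_ids = outcome_ids,
                            seed = seed + 1000L * d + i),
                 error = function(e) {
                   say("  look %d failed: %s", i, conditionMessage(e))
                   data.table::rbindlist(lapply(outcome_ids, function(o)
                     estimate_record(des, var, o, months[i],
                                     note = paste("stage failure:",
                                                  conditionMessage(e)))))
                 })))
    }
    res[[d]] <- rows
  }
  est <- data.table::rbindlist(res, fill = TRUE)

  # impute positives from each look's estimable negatives
  negs <- est[estimable == TRUE & true_effect_size == 1]
  pos <- data.table::rbindlist(lapply(k, function(kk) impute_positive(negs, kk)))
  est <- rbind(est, pos, fill = TRUE)

  est <- attach_critical_values(est, alpha = alpha, cv_reps = cv_reps,
                                seed = seed + 777L)
  est <- loo_calibrate(est)
  data.table::setorder(est, design, variant, outcome_id, true_effect_size,
                       look_month)
  est[]
}

#' Attach MaxSPRT critical values to an estimates table
#'
#' One critical value per (design, variant, outcome): the Poisson model on
#' the cumulative expected counts for the historical comparator, the
#' binomial model on the cumulative total supporting events (with the
#' final-look control-to-risk time ratio) for all other designs.
#'
#' @param est Estimates table from the grid (negative-control rows are used
#'   to define each outcome's schedule; positives inherit their parent's
#'   critical value).
#' @param alpha MaxSPRT alpha.
#' @param cv_reps Monte-Carlo replicates.
#' @param seed Seed.
#' @return The table with a `cv` column.
#' @export
attach_critical_values <- function(est, alpha = 0.05, cv_reps = 2e4, seed = 1L) {
  est <- data.table::copy(est)
  est[, cv := NA_real_]
  keys <- unique(est[true_effect_size == 1,
                     .(design, variant, outcome_id)])
  set.seed(seed)
  for (i in seq_len(nrow(keys))) {
    ky <- keys[i]
    sub <- est[ky, on = c("design", "variant", "outcome_id")]
    sub <- sub[true_effect_size == 1][order(look_month)]
    if (all(is.na(sub$look_month))) next
    cv_val <- tryCatch({
      if (ky$design == "historical_comparator") {
        sched <- cummax(data.table::nafill(sub$time_exposed, fill = 0))
        if (max(sched) <= 0) NA_real_ else
          critical_value(sched, alpha, "poisson", mc_reps = cv_reps)$value
      } else {
        tot <- data.table::nafill(sub$events_exposed, fill = 0) +
          data.table::nafill(sub$events_comparator, fill = 0)
        sched <- cummax(tot)
        te <- rev(sub$time_exposed); tc <- rev(sub$time_comparator)
        te <- te[!is.na(te)][1]; tc <- tc[!is.na(tc)][1]
        if (max(sched) <= 0 || is.na(te) || is.na(tc) || te <= 0 || tc <= 0)
          NA_real_
        else critical_value(sched, alpha, "binomial", z = tc / te,
                            mc_reps = cv_reps)$value
      }
    }, error = function(e) NA_real_)
    est[ky, on = c("design", "variant", "outcome_id"), cv := cv_val]
  }
  est[]
}

#' Type 1 error over negative controls
#'
#' Fraction of estimable negative-control rows rejecting the null: one-sided
#' p below `alpha` (default), or LLR above the critical value when
#' `sequential = TRUE`.
#'
#' @param records Estimates rows (filter to the look(s) of interest first).
#' @param use_calibrated Use calibrated p/LLR columns.
#' @param sequential Use the MaxSPRT rule `llr > cv` instead of the p-value.
#' @param alpha Rejection threshold for the p-value rule.
#' @return A fraction in `[0, 1]`, or `NA` (with a warning) when no
#'   estimable negatives are present.
#' @export
type1_error <- function(records, use_calibrated = FALSE, sequential = FALSE,
                        alpha = 0.05) {
  r <- data.table::as.data.table(records)[true_effect_size == 1 &
                                          estimable == TRUE]
  if (nrow(r) == 0L) { warning("no estimable negatives"); return(NA_real_) }
  if (sequential) {
    llr <- if (use_calibrated) r$llr_calibrated else r$llr
    mean(!is.na(llr) & !is.na(r$cv) & llr > r$cv)
  } else {
    p <- if (use_calibrated) r$p_calibrated else r$p_one_sided
    mean(!is.na(p) & p < alpha)
  }
}

#' Type 2 error over positive controls of one true effect size
#'
#' @inheritParams type1_error
#' @param true_effect_size Imputed effect size (1.5, 2 or 4).
#' @return Fraction of estimable positives of that size NOT rejected.
#' @export
type2_error <- function(records, true_effect_size, use_calibrated = FALSE,
                        sequential = FALSE, alpha = 0.05) {
  k <- true_effect_size
  r <- data.table::as.data.table(records)[true_effect_size == k &
                                          estimable == TRUE]
  if (nrow(r) == 0L) { warning("no estimable positives"); return(NA_real_) }
  if (sequential) {
    llr <- if (use_calibrated) r$llr_calibrated else r$llr
    1 - mean(!is.na(llr) & !is.na(r$cv) & llr > r$cv)
  } else {
    p <- if (use_calibrated) r$p_calibrated else r$p_one_sided
    1 - mean(!is.na(p) & p < alpha)
  }
}

#' Months to a target sensitivity
#'
#' For each true effect size, the earliest look by which at least `target`
#' of that size's positive-control outcomes have signalled (calibrated LLR
#' above the critical value at that or an earlier look; signals persist).
#'
#' @param records Sequential estimates rows for one (design, variant).
#' @param target Sensitivity target (default 0.5).
#' @param use_calibrated Use the calibrated LLR (default TRUE).
#' @return A `data.table` with `true_effect_size`, `months` (NA = never).
#' @export
time_to_sensitivity <- function(records, target = 0.5, use_calibrated = TRUE) {
  r <- data.table::as.data.table(records)[true_effect_size > 1]
  sizes <- sort(unique(r$true_effect_size))
  out <- data.table::data.table(true_effect_size = sizes,
                                months = NA_integer_)
  for (i in seq_along(sizes)) {
    rk <- r[true_effect_size == sizes[i]]
    n_out <- data.table::uniqueN(rk$outcome_id)
    if (n_out == 0L) next
    first_hit <- rk[
      , .(first = {
        l <- if (use_calibrated) llr_calibrated else llr
        h <- which(!is.na(l) & !is.na(cv) & l > cv &
                   !is.na(look_month))
        if (length(h)) min(look_month[h]) else NA_integer_
      }), by = outcome_id]
    looks <- sort(unique(r$look_month))
    for (m in looks) {
      sens <- sum(!is.na(first_hit$first) & first_hit$first <= m) / n_out
      if (sens >= target) { out$months[i] <- m; break }
    }
  }
  out[]
}

#' Performance summary over the grid
#'
#' One row per (design, variant): uncalibrated and calibrated type 1 error
#' (final-look p-value rule and sequential MaxSPRT rule), type 2 error per
#' true effect size, and months to 50% sensitivity per true effect size.
#'
#' @param est Full estimates table from [run_grid()].
#' @param target Sensitivity target for the timeliness metric.
#' @return A `data.table` of performance results.
#' @export
summarize_performance <- function(est, target = 0.5) {
  est <- data.table::as.data.table(est)
  final_look <- max(est$look_month, na.rm = TRUE)
  sizes <- sort(unique(est[true_effect_size > 1, true_effect_size]))
  groups <- unique(est[, .(design, variant)])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- est[groups[g], on = c("design", "variant")]
    fin <- sub[look_month == final_look]
    row <- data.table::data.table(
      design = groups$design[g], variant = groups$variant[g],
      type1 = suppressWarnings(type1_error(fin)),
      type1_calibrated = suppressWarnings(type1_error(fin, use_calibrated = TRUE)),
      type1_sequential = suppressWarnings(type1_error(sub, sequential = TRUE)),
      type1_sequential_calibrated =
        suppressWarnings(type1_error(sub, use_calibrated = TRUE,
                                     sequential = TRUE)))
    for (kk in sizes) {
      row[[sprintf("type2_rr%g", kk)]] <-
        suppressWarnings(type2_error(fin, kk))
      row[[sprintf("type2_rr%g_calibrated", kk)]] <-
        suppressWarnings(type2_error(fin, kk, use_calibrated = TRUE))
    }
    tts <- time_to_sensitivity(sub, target = target)
    for (i in seq_len(nrow(tts)))
      row[[sprintf("months_to_%d0pct_rr%g", round(target * 10),
                   tts$true_effect_size[i])]] <- tts$months[i]
    out[[g]] <- row
  }
  data.table::rbindlist(out, fill = TRUE)
}
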