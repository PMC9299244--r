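#' Poisson MaxSPRT log-likelihood ratio
#'
#' One-sided log-likelihood ratio of the maximum-likelihood alternative
#' against the null for an observed count `c` with null expectation `u`:
#' `c * log(c / u) - (c - u)` when `c > u`, else 0.
#'
#' @param c Observed event count(s), non-negative.
#' @param u Expected count(s) under the null, positive.
#' @return Non-negative LLR, vectorised over `c` and `u`.
#' @export
poisson_llr <- function(c, u) {
  if (any(u <= 0)) stop("expected count u must be > 0", call. = FALSE)
  if (any(c < 0)) stop("observed count c must be >= 0", call. = FALSE)
  ifelse(c > u, c * log(c / u) - (c - u), 0)
}

#' Binomial MaxSPRT log-likelihood ratio
#'
#' For `c` of `n` total events falling in the risk window when the null
#' probability is `p0 = 1 / (1 + z)` (with `z` the control-to-risk
#' person-time ratio): `c * log(phat / p0) + (n - c) * log((1 - phat) /
#' (1 - p0))` with `phat = c / n`, when `phat > p0`; else 0. Boundary terms
#' use `0 * log(0) = 0`.
#'
#' @param c Risk-window event count(s).
#' @param n Total event count(s).
#' @param z Control-to-risk time ratio(s), positive.
#' @return Non-negative LLR, vectorised.
#' @export
binomial_llr <- function(c, n, z) {
  if (any(z <= 0)) stop("time ratio z must be > 0", call. = FALSE)
  if (any(c < 0 | c > n)) stop("need 0 <= c <= n", call. = FALSE)
  p0 <- 1 / (1 + z)
  out <- numeric(length(c + n + z))  # recycled length
  c <- rep_len(c, length(out)); n <- rep_len(n, length(out))
  p0 <- rep_len(p0, length(out))
  pos <- n > 0 & c / n > p0
  if (any(pos)) {
    ph <- c[pos] / n[pos]
    t1 <- ifelse(c[pos] > 0, c[pos] * log(ph / p0[pos]), 0)
    t2 <- ifelse(n[pos] - c[pos] > 0,
                 (n[pos] - c[pos]) * log((1 - ph) / (1 - p0[pos])), 0)
    out[pos] <- t1 + t2
  }
  out
}

#' Normal-approximation LLR from a log estimate and standard error
#'
#' Used to carry MaxSPRT over to designs whose output is a Wald-type
#' `(log estimate, SE)` pair (cohort, case-control): `theta^2 / (2 * se^2)`
#' for `theta > 0`, else 0.
#'
#' @param log_estimate,se Numeric vectors.
#' @return Non-negative LLR.
#' @export
normal_llr <- function(log_estimate, se) {
  ifelse(!is.na(log_estimate) & log_estimate > 0,
         log_estimate^2 / (2 * se^2), 0)
}

#' Monte-Carlo MaxSPRT critical value for a group-sequential look schedule
#'
#' Finds the flat LLR boundary whose any-look null crossing probability is at
#' most `alpha` (and maximally so) for a given schedule, by simulating null
#' data paths and taking the `ceiling((1 - alpha) * mc_reps)`-th order
#' statistic of the per-replicate maximum LLR.
#'
#' * `model = "poisson"`: `schedule` is the non-decreasing vector of
#'   cumulative expected counts at each look; null counts accrue as
#'   independent Poisson increments and the per-look LLR is
#'   [poisson_llr()] of the cumulative count.
#' * `model = "binomial"`: `schedule` is the non-decreasing vector of
#'   cumulative total event counts; `z` is the control-to-risk time ratio;
#'   null risk-window events accrue as binomial increments with
#'   `p0 = 1/(1+z)` and the per-look LLR is [binomial_llr()].
#'
#' @param schedule Cumulative expected counts (poisson) or cumulative total
#'   events (binomial), one per look, non-decreasing.
#' @param alpha Overall one-sided type 1 error, in (0, 0.5).
#' @param model `"poisson"` or `"binomial"`.
#' @param z Control-to-risk time ratio (binomial model only).
#' @param mc_reps Number of Monte-Carlo null replicates.
#' @param seed Optional seed.
#' @return A list of class `critical_value`: `value` (the boundary),
#'   `model`, `alpha`, `attained_alpha` (Monte-Carlo estimate of the
#'   crossing probability at the boundary), `mc_reps`, `schedule`.
#' @export
critical_value <- function(schedule, alpha = 0.05, model = c("poisson", "binomial"),
                           z = NULL, mc_reps = 1e5, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)", call. = FALSE)
  if (any(diff(schedule) < -1e-9))
    stop("schedule must be non-decreasing", call. = FALSE)
  k <- length(schedule)
  max_llr <- numeric(mc_reps)
  if (model == "poisson") {
    if (all(schedule <= 0)) stop("all expected counts are 0", call. = FALSE)
    inc <- diff(c(0, schedule))
    counts <- matrix(rpois(mc_reps * k, rep(inc, each = mc_reps)),
                     nrow = mc_reps)
    cum <- counts %*% upper.tri(diag(k), diag = TRUE)
    llr <- poisson_llr(as.vector(cum), rep(pmax(schedule, 1e-12), each = mc_reps))
    max_llr <- apply(matrix(llr, nrow = mc_reps), 1, max)
  } else {
    if (is.null(z)) stop("binomial model needs the time ratio z", call. = FALSE)
    if (all(schedule <= 0)) stop("all event totals are 0", call. = FALSE)
    inc <- diff(c(0, schedule))
    p0 <- 1 / (1 + z)
    counts <- matrix(rbinom(mc_reps * k, size = rep(inc, each = mc_reps), prob = p0),
                     nrow = mc_reps)
    cum <- counts %*% upper.tri(diag(k), diag = TRUE)
    ntot <- rep(schedule, each = mc_reps)
    llr <- binomial_llr(as.vector(cum), pmax(ntot, 1), z)
    llr[ntot == 0] <- 0
    max_llr <- apply(matrix(llr, nrow = mc_reps), 1, max)
  }
  ord <- sort(max_llr)
  cv <- ord[ceiling((1 - alpha) * mc_reps)]
  structure(list(value = cv, model = model, alpha = alpha,
                 attained_alpha = mean(max_llr > cv),
                 mc_reps = mc_reps, schedule = schedule, z = z),
            class = "critical_value")
}

#' First look at which a signal is declared
#'
#' @param llrs Per-look LLR sequence (aligned to the look schedule).
#' @param cv Critical value (a number or a `critical_value` object).
#' @return The earliest look index with `llr > cv`, or `NA_integer_` if the
#'   boundary is never crossed.
#' @export
sequential_signal <- function(llrs, cv) {
  if (inherits(cv, "critical_value")) cv <- cv$value
  hit <- which(!is.na(llrs) & llrs > cv)
  if (length(hit)) hit[1L] else NA_integer_
}
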