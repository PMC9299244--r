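# Diagnostic figures for the evaluation results. ggplot2 is in Suggests;
# each function errors cleanly when it is unavailable.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Negative-control estimates against their standard errors
#'
#' The classic funnel view: log estimate on x, SE on y, with the region
#' where the one-sided p-value falls below `alpha` shaded by the boundary
#' line `se = theta / qnorm(1 - alpha)`.
#'
#' @param est Estimates table (negative controls at one look are plotted).
#' @param alpha Significance threshold drawn.
#' @return A ggplot object.
#' @export
plot_estimates <- function(est, alpha = 0.05) {
  .need_ggplot()
  r <- data.table::as.data.table(est)[true_effect_size == 1 & estimable == TRUE]
  z <- stats::qnorm(1 - alpha)
  ggplot2::ggplot(r, ggplot2::aes(x = exp(log_estimate), y = se)) +
    ggplot2::geom_abline(intercept = 0, slope = 1 / z, colour = "red",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ design + variant) +
    ggplot2::labs(x = "estimate (ratio scale)", y = "standard error")
}

#' Fitted systematic-error distributions
#'
#' Normal densities with the fitted (mu, tau) per (design, variant) at the
#' final look, from the calibration columns of the estimates table.
#'
#' @param est Estimates table with `null_mu`, `null_tau` columns.
#' @return A ggplot object.
#' @export
plot_null_distributions <- function(est) {
  .need_ggplot()
  r <- data.table::as.data.table(est)[!is.na(null_mu),
    .(mu = stats::median(null_mu), tau = stats::median(null_tau)),
    by = .(design, variant)]
  grid <- r[, .(x = seq(-2, 2, length.out = 200)), by = .(design, variant)]
  grid <- merge(grid, r, by = c("design", "variant"))
  grid[, dens := stats::dnorm(x, mu, pmax(tau, 0.01))]
  ggplot2::ggplot(grid, ggplot2::aes(x = x, y = dens)) +
    ggplot2::geom_area(fill = "red", alpha = 0.4) +
    ggplot2::facet_wrap(~ design + variant, scales = "free_y") +
    ggplot2::labs(x = "systematic error (log scale)", y = "density")
}

#' Type 1 / type 2 error bars before and after calibration
#'
#' @param perf Output of [summarize_performance()].
#' @return A ggplot object.
#' @export
plot_type12 <- function(perf) {
  .need_ggplot()
  p <- data.table::as.data.table(perf)
  long <- data.table::melt(p, id.vars = c("design", "variant"),
                           measure.vars = intersect(
                             c("type1", "type1_calibrated"), names(p)),
                           variable.name = "metric", value.name = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = variant, y = error, fill = metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::facet_wrap(~ design, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "type 1 error (negative controls)")
}

#' Months-to-sensitivity tiles
#'
#' @param perf Output of [summarize_performance()].
#' @param target Sensitivity target used when building `perf`.
#' @return A ggplot object.
#' @export
plot_time_to_sensitivity <- function(perf, target = 0.5) {
  .need_ggplot()
  p <- data.table::as.data.table(perf)
  cols <- grep(sprintf("^months_to_%d0pct", round(target * 10)), names(p),
               value = TRUE)
  long <- data.table::melt(p, id.vars = c("design", "variant"),
                           measure.vars = cols,
                           variable.name = "effect", value.name = "months")
  long[, effect := sub(".*_rr", "RR ", effect)]
  ggplot2::ggplot(long, ggplot2::aes(x = effect,
                                     y = paste(design, variant, sep = ": "),
                                     fill = months)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(months), "never",
                                                   months)), size = 3) +
    ggplot2::labs(x = "true effect size", y = NULL,
                  fill = "months")
}
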