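#' Assemble a survival dataset
#'
#' One row per subject: observation time in hours, an event flag (1 =
#' death observed, 0 = censored -- the animal was still alive when
#' observation ended), and an optional group label.
#'
#' @param time positive observation times, hours.
#' @param event 0/1 (or logical) event flags.
#' @param group optional group labels (condition, genotype, dose, ...).
#' @return a data frame of class `surv_data` with columns `time`, `event`,
#'   `group`.
#' @seealso [calls_to_surv_data()] to build one from death calls.
#' @export
surv_data <- function(time, event, group = "all") {
  stop_if(length(time) == 0L, "need at least one subject")
  stop_if(any(!is.finite(time)) || any(time <= 0), "`time` must be positive")
  event <- as.integer(event)
  stop_if(length(event) != length(time) || !all(event %in% c(0L, 1L)),
          "`event` must be 0/1, one per subject")
  out <- data.frame(time = as.numeric(time), event = event,
                    group = rep_len(as.character(group), length(time)))
  class(out) <- c("surv_data", "data.frame")
  out
}

#' Convert death calls to a survival dataset
#'
#' Dead arenas contribute an event at the death time; censored arenas
#' contribute censored observation time. Excluded and empty arenas are
#' dropped. Multi-occupancy arenas (classes 2-3) are kept by default --
#' their call marks when the last resident stopped -- but can be dropped.
#'
#' @param calls death-call data frame from [vitality_from_objects()].
#' @param group group label for these calls.
#' @param drop_multi drop arenas with occupancy class 2-3 (default FALSE).
#' @return a [surv_data()].
#' @export
calls_to_surv_data <- function(calls, group = "all", drop_multi = FALSE) {
  keep <- calls$status %in% c("dead", "censored") & calls$time_h > 0
  if (drop_multi) keep <- keep & !calls$multi_occupancy
  stop_if(!any(keep), "no scoreable arenas in `calls`")
  surv_data(calls$time_h[keep], calls$status[keep] == "dead", group = group)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function: at each distinct event
#' time the conditional survival fraction `1 - d/n` is multiplied in,
#' censored subjects leaving the risk set after their censor time.
#' The median (and quartile) lifespans are read off the curve as the
#' smallest time at which the estimate drops to or below the target
#' fraction -- no interpolation, since hourly sampling would make
#' interpolated precision spurious.
#'
#' @param data a [surv_data()] (groups are pooled; subset first to compare).
#' @return an object of class `km_curve`: data frame `curve` with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, plus `median`, `q25`,
#'   `q75` (NA when not reached) and `n`.
#' @export
km_curve <- function(data) {
  stop_if(!is.data.frame(data) || nrow(data) == 0L, "`data` must be non-empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                           conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  structure(list(curve = curve, n = nrow(data),
                 median = km_quantile(curve, 0.5),
                 q25 = km_quantile(curve, 0.25),
                 q75 = km_quantile(curve, 0.75)),
            class = "km_curve")
}

# smallest time with S(t) <= 1 - p (p = fraction dead)
km_quantile <- function(curve, p) {
  hit <- which(curve$survival <= 1 - p + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve$time[min(hit)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "<km_curve> n = %d; median %s h (quartiles: 25%%, %s h; 75%%, %s h)\n",
    x$n, fmt_or_nr(x$median), fmt_or_nr(x$q25), fmt_or_nr(x$q75)))
  invisible(x)
}

fmt_or_nr <- function(x) if (is.na(x)) "not reached" else sprintf("%.1f", x)

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: over the pooled
#' event times, observed minus expected events in one group with
#' hypergeometric variance; the statistic is chi-square with 1 degree of
#' freedom under the null of identical hazards.
#'
#' @param a,b two [surv_data()] datasets (or one dataset with exactly two
#'   groups passed as `a`).
#' @return list with `statistic`, `p_value`, `df` (= 1), and per-group
#'   observed/expected counts.
#' @export
log_rank <- function(a, b = NULL) {
  if (is.null(b)) {
    g <- unique(a$group)
    stop_if(length(g) != 2L, "`a` must contain exactly two groups")
    pooled <- a
  } else {
    stop_if(nrow(a) == 0L || nrow(b) == 0L, "both groups must be non-empty")
    pooled <- rbind(
      data.frame(time = a$time, event = a$event, group = "a"),
      data.frame(time = b$time, event = b$event, group = "b"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = pooled)
  stat <- as.numeric(sd_$chisq)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, observed = as.numeric(sd_$obs), expected = as.numeric(sd_$exp))
}

#' Summarise a survival dataset
#'
#' Reports the sample size, mean lifespan with standard error computed over
#' observed deaths only (censored animals cannot contribute a lifespan
#' without imputation; their count is reported alongside), the Kaplan-Meier
#' median and quartiles, and percent lethality at requested times. Lethality
#' at `t` is the fraction of events at or before `t` among subjects with an
#' event by `t` or still under observation at `t` (equal to `1 - S(t)` when
#' no censoring precedes `t`).
#'
#' @param data a [surv_data()].
#' @param lethality_at numeric vector of times (hours) at which to report
#'   percent dead.
#' @return a list of class `surv_summary`: `n`, `n_events`, `n_censored`,
#'   `mean`, `sem`, `median`, `q25`, `q75`, and `lethality` (data frame
#'   `time_h`, `percent_dead`).
#' @export
summarize_survival <- function(data, lethality_at = numeric()) {
  ev <- data$time[data$event == 1]
  km <- km_curve(data)
  leth <- vapply(lethality_at, function(t) {
    at_risk <- sum(data$time >= t | (data$event == 1 & data$time <= t))
    if (at_risk == 0) return(NA_real_)
    100 * sum(data$event == 1 & data$time <= t) / at_risk
  }, numeric(1))
  structure(list(
    n = nrow(data), n_events = length(ev),
    n_censored = nrow(data) - length(ev),
    mean = if (length(ev)) mean(ev) else NA_real_,
    sem = if (length(ev) > 1) sd(ev) / sqrt(length(ev)) else NA_real_,
    median = km$median, q25 = km$q25, q75 = km$q75,
    lethality = data.frame(time_h = as.numeric(lethality_at),
                           percent_dead = leth)),
    class = "surv_summary")
}

#' @export
print.surv_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d (%d deaths, %d censored)\nmedian %s h (quartiles: 25%%, %s h; 75%%, %s h)\nmean %s h (SEM %s h)%s\n",
    x$n, x$n_events, x$n_censored, fmt_or_nr(x$median), fmt_or_nr(x$q25),
    fmt_or_nr(x$q75),
    if (is.na(x$mean)) "NA" else sprintf("%.1f", x$mean),
    if (is.na(x$sem)) "NA" else sprintf("%.1f", x$sem),
    if (x$n_censored > 0) "  [mean over observed deaths only]" else ""))
  for (i in seq_len(nrow(x$lethality)))
    cat(sprintf("%.1f%% lethality at %g h\n",
                x$lethality$percent_dead[i], x$lethality$time_h[i]))
  invisible(x)
}

#' Power-law dose-response fit of median lifespan vs concentration
#'
#' Fits `median = a * dose^b` by least squares on the log-log scale
#' (ordinary "power fit" trendline convention): the slope of
#' `ln(median) ~ ln(dose)` is the exponent `b` and the intercept is
#' `ln(a)`; the regression R-squared on that scale is reported. The fitted
#' curve is the LT50 dose-response: the concentration-dependent median
#' survival time.
#'
#' @param doses stressor concentrations (e.g. mM), strictly positive.
#' @param medians median lifespans at each dose, hours, strictly positive.
#' @return object of class `dose_response_fit`: `a` (hours), `b`
#'   (dimensionless), `r_squared`, and the input `doses`/`medians`.
#' @examples
#' fit_power_law(c(0.25, 0.5, 0.75, 1), 10.503 * c(0.25, 0.5, 0.75, 1)^-1.394)
#' @export
fit_power_law <- function(doses, medians) {
  stop_if(length(doses) != length(medians), "`doses`/`medians` length mismatch")
  stop_if(length(doses) < 2L, "need at least 2 dose/median pairs")
  stop_if(any(doses <= 0) || any(medians <= 0),
          "doses and medians must be strictly positive")
  fit <- stats::lm(log(medians) ~ log(doses))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(medians) - mean(log(medians)))^2)
  r2 <- if (ss_tot < 1e-24) 1 else 1 - ss_res / ss_tot  # flat data: exact fit
  dose_response_fit(a = exp(unname(coef(fit)[1])), b = unname(coef(fit)[2]),
                    r_squared = r2, doses = doses, medians = medians)
}

#' Construct a dose-response fit object directly
#'
#' Useful for working with a published model `y = a * x^b` without refitting.
#'
#' @param a coefficient (hours); must be positive.
#' @param b exponent (dimensionless).
#' @param r_squared optional fit R-squared.
#' @param doses,medians optional underlying data.
#' @return object of class `dose_response_fit`.
#' @export
dose_response_fit <- function(a, b, r_squared = NA_real_, doses = NULL,
                              medians = NULL) {
  stop_if(!is_number(a) || a <= 0, "`a` must be positive")
  stop_if(!is_number(b), "`b` must be a number")
  structure(list(a = a, b = b, r_squared = r_squared,
                 doses = doses, medians = medians),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> y = %.4g * x^%.4g", x$a, x$b))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Predicted median lifespan at a dose
#'
#' @param fit a [dose_response_fit()].
#' @param dose concentration(s), same units as the fit's doses.
#' @return predicted median lifespan(s), hours.
#' @export
predict_median <- function(fit, dose) fit$a * dose^fit$b

#' Equivalent dose for an observed median lifespan
#'
#' Inverts the power-law model: the concentration at which the modeled
#' population's median lifespan would equal `observed_median`, i.e.
#' `x = (y / a)^(1/b)`. Comparing this equivalent dose with the dose a
#' sensitised group actually received expresses its phenotype on the
#' concentration axis.
#'
#' @param fit a [dose_response_fit()] with nonzero exponent.
#' @param observed_median observed median lifespan, hours (> 0).
#' @return equivalent concentration, in the fit's dose units.
#' @examples
#' equivalent_dose(dose_response_fit(10.503, -1.394), 36)  # ~0.413
#' @export
equivalent_dose <- function(fit, observed_median) {
  stop_if(!inherits(fit, "dose_response_fit"), "`fit` must be a dose_response_fit")
  stop_if(fit$b == 0, "exponent is 0; dose-response is flat and not invertible")
  stop_if(any(observed_median <= 0), "`observed_median` must be positive")
  (observed_median / fit$a)^(1 / fit$b)
}

#' Relative sensitivity of a group versus the modeled dose-response
#'
#' Expresses how much more sensitive a group is than the reference model:
#' the percent increase of the equivalent dose over the dose actually
#' applied, `100 * (equivalent_dose / actual_dose - 1)`. A group responding
#' to 0.25 mM the way the model predicts for 0.413 mM is ~65% more
#' sensitive.
#'
#' @param fit a [dose_response_fit()].
#' @param actual_dose concentration the group was exposed to (> 0).
#' @param observed_median the group's observed median lifespan, hours.
#' @return percent increased sensitivity (can be negative for resistance).
#' @export
relative_sensitivity <- function(fit, actual_dose, observed_median) {
  stop_if(any(actual_dose <= 0), "`actual_dose` must be positive")
  100 * (equivalent_dose(fit, observed_median) / actual_dose - 1)
}
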