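# Frequentist survival analysis: Kaplan-Meier estimation, the one-sided
# log-rank sensitivity test, and Schoenfeld-style design power.
# Product-limit and O-E/variance arithmetic is delegated to the survival
# package; this module owns the median/range conventions, the one-sided
# direction, and the design formula.

#' Kaplan-Meier estimate with clinical median/range conventions
#'
#' Product-limit estimator of the survival function.  The median is the
#' smallest observed time at which the estimate drops to 0.5 or below
#' (`NA` when the curve never reaches 0.5).  The range is the minimum and
#' maximum observed time, with a flag marking a censored maximum; rendered
#' as e.g. `"0.8-19.1+"` by [format_km_range()].
#'
#' @param time non-negative times (months).
#' @param status event indicators, 1 = event, 0 = censored.
#' @return object of class `km_curve`: step coordinates `time`, `surv`,
#'   `n_risk`, `n_event`, plus `median`, `range_min`, `range_max`,
#'   `range_max_censored`, `n`, `n_events`.
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4, 5), rep(1, 5))
#' km$median
#' @export
km_estimate <- function(time, status) {
  stopifnot(length(time) == length(status), length(time) >= 1,
            all(time >= 0), all(status %in% c(0, 1)))
  if (all(status == 0) && all(time == 0))
    stop("degenerate sample: every observation censored at time 0",
         call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.type = "none")
  surv <- fit$surv
  at_or_below <- fit$time[fit$n.event > 0 & surv <= 0.5 + 1e-12]
  med <- if (length(at_or_below)) min(at_or_below) else NA_real_
  imax <- which.max(time)
  structure(
    list(time = fit$time, surv = surv,
         n_risk = fit$n.risk, n_event = fit$n.event,
         median = med,
         range_min = min(time), range_max = time[imax],
         range_max_censored = !any(status[time == time[imax]] == 1),
         n = length(time), n_events = sum(status)),
    class = "km_curve")
}

#' Survival probability at given times from a `km_curve`
#'
#' Right-continuous step-function evaluation; returns 1 before the first
#' event time.
#'
#' @param km a [km_estimate()] result.
#' @param t times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Render a median (range) string, censored maximum flagged with "+"
#'
#' @param km a `km_curve`.
#' @param digits decimals for the times.
#' @return character scalar such as `"8.3 (0.8-19.1+)"`.
#' @export
format_km_range <- function(km, digits = 1) {
  stopifnot(inherits(km, "km_curve"))
  med <- if (is.na(km$median)) "NE" else
    sprintf("%.*f", digits, round_half_up(km$median, digits))
  sprintf("%s (%.*f-%.*f%s)", med,
          digits, round_half_up(km$range_min, digits),
          digits, round_half_up(km$range_max, digits),
          if (km$range_max_censored) "+" else "")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  cat("  median (range):", format_km_range(x), "\n")
  invisible(x)
}

#' One-sided log-rank test (experimental hazard lower)
#'
#' Standard log-rank test with hypergeometric variance and the
#' simultaneous-death tie convention; no continuity correction.  The
#' statistic is `z = (O_e - E_e) / sqrt(V)` where `O_e`, `E_e` are observed
#' and expected events in the experimental arm, and the one-sided p-value is
#' `pnorm(z)` -- small when the experimental arm has fewer events than
#' expected, i.e. lower hazard.
#'
#' @param time_e,status_e experimental-arm times and event flags.
#' @param time_c,status_c control-arm times and event flags.
#' @return object of class `logrank_test`: `z`, `p_one_sided`,
#'   `observed_e`, `expected_e`, `variance`, `chisq`, `estimable`.  When the
#'   pooled sample has no events the test is flagged not estimable and the
#'   statistic and p-value are `NA`.
#' @examples
#' lr <- logrank_one_sided(c(2, 4, 6), c(1, 1, 1), c(1, 3, 5), c(1, 1, 1))
#' lr$p_one_sided
#' @export
logrank_one_sided <- function(time_e, status_e, time_c, status_c) {
  stopifnot(length(time_e) == length(status_e),
            length(time_c) == length(status_c),
            length(time_e) >= 1, length(time_c) >= 1)
  if (sum(status_e) + sum(status_c) == 0) {
    warning("no events in the pooled sample; log-rank p undefined")
    return(structure(list(z = NA_real_, p_one_sided = NA_real_,
                          observed_e = 0, expected_e = NA_real_,
                          variance = NA_real_, chisq = NA_real_,
                          estimable = FALSE),
                     class = "logrank_test"))
  }
  arm <- factor(rep(c("control", "experimental"),
                    c(length(time_c), length(time_e))),
                levels = c("control", "experimental"))
  time <- c(time_c, time_e)
  status <- c(status_c, status_e)
  sd <- survival::survdiff(survival::Surv(time, status) ~ arm, rho = 0)
  v <- if (is.matrix(sd$var)) sd$var[2, 2] else sd$var
  u <- sd$obs[2] - sd$exp[2]
  z <- if (v > 0) u / sqrt(v) else 0
  structure(
    list(z = z, p_one_sided = stats::pnorm(z),
         observed_e = unname(sd$obs[2]), expected_e = unname(sd$exp[2]),
         variance = v, chisq = sd$chisq, estimable = TRUE),
    class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  if (!x$estimable) {
    cat("Log-rank test: not estimable (no events)\n")
    return(invisible(x))
  }
  cat(sprintf("One-sided log-rank (experimental hazard lower): z = %.4f, p = %.4f\n",
              x$z, x$p_one_sided))
  cat(sprintf("  experimental: observed %g, expected %.2f (variance %.2f)\n",
              x$observed_e, x$expected_e, x$variance))
  invisible(x)
}

#' Schoenfeld design power for a log-rank comparison
#'
#' Closed-form power of the one-sided log-rank test under proportional
#' hazards: `power = pnorm(sqrt(d * p1 * p2) * |log hr| - z_{1-alpha})`,
#' where `d` is the total number of events and `p1, p2` the allocation
#' fractions.  At `hr = 1` the power equals `alpha` exactly.
#'
#' @param hr hazard ratio (experimental / control), > 0.
#' @param n_events total events contributing to the comparison.
#' @param alloc_fracs allocation fractions, summing to 1.
#' @param alpha_one_sided one-sided type I error.
#' @return object of class `design_power` with the inputs and `power`.
#' @examples
#' schoenfeld_power(7 / 9, 99, c(2 / 3, 1 / 3), 0.20)$power
#' @export
schoenfeld_power <- function(hr, n_events, alloc_fracs = c(2/3, 1/3),
                             alpha_one_sided = 0.20) {
  stopifnot(hr > 0, n_events >= 1, length(alloc_fracs) == 2,
            abs(sum(alloc_fracs) - 1) < 1e-12, all(alloc_fracs > 0),
            alpha_one_sided > 0, alpha_one_sided < 1)
  pw <- stats::pnorm(sqrt(n_events * prod(alloc_fracs)) * abs(log(hr)) -
                     stats::qnorm(1 - alpha_one_sided))
  structure(list(hazard_ratio = hr, n_events = n_events,
                 alloc_fracs = alloc_fracs,
                 alpha_one_sided = alpha_one_sided, power = pw),
            class = "design_power")
}

#' @export
print.design_power <- function(x, ...) {
  cat(sprintf("Schoenfeld design power: %.3f (HR %.3f, %d events, one-sided alpha %.2f)\n",
              x$power, x$hazard_ratio, x$n_events, x$alpha_one_sided))
  invisible(x)
}

#' Simulated power of the one-sided log-rank design
#'
#' Monte-Carlo rejection rate of the one-sided log-rank test over trials
#' drawn by the synthetic generator's survival core under full follow-up
#' (every patient an event).  Used to cross-check [schoenfeld_power()].
#'
#' @param n_total,allocation_ratio,median_os_e,median_os_c design settings
#'   (see [trial_config()]).
#' @param alpha_one_sided rejection level for the one-sided p-value.
#' @param n_reps number of simulated trials.
#' @param seed master seed; replicate seeds are drawn from it once and
#'   recorded.
#' @return object of class `operating_characteristics` (see
#'   [operating_characteristics()]).
#' @export
logrank_power_sim <- function(n_total = 99, allocation_ratio = c(2, 1),
                              median_os_e = 9, median_os_c = 7,
                              alpha_one_sided = 0.20,
                              n_reps = 10000, seed = 1) {
  stopifnot(n_reps >= 100)
  config <- trial_config(n_total = n_total,
                         allocation_ratio = allocation_ratio,
                         median_os_e = median_os_e, median_os_c = median_os_c,
                         median_pfs_e = median_os_e / 2,
                         median_pfs_c = median_os_c / 2,
                         accrual_duration = 0, followup_duration = Inf,
                         dropout_hazard = 0)
  seeds <- replicate_seeds(seed, n_reps)
  rej <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    s <- .sim_survival(config)
    e <- s$arm == "experimental"
    lr <- logrank_one_sided(s$os_time[e], s$os_event[e],
                            s$os_time[!e], s$os_event[!e])
    if (lr$estimable && lr$p_one_sided < alpha_one_sided) rej <- rej + 1L
  }
  r <- rej / n_reps
  structure(
    list(n_reps = n_reps, reject_rate = r,
         mc_standard_error = sqrt(r * (1 - r) / n_reps),
         scenario = list(rule = "one-sided log-rank",
                         alpha_one_sided = alpha_one_sided,
                         true_medians = c(experimental = median_os_e,
                                          control = median_os_c),
                         n_total = n_total,
                         allocation_ratio = allocation_ratio,
                         seed = seed)),
    class = "operating_characteristics")
}
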