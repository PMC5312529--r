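# Bayesian augmented-control comparison of overall survival.
#
# Model: per-arm exponential hazards lambda with conjugate gamma priors.
# The exponential likelihood has sufficient statistics (d, T): number of
# events and total exposure in patient-months, so a Gamma(a, b) prior
# updates to Gamma(a + d, b + T).  The concurrent control arm is augmented
# by historical control data through a power prior: the historical
# likelihood enters raised to a weight a0 in [0, 1], i.e. its sufficient
# statistics enter multiplied by a0.  The decision rule declares
# superiority when P(lambda_e < lambda_c | data) exceeds a threshold
# (default 0.8, strict).

#' Exponential sufficient statistics of a survival sample
#'
#' `d` = number of events, `total_exposure` = sum of all observation times
#' (events and censored alike), in patient-months.  These are the complete
#' sufficient statistics of the censored exponential likelihood; the hazard
#' MLE is `d / total_exposure`.
#'
#' @param time non-negative observation times (months).
#' @param status event flags, 1 = event, 0 = censored.
#' @return object of class `exp_suffstats` with `n_events`,
#'   `total_exposure`, `n`.
#' @examples
#' exp_suffstats(c(2, 3), c(1, 0))  # d = 1, T = 5
#' @export
exp_suffstats <- function(time, status) {
  stopifnot(length(time) >= 1, length(time) == length(status),
            all(time >= 0), all(status %in% c(0, 1)))
  structure(list(n_events = sum(status), total_exposure = sum(time),
                 n = length(time)),
            class = "exp_suffstats")
}

#' @export
print.exp_suffstats <- function(x, ...) {
  cat(sprintf("Exponential sufficient statistics: d = %g events, T = %.2f patient-months (n = %d)\n",
              x$n_events, x$total_exposure, x$n))
  invisible(x)
}

#' Historical control summary
#'
#' Wraps the exponential sufficient statistics of a historical control
#' population for use in the power-prior update.
#'
#' @param n_events historical events.
#' @param total_exposure historical exposure, patient-months.
#' @param label descriptive label.
#' @return object of class `historical_control`.
#' @seealso [default_historical_control()]
#' @export
historical_control <- function(n_events, total_exposure,
                               label = "historical control") {
  stopifnot(n_events >= 0, total_exposure > 0)
  structure(list(label = label, n_events = n_events,
                 total_exposure = total_exposure),
            class = "historical_control")
}

#' Default historical gemcitabine control fixture
#'
#' A reconstruction of the historical gemcitabine experience backing the
#' augmented-control design: `n_events` exponential events at the stated
#' median, so `total_exposure = n_events * median / log(2)` patient-months
#' (the exposure at which the hazard MLE equals `log(2) / median`).  The
#' default, 300 events at median 7 months, together with the default
#' borrowing weight `a0 = 0.15`, contributes 45 effective control events.
#'
#' @param median_os historical median overall survival, months.
#' @param n_events historical event count.
#' @return a [historical_control()].
#' @export
default_historical_control <- function(median_os = 7, n_events = 300) {
  historical_control(n_events = n_events,
                     total_exposure = n_events * median_os / log(2),
                     label = sprintf("synthetic historical control (median %g months)",
                                     median_os))
}

#' Gamma posterior (or prior) for an exponential hazard
#'
#' @param shape,rate positive gamma parameters; the hazard posterior mean is
#'   `shape / rate` per month and the implied median survival `log(2) *
#'   rate / shape` months.
#' @return object of class `gamma_posterior`.
#' @export
gamma_posterior <- function(shape, rate) {
  stopifnot(is.finite(shape), is.finite(rate), shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate), class = "gamma_posterior")
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf("Gamma(%g, %g) hazard posterior: mean %.4f /month, implied median OS %.2f months\n",
              x$shape, x$rate, x$shape / x$rate, log(2) * x$rate / x$shape))
  invisible(x)
}

#' Vague default prior for an arm hazard
#' @return `gamma_posterior(0.001, 0.001)`.
#' @export
vague_hazard_prior <- function() gamma_posterior(0.001, 0.001)

#' Conjugate update of a hazard prior by a survival sample
#'
#' @param suff an [exp_suffstats()].
#' @param prior a [gamma_posterior()]; defaults to the vague prior.
#' @return the updated [gamma_posterior()].
#' @export
hazard_posterior <- function(suff, prior = vague_hazard_prior()) {
  stopifnot(inherits(suff, "exp_suffstats"), inherits(prior, "gamma_posterior"))
  gamma_posterior(prior$shape + suff$n_events,
                  prior$rate + suff$total_exposure)
}

#' Power-prior augmented-control posterior
#'
#' Combines concurrent control data with historical control data discounted
#' by the borrowing weight `a0`:
#' `shape = prior.shape + a0 * d_hist + d_conc`,
#' `rate  = prior.rate  + a0 * T_hist + T_conc`.
#' `a0 = 0` reduces to the concurrent-only posterior; `a0 = 1` to complete
#' pooling.
#'
#' @param concurrent [exp_suffstats()] of the concurrent control arm.
#' @param historical a [historical_control()].
#' @param a0 borrowing weight in `[0, 1]`.
#' @param prior initial [gamma_posterior()].
#' @return the augmented [gamma_posterior()] for the control hazard.
#' @examples
#' conc <- exp_suffstats(rep(10.1, 33), rep(1, 33))  # d = 33, T = 333.3
#' augmented_control_posterior(conc, default_historical_control(), a0 = 0.2)
#' @export
augmented_control_posterior <- function(concurrent,
                                        historical = default_historical_control(),
                                        a0 = 0.15,
                                        prior = vague_hazard_prior()) {
  stopifnot(inherits(concurrent, "exp_suffstats"),
            inherits(historical, "historical_control"),
            inherits(prior, "gamma_posterior"))
  if (!is.finite(a0) || a0 < 0 || a0 > 1)
    stop("borrowing weight a0 must lie in [0, 1]", call. = FALSE)
  gamma_posterior(
    prior$shape + a0 * historical$n_events + concurrent$n_events,
    prior$rate + a0 * historical$total_exposure + concurrent$total_exposure)
}

#' Posterior probability that the experimental hazard is lower
#'
#' `P(lambda_e < lambda_c)` for independent gamma posteriors.  The exact
#' method uses the Beta identity
#' `P(lambda_e < lambda_c) = P(Beta(a_e, a_c) < b_e / (b_e + b_c))`
#' (write each gamma as a scaled standard gamma; the ratio of standard
#' gammas is Beta-distributed).  The Monte-Carlo method draws from both
#' posteriors; the two agree within ~0.002 at 1e5 draws.
#'
#' @param post_e,post_c [gamma_posterior()] objects for the experimental and
#'   control hazards.
#' @param method `"exact"` (default) or `"mc"`.
#' @param n_draws Monte-Carlo draws when `method = "mc"`.
#' @return probability in `[0, 1]`.
#' @examples
#' posterior_prob_superiority(gamma_posterior(10, 100), gamma_posterior(10, 70))
#' @export
posterior_prob_superiority <- function(post_e, post_c,
                                       method = c("exact", "mc"),
                                       n_draws = 1e5) {
  stopifnot(inherits(post_e, "gamma_posterior"),
            inherits(post_c, "gamma_posterior"))
  method <- match.arg(method)
  if (method == "exact") {
    stats::pbeta(post_e$rate / (post_e$rate + post_c$rate),
                 post_e$shape, post_c$shape)
  } else {
    le <- stats::rgamma(n_draws, post_e$shape, rate = post_e$rate)
    lc <- stats::rgamma(n_draws, post_c$shape, rate = post_c$rate)
    mean(le < lc)
  }
}

#' Superiority decision at a posterior-probability threshold
#'
#' Strict exceedance: superiority is declared only when the posterior
#' probability is strictly greater than the threshold, so a probability of
#' exactly 0.8 does not qualify.
#'
#' @param prob posterior probability of superiority, in `[0, 1]`.
#' @param threshold decision threshold (default 0.8).
#' @return object of class `superiority_result`: `posterior_prob`,
#'   `threshold`, `decision`.
#' @export
decide_superiority <- function(prob, threshold = 0.8) {
  stopifnot(is.finite(prob), prob >= 0, prob <= 1,
            threshold >= 0, threshold <= 1)
  structure(list(posterior_prob = prob, threshold = threshold,
                 decision = prob > threshold),
            class = "superiority_result")
}

#' @export
print.superiority_result <- function(x, ...) {
  cat(sprintf("Posterior probability of superiority: %.3f (threshold %.2f) -> %s\n",
              x$posterior_prob, x$threshold,
              if (x$decision) "SUPERIOR" else "not superior"))
  invisible(x)
}

#' Full augmented-control analysis of one trial dataset
#'
#' Convenience wrapper: extracts per-arm exponential sufficient statistics
#' from a patients table, forms the vague-prior experimental posterior and
#' the power-prior augmented control posterior, and applies the decision
#' rule.
#'
#' @param patients data frame with columns `arm`, `os_time`, `os_event`
#'   (as produced by [simulate_trial()]).
#' @param historical a [historical_control()].
#' @param a0 borrowing weight.
#' @param threshold decision threshold.
#' @param prior per-arm initial prior.
#' @return list with `posterior_e`, `posterior_c`, `prob`, `result` (a
#'   `superiority_result`), and the sufficient statistics.
#' @export
bayes_os_analysis <- function(patients,
                              historical = default_historical_control(),
                              a0 = 0.15, threshold = 0.8,
                              prior = vague_hazard_prior()) {
  stopifnot(all(c("arm", "os_time", "os_event") %in% names(patients)))
  e <- patients$arm == "experimental"
  suff_e <- exp_suffstats(patients$os_time[e], patients$os_event[e])
  suff_c <- exp_suffstats(patients$os_time[!e], patients$os_event[!e])
  post_e <- hazard_posterior(suff_e, prior)
  post_c <- augmented_control_posterior(suff_c, historical, a0, prior)
  prob <- posterior_prob_superiority(post_e, post_c)
  list(posterior_e = post_e, posterior_c = post_c,
       suff_e = suff_e, suff_c = suff_c,
       prob = prob, result = decide_superiority(prob, threshold))
}

#' Operating characteristics of the augmented-control decision rule
#'
#' Simulates replicate trials under stated true medians, analyzes each with
#' the full augmented-control pipeline (vague-prior experimental posterior,
#' power-prior control posterior, strict threshold rule), and reports the
#' rejection fraction with its Monte-Carlo standard error.  With equal true
#' medians this is the design's type I error; under the design alternative
#' it is power.  Full follow-up (every patient an event) is the default,
#' matching the design's event arithmetic; pass a censored
#' [trial_config()] via `config` for censored variants.
#'
#' @param true_median_e,true_median_c true OS medians, months.
#' @param n_total,allocation_ratio trial size and allocation.
#' @param historical a [historical_control()].
#' @param a0 borrowing weight in `[0, 1]`.
#' @param threshold posterior-probability decision threshold.
#' @param prior per-arm initial prior.
#' @param n_reps number of simulated trials (>= 100).
#' @param seed master seed; per-replicate seeds are drawn from it once and
#'   recorded in the scenario block.
#' @param config optional full [trial_config()] overriding the survival
#'   settings above (used for censored-variant studies).
#' @return object of class `operating_characteristics`: `n_reps`,
#'   `reject_rate`, `mc_standard_error`, and a `scenario` descriptor.
#' @examples
#' oc <- operating_characteristics(7, 7, n_reps = 200, seed = 1)
#' oc$reject_rate
#' @export
operating_characteristics <- function(true_median_e, true_median_c,
                                      n_total = 99,
                                      allocation_ratio = c(2, 1),
                                      historical = default_historical_control(),
                                      a0 = 0.15, threshold = 0.8,
                                      prior = vague_hazard_prior(),
                                      n_reps = 5000, seed = 1,
                                      config = NULL) {
  stopifnot(n_reps >= 100)
  if (is.null(config)) {
    config <- trial_config(n_total = n_total,
                           allocation_ratio = allocation_ratio,
                           median_os_e = true_median_e,
                           median_os_c = true_median_c,
                           median_pfs_e = true_median_e / 2,
                           median_pfs_c = true_median_c / 2,
                           accrual_duration = 0, followup_duration = Inf,
                           dropout_hazard = 0)
  }
  seeds <- replicate_seeds(seed, n_reps)
  rej <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    s <- .sim_survival(config)
    e <- s$arm == "experimental"
    post_e <- hazard_posterior(exp_suffstats(s$os_time[e], s$os_event[e]),
                               prior)
    post_c <- augmented_control_posterior(
      exp_suffstats(s$os_time[!e], s$os_event[!e]), historical, a0, prior)
    if (posterior_prob_superiority(post_e, post_c) > threshold)
      rej <- rej + 1L
  }
  r <- rej / n_reps
  structure(
    list(n_reps = n_reps, reject_rate = r,
         mc_standard_error = sqrt(r * (1 - r) / n_reps),
         scenario = list(rule = "augmented-control posterior probability",
                         true_medians = c(experimental = true_median_e,
                                          control = true_median_c),
                         a0 = a0, threshold = threshold,
                         historical = historical,
                         n_total = config$n_total,
                         allocation_ratio = config$allocation_ratio,
                         seed = seed)),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s):\n", x$scenario$rule))
  tm <- x$scenario$true_medians
  cat(sprintf("  true medians %g vs %g months; %d replicates\n",
              tm[1], tm[2], x$n_reps))
  cat(sprintf("  rejection rate %.4f (MC SE %.4f)\n",
              x$reject_rate, x$mc_standard_error))
  invisible(x)
}
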