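#' Trial design configuration
#'
#' Bundles everything the synthetic-trial generator needs: sample size,
#' allocation, true survival medians, censoring mechanism, response-category
#' probabilities, and the population pharmacokinetic block.  Defaults encode
#' the study conditions of a 99-patient, 2:1 randomized pancreatic-cancer
#' trial: exponential overall survival with medians 9 (experimental) vs 7
#' (control) months, progression-free survival medians 3.5 vs 5.6 months,
#' and best-response frequencies 0/14/22 CR/PR/SD of 65 (experimental) and
#' 0/3/19 of 34 (control), the remainder split between progressive disease
#' and not-evaluable.
#'
#' @param n_total total number of randomized patients (>= 2).
#' @param allocation_ratio integer pair `c(experimental, control)`; block
#'   randomization uses blocks of `sum(allocation_ratio)`.
#' @param median_os_e,median_os_c true median overall survival, months.
#' @param median_pfs_e,median_pfs_c true median progression-free survival,
#'   months; each must be strictly less than the same arm's OS median.
#' @param accrual_duration,followup_duration months; a patient entering at
#'   uniform time `u` in `[0, accrual_duration]` is administratively censored
#'   at `accrual_duration + followup_duration - u` months on study.  Use
#'   `accrual_duration = 0, followup_duration = Inf` for full follow-up.
#' @param dropout_hazard per-month exponential dropout rate (0 disables).
#' @param response_probs_e,response_probs_c named probability vectors over
#'   `CR, PR, SD, PD, NE`; each must sum to 1 within 1e-12.
#' @param os_shape Weibull shape for survival times; 1 (the default) is
#'   exponential, the design's framing.  Medians are preserved for any shape.
#' @param frailty_var variance of the mean-1 gamma frailty acting on the
#'   progression hazard (links PFS to OS; see the methods vignette).
#' @param pk a [population_pk()] block.
#' @return an object of class `trial_config` (a validated list).
#' @seealso [simulate_trial()]
#' @examples
#' cfg <- trial_config()
#' cfg$n_total
#' @export
trial_config <- function(n_total = 99,
                         allocation_ratio = c(2, 1),
                         median_os_e = 9, median_os_c = 7,
                         median_pfs_e = 3.5, median_pfs_c = 5.6,
                         accrual_duration = 18, followup_duration = 6,
                         dropout_hazard = 0.01,
                         response_probs_e = c(CR = 0, PR = 14/65, SD = 22/65,
                                              PD = 25/65, NE = 4/65),
                         response_probs_c = c(CR = 0, PR = 3/34, SD = 19/34,
                                              PD = 10/34, NE = 2/34),
                         os_shape = 1,
                         frailty_var = 0.25,
                         pk = population_pk()) {
  stopifnot(
    length(n_total) == 1, n_total >= 2, n_total == as.integer(n_total),
    length(allocation_ratio) == 2,
    all(allocation_ratio >= 1),
    all(allocation_ratio == as.integer(allocation_ratio)),
    median_os_e > 0, median_os_c > 0,
    median_pfs_e > 0, median_pfs_c > 0,
    median_pfs_e < median_os_e, median_pfs_c < median_os_c,
    accrual_duration >= 0, followup_duration > 0,
    dropout_hazard >= 0, os_shape > 0, frailty_var >= 0
  )
  check_probs <- function(p, who) {
    if (!identical(sort(names(p)), sort(c("CR", "PR", "SD", "PD", "NE"))))
      stop(who, " must be named over CR, PR, SD, PD, NE", call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(who, " must be a probability vector summing to 1 (within 1e-12)",
           call. = FALSE)
    p[c("CR", "PR", "SD", "PD", "NE")]
  }
  response_probs_e <- check_probs(response_probs_e, "response_probs_e")
  response_probs_c <- check_probs(response_probs_c, "response_probs_c")
  stopifnot(inherits(pk, "population_pk"))

  structure(
    list(n_total = as.integer(n_total),
         allocation_ratio = as.integer(allocation_ratio),
         median_os_e = median_os_e, median_os_c = median_os_c,
         median_pfs_e = median_pfs_e, median_pfs_c = median_pfs_c,
         accrual_duration = accrual_duration,
         followup_duration = followup_duration,
         dropout_hazard = dropout_hazard,
         response_probs_e = response_probs_e,
         response_probs_c = response_probs_c,
         os_shape = os_shape, frailty_var = frailty_var,
         pk = pk),
    class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Trial configuration\n")
  cat(sprintf("  n = %d, allocation %d:%d (blocks of %d)\n", x$n_total,
              x$allocation_ratio[1], x$allocation_ratio[2],
              sum(x$allocation_ratio)))
  cat(sprintf("  OS medians (months): experimental %.3g, control %.3g\n",
              x$median_os_e, x$median_os_c))
  cat(sprintf("  PFS medians (months): experimental %.3g, control %.3g\n",
              x$median_pfs_e, x$median_pfs_c))
  cat(sprintf("  accrual %.3g + follow-up %.3g months, dropout hazard %.3g/month\n",
              x$accrual_duration, x$followup_duration, x$dropout_hazard))
  invisible(x)
}

#' Population pharmacokinetic block
#'
#' Two-compartment disposition parameters for a constant-rate intravenous
#' infusion, with log-normal inter-patient variability.  Defaults describe a
#' 230 mg dose given as a 1-hour infusion: clearance 7.79 L/h, steady-state
#' volume 104 L (split 55 L central / 49 L peripheral), inter-compartmental
#' clearance 15 L/h, 50% CV on clearance and central volume.  All volumes in
#' mL, clearances in mL/h, dose in ng, times in hours, so concentrations come
#' out in ng/mL.
#'
#' @param dose dose per administration, ng (default 230 mg).
#' @param infusion_duration hours.
#' @param cl_geomean,vc_geomean,vp_geomean,q_geomean geometric means of
#'   clearance (mL/h), central and peripheral volumes (mL), and
#'   inter-compartmental clearance (mL/h).
#' @param iiv_cv named percent CVs of the log-normal inter-patient
#'   variability on `cl`, `vc`, `vp`, `q` (0 switches a component off).
#' @param iov_cv_cl percent CV of inter-occasion (dosing-day) variability on
#'   clearance; drives the spread of intra-cycle accumulation ratios.
#' @param sampling_times hours after the start of infusion; the default
#'   `c(0, 1, 2, 4, 25)` is pre-dose, end of infusion, and 1, 3, 24 h after
#'   the end of a 1-h infusion.
#' @return an object of class `population_pk`.
#' @export
population_pk <- function(dose = 230e6, infusion_duration = 1,
                          cl_geomean = 7790,
                          vc_geomean = 55000, vp_geomean = 49000,
                          q_geomean = 15000,
                          iiv_cv = c(cl = 50, vc = 50, vp = 30, q = 30),
                          iov_cv_cl = 25,
                          sampling_times = c(0, 1, 2, 4, 25)) {
  stopifnot(
    dose > 0, infusion_duration > 0,
    cl_geomean > 0, vc_geomean > 0, vp_geomean > 0, q_geomean > 0,
    all(c("cl", "vc", "vp", "q") %in% names(iiv_cv)),
    all(iiv_cv >= 0), iov_cv_cl >= 0,
    length(sampling_times) >= 2,
    all(diff(sampling_times) > 0)
  )
  structure(
    list(dose = dose, infusion_duration = infusion_duration,
         cl_geomean = cl_geomean, vc_geomean = vc_geomean,
         vp_geomean = vp_geomean, q_geomean = q_geomean,
         iiv_cv = iiv_cv[c("cl", "vc", "vp", "q")], iov_cv_cl = iov_cv_cl,
         sampling_times = sampling_times),
    class = "population_pk")
}

#' @export
print.population_pk <- function(x, ...) {
  cat("Population PK (two-compartment, constant-rate infusion)\n")
  cat(sprintf("  dose %.4g mg over %.3g h\n", x$dose / 1e6, x$infusion_duration))
  cat(sprintf("  CL %.4g L/h, Vc %.4g L, Vp %.4g L, Q %.4g L/h\n",
              x$cl_geomean / 1000, x$vc_geomean / 1000, x$vp_geomean / 1000,
              x$q_geomean / 1000))
  cat(sprintf("  IIV CV%%: CL %g, Vc %g, Vp %g, Q %g; IOV on CL %g\n",
              x$iiv_cv["cl"], x$iiv_cv["vc"], x$iiv_cv["vp"], x$iiv_cv["q"],
              x$iov_cv_cl))
  cat("  sampling times (h):", paste(x$sampling_times, collapse = ", "), "\n")
  invisible(x)
}
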