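# Synthetic patient-level trial generator.  Every downstream analysis module
# is exercised on datasets produced here, so the generator's distributional
# contracts (exponential OS marginals, block randomization, two-compartment
# infusion kinetics) are themselves under test.

ARM_LEVELS <- c("control", "experimental")

#' Permuted-block treatment assignment
#'
#' Assigns `n` patients to experimental/control in permuted blocks of size
#' `sum(ratio)`.  A final incomplete block is filled by sampling the block
#' contents without replacement, so realized arm sizes can deviate from the
#' exact ratio only in the last block.
#'
#' @param n number of patients.
#' @param ratio integer pair `c(experimental, control)`.
#' @return factor of length `n` with levels `control`, `experimental`, in
#'   randomization order.  Uses the current RNG state.
#' @export
block_randomize <- function(n, ratio = c(2, 1)) {
  stopifnot(n >= 1, length(ratio) == 2, all(ratio >= 1))
  block <- rep(c("experimental", "control"), ratio)
  k <- length(block)
  n_blocks <- ceiling(n / k)
  out <- unlist(lapply(seq_len(n_blocks), function(i) sample(block)))
  factor(out[seq_len(n)], levels = ARM_LEVELS)
}

# progression hazard multiplier theta for one arm: solves
#   S_os(m_pfs) * E[exp(-Z * theta * m_pfs)] = 1/2,  Z ~ Gamma(1/v, 1/v)
# so that PFS = min(progression, OS) has the configured marginal median.
.pfs_theta <- function(median_pfs, median_os, shape, frailty_var) {
  s_os <- exp(-log(2) * (median_pfs / median_os)^shape)
  target <- 0.5 / s_os  # Laplace transform value needed at m_pfs
  if (target >= 1) stop("PFS median not below OS median", call. = FALSE)
  v <- frailty_var
  if (v == 0) return(-log(target) / median_pfs)
  # (1 + v * theta * t)^(-1/v) = target  =>  closed form
  (target^(-v) - 1) / (v * median_pfs)
}

# survival core shared by simulate_trial() and the OC simulator.
# Assumes the RNG is already seeded.  Returns arm + OS/PFS with censoring.
.sim_survival <- function(config) {
  n <- config$n_total
  arm <- block_randomize(n, config$allocation_ratio)
  exp_arm <- arm == "experimental"

  m_os <- ifelse(exp_arm, config$median_os_e, config$median_os_c)
  m_pfs <- ifelse(exp_arm, config$median_pfs_e, config$median_pfs_c)
  shape <- config$os_shape
  scale_os <- m_os / log(2)^(1 / shape)      # Weibull scale giving the median
  os_raw <- stats::rweibull(n, shape = shape, scale = scale_os)

  v <- config$frailty_var
  z <- if (v > 0) stats::rgamma(n, shape = 1 / v, rate = 1 / v) else rep(1, n)
  th_e <- .pfs_theta(config$median_pfs_e, config$median_os_e, shape, v)
  th_c <- .pfs_theta(config$median_pfs_c, config$median_os_c, shape, v)
  theta <- ifelse(exp_arm, th_e, th_c)
  prog_raw <- stats::rexp(n, rate = 1) / (z * theta)  # Exp(z * theta)
  pfs_raw <- pmin(prog_raw, os_raw)

  entry <- if (config$accrual_duration > 0)
    stats::runif(n, 0, config$accrual_duration) else rep(0, n)
  admin <- config$accrual_duration + config$followup_duration - entry
  dropout <- if (config$dropout_hazard > 0)
    stats::rexp(n, rate = config$dropout_hazard) else rep(Inf, n)
  cens <- pmin(admin, dropout)

  data.frame(
    arm = arm,
    entry_month = entry,
    os_time = pmin(os_raw, cens),
    os_event = as.integer(os_raw <= cens),
    pfs_time = pmin(pfs_raw, cens),
    pfs_event = as.integer(pfs_raw <= cens)
  )
}

#' Simulate a complete patient-level trial dataset
#'
#' Generates one randomized trial under a [trial_config()]: permuted-block
#' 2:1 assignment, exponential (or Weibull) overall survival with the
#' configured medians, progression-free survival coupled to OS through a
#' gamma-frailty progression hazard (so PFS <= OS always), administrative
#' and dropout censoring, RECIST best-response categories, baseline/week-8
#' target-lesion sums consistent with the response category, CA19-9 series,
#' demographics, pharmacokinetic profiles for the experimental arm (days 2
#' and 16 of cycle 1), and adverse-event / ECG records.
#'
#' Identical `(config, seed)` pairs give identical datasets.
#'
#' @param config a [trial_config()].
#' @param seed integer master seed.
#' @param tables which auxiliary tables to generate besides `patients`:
#'   any of `"pk"`, `"ae"` (which includes ECG), `"ca199"`.  Restricting
#'   this is useful for large-`n` distributional studies where only the
#'   patients table matters.
#' @return an object of class `trial_dataset`: a list with data frames
#'   `patients`, `pk` (long concentration-time samples), `ae`, `ecg`,
#'   `ca199` (long by cycle), plus the `config` and `seed` used.
#' @examples
#' ds <- simulate_trial(trial_config(), seed = 1)
#' table(ds$patients$arm)
#' @export
simulate_trial <- function(config = trial_config(), seed = 1,
                           tables = c("pk", "ae", "ca199")) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(seed)
  n <- config$n_total
  surv <- .sim_survival(config)
  exp_arm <- surv$arm == "experimental"

  # RECIST best response by configured category probabilities
  cats <- c("CR", "PR", "SD", "PD", "NE")
  best_response <- character(n)
  best_response[exp_arm] <- sample(cats, sum(exp_arm), replace = TRUE,
                                   prob = config$response_probs_e)
  best_response[!exp_arm] <- sample(cats, sum(!exp_arm), replace = TRUE,
                                    prob = config$response_probs_c)
  best_response <- factor(best_response, levels = cats)

  # target-lesion sums: week-8 change consistent with the category
  baseline_sum <- stats::rlnorm(n, log(80), 0.4)
  change <- numeric(n)
  change[best_response == "CR"] <- -1
  change[best_response == "PR"] <- -stats::runif(sum(best_response == "PR"), 0.30, 0.70)
  change[best_response == "SD"] <- stats::runif(sum(best_response == "SD"), -0.29, 0.19)
  change[best_response == "PD"] <- stats::runif(sum(best_response == "PD"), 0.20, 0.60)
  week8_sum <- baseline_sum * (1 + change)
  week8_sum[best_response == "NE"] <- NA_real_

  # duration of response (responders only): onset ~ first assessments,
  # end at progression/death, censored with PFS
  responder <- best_response %in% c("CR", "PR")
  onset <- ifelse(responder, stats::runif(n, 1.2, 2.5), NA_real_)
  dor_time <- ifelse(responder, pmax(surv$pfs_time - onset, 0.1), NA_real_)
  dor_event <- ifelse(responder, surv$pfs_event, NA_integer_)

  # demographics (baseline table emulation)
  age <- pmin(pmax(round(stats::rnorm(n, 64, 9)), 35), 92)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.37, 0.63))
  bsa <- round(stats::rnorm(n, 1.8, 0.2), 2)
  stage <- sample(c("II", "III", "IV", "Unknown"), n, replace = TRUE,
                  prob = c(0.09, 0.13, 0.77, 0.01))
  ecog <- sample(0:2, n, replace = TRUE, prob = c(0.42, 0.49, 0.09))

  # CA19-9: baseline lognormal around 500 U/mL (ULN 37), per-cycle
  # multiplicative drift tied to the response category
  uln <- 37
  ca_base <- stats::rlnorm(n, log(500), 2.0)
  n_cycles <- pmax(1L, pmin(8L, as.integer(ceiling(surv$pfs_time / 0.92))))
  drift <- c(CR = log(0.45), PR = log(0.5), SD = log(0.8),
             PD = log(1.15), NE = 0)[as.character(best_response)]
  ca199 <- NULL
  if ("ca199" %in% tables) {
    ca_rows <- lapply(seq_len(n), function(i) {
      k <- n_cycles[i]
      vals <- ca_base[i] * exp(cumsum(stats::rnorm(k, drift[i], 0.3)))
      data.frame(patient_id = i, cycle = seq_len(k), ca199_u_ml = vals)
    })
    ca199 <- do.call(rbind, ca_rows)
  }

  patients <- data.frame(
    patient_id = seq_len(n),
    arm = surv$arm,
    entry_month = surv$entry_month,
    os_time = surv$os_time, os_event = surv$os_event,
    pfs_time = surv$pfs_time, pfs_event = surv$pfs_event,
    best_response = best_response,
    baseline_target_sum_mm = baseline_sum,
    week8_target_sum_mm = week8_sum,
    dor_time = dor_time, dor_event = dor_event,
    age_years = age, sex = sex, bsa_m2 = bsa,
    stage = factor(stage, levels = c("II", "III", "IV", "Unknown")),
    ecog = ecog,
    ca199_baseline_u_ml = ca_base, uln_ca199_u_ml = uln
  )
  ds <- structure(list(patients = patients, ca199 = ca199,
                       pk = NULL, ae = NULL, ecg = NULL,
                       config = config, seed = seed),
                  class = "trial_dataset")

  if ("pk" %in% tables) {
    # PK for the experimental arm: day 2 for everyone, day 16 only for
    # patients still on study after one month (mirrors declining profile n).
    # Individual parameters are shared across days; only the occasion
    # component of clearance differs.
    ids_e <- patients$patient_id[exp_arm]
    ids_d16 <- patients$patient_id[exp_arm & patients$os_time > 1]
    pk <- simulate_pk_profiles(config$pk, length(ids_e), seed = seed + 1L,
                               days = c(2, 16), patient_ids = ids_e)
    ds$pk <- pk[pk$day == 2 | pk$patient_id %in% ids_d16, , drop = FALSE]
    rownames(ds$pk) <- NULL
  }

  if ("ae" %in% tables) {
    sae <- simulate_ae_and_ecg(ds, seed = seed + 3L)
    ds$ae <- sae$ae
    ds$ecg <- sae$ecg
  }
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat(sprintf("Synthetic trial dataset: %d patients (%d experimental / %d control)\n",
              nrow(x$patients), tab["experimental"], tab["control"]))
  cat(sprintf("  OS events: %d; PFS events: %d\n",
              sum(x$patients$os_event), sum(x$patients$pfs_event)))
  if (!is.null(x$pk))
    cat(sprintf("  PK samples: %d rows (%d profiles)\n", nrow(x$pk),
                nrow(unique(x$pk[c("patient_id", "day")]))))
  if (!is.null(x$ae)) cat(sprintf("  AE records: %d\n", nrow(x$ae)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Two-compartment constant-rate infusion concentration
#'
#' Closed-form plasma concentration for a two-compartment model with
#' elimination from the central compartment, during and after a constant-rate
#' infusion of duration `tinf`.
#'
#' @param times hours since the start of infusion (vector).
#' @param dose ng; `tinf` hours; `cl`, `q` mL/h; `vc`, `vp` mL.
#' @param tinf,cl,vc,vp,q model parameters, see above.
#' @return concentrations, ng/mL.
#' @export
two_compartment_conc <- function(times, dose, tinf, cl, vc, vp, q) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- (alpha - k21) / (alpha - beta)
  b <- (k21 - beta) / (alpha - beta)
  r0 <- dose / tinf
  f <- function(l, t) ifelse(t <= tinf,
                             1 - exp(-l * t),
                             (1 - exp(-l * tinf)) * exp(-l * (t - tinf)))
  (r0 / vc) * (a * f(alpha, pmax(times, 0)) / alpha +
               b * f(beta, pmax(times, 0)) / beta)
}

#' Simulate concentration-time profiles
#'
#' Draws per-patient two-compartment parameters with log-normal inter-patient
#' variability (geometric means preserved), optional log-normal
#' inter-occasion variability on clearance per dosing day, and evaluates the
#' infusion model at the protocol sampling times.  The pre-dose sample is
#' exactly 0 and all concentrations are non-negative.  No assay noise is
#' added: with all CVs 0 the output equals the closed-form kinetics.
#'
#' @param pop a [population_pk()].
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param days dosing-day labels (days 2 and 16 of cycle 1 under the
#'   protocol).  Inter-patient parameters are drawn once per patient and
#'   shared across days; only the inter-occasion clearance component is
#'   redrawn per day.
#' @param patient_ids optional ids (default `1:n_patients`).
#' @return long data frame `patient_id, cycle, day, time_h, conc_ng_ml,
#'   dose_ng, tinf_h`, with the drawn individual parameters attached as
#'   `attr(, "individual_params")` (one row per patient and day).
#' @export
simulate_pk_profiles <- function(pop, n_patients, seed = 1, days = 2,
                                 patient_ids = NULL) {
  stopifnot(inherits(pop, "population_pk"), n_patients >= 1,
            length(days) >= 1)
  if (is.null(patient_ids)) patient_ids <- seq_len(n_patients)
  stopifnot(length(patient_ids) == n_patients)
  set.seed(seed)
  sdlog <- function(cv) sqrt(log(1 + (cv / 100)^2))
  draw <- function(gm, cv) gm * exp(stats::rnorm(n_patients, 0, sdlog(cv)))
  cl <- draw(pop$cl_geomean, pop$iiv_cv["cl"])
  vc <- draw(pop$vc_geomean, pop$iiv_cv["vc"])
  vp <- draw(pop$vp_geomean, pop$iiv_cv["vp"])
  q <- draw(pop$q_geomean, pop$iiv_cv["q"])

  tt <- pop$sampling_times
  out <- NULL
  pars <- NULL
  for (day in days) {
    cl_occ <- cl * exp(stats::rnorm(n_patients, 0, sdlog(pop$iov_cv_cl)))
    rows <- lapply(seq_len(n_patients), function(i) {
      conc <- two_compartment_conc(tt, pop$dose, pop$infusion_duration,
                                   cl_occ[i], vc[i], vp[i], q[i])
      conc[tt == 0] <- 0  # pre-dose
      data.frame(patient_id = patient_ids[i], cycle = 1L, day = day,
                 time_h = tt, conc_ng_ml = conc,
                 dose_ng = pop$dose, tinf_h = pop$infusion_duration)
    })
    out <- rbind(out, do.call(rbind, rows))
    pars <- rbind(pars, data.frame(patient_id = patient_ids, day = day,
                                   cl_ml_h = cl_occ, vc_ml = vc,
                                   vp_ml = vp, q_ml_h = q))
  }
  attr(out, "individual_params") <- pars
  out
}

#' Default adverse-event incidence table
#'
#' Per-term, per-arm probabilities of a drug-related treatment-emergent
#' adverse event, taken from the incidence pattern of a gemcitabine +/- CHK1
#' inhibitor trial (most common terms: thrombocytopenia, nausea, fatigue,
#' neutropenia), with conditional grade-3/4 probabilities concentrated on
#' the hematological terms.
#'
#' @return data frame `term, arm, prob, p_grade3, p_grade4`.
#' @export
default_ae_incidence <- function() {
  terms <- c("thrombocytopenia", "nausea", "fatigue", "neutropenia",
             "anemia", "vomiting", "decreased appetite", "diarrhea",
             "pyrexia", "asthenia", "constipation", "leukopenia",
             "stomatitis", "alopecia", "oedema peripheral")
  p_e <- c(.323, .338, .246, .215, .138, .215, .185, .169,
           .138, .108, .138, .108, .154, .092, .108)
  p_c <- c(.412, .235, .294, .265, .265, .088, .088, .088,
           .147, .147, .088, .147, .029, .118, .059)
  hema <- terms %in% c("thrombocytopenia", "neutropenia", "anemia", "leukopenia")
  data.frame(
    term = rep(terms, 2),
    arm = rep(c("experimental", "control"), each = length(terms)),
    prob = c(p_e, p_c),
    p_grade3 = rep(ifelse(hema, 0.30, 0.08), 2),
    p_grade4 = rep(ifelse(hema, 0.05, 0.01), 2)
  )
}

#' Simulate adverse-event and ECG records for a trial dataset
#'
#' Adverse events are Bernoulli draws per patient and preferred term from an
#' incidence table (probabilities may differ by arm); severity grades are
#' drawn from the table's conditional grade-3/4 probabilities, remainder
#' split between grades 1 and 2.  ECG records (experimental arm, baseline
#' plus post-dose days 2 and 16) are constructed so that a configured
#' fraction of patients lands in the QTcF change-from-baseline categories
#' (30, 60] ms and > 60 ms.
#'
#' @param dataset a `trial_dataset` (only `patients` is used).
#' @param incidence_table data frame `term, arm, prob[, p_grade3, p_grade4]`;
#'   probabilities must lie in `[0, 1]`.
#' @param seed integer seed.
#' @param qtc_change_probs named vector `c(cat_30_60 = , cat_gt60 = )`:
#'   per-patient probabilities that the maximum post-baseline QTcF change
#'   falls in (30, 60] or exceeds 60 ms.
#' @return list with data frames `ae` (`patient_id, arm, term, grade,
#'   drug_related, treatment_emergent`) and `ecg`
#'   (`patient_id, timepoint, qt_ms, rr_s`).
#' @export
simulate_ae_and_ecg <- function(dataset,
                                incidence_table = default_ae_incidence(),
                                seed = 1,
                                qtc_change_probs = c(cat_30_60 = 0.08,
                                                     cat_gt60 = 0)) {
  stopifnot(inherits(dataset, "trial_dataset"),
            all(c("term", "arm", "prob") %in% names(incidence_table)))
  if (any(incidence_table$prob < 0 | incidence_table$prob > 1))
    stop("incidence probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(incidence_table$p_grade3)) incidence_table$p_grade3 <- 0.08
  if (is.null(incidence_table$p_grade4)) incidence_table$p_grade4 <- 0.01
  stopifnot(all(qtc_change_probs >= 0), sum(qtc_change_probs) <= 1)
  set.seed(seed)
  pts <- dataset$patients

  ae_rows <- lapply(seq_len(nrow(incidence_table)), function(j) {
    row <- incidence_table[j, ]
    ids <- pts$patient_id[pts$arm == row$arm]
    hit <- ids[stats::runif(length(ids)) < row$prob]
    if (!length(hit)) return(NULL)
    u <- stats::runif(length(hit))
    grade <- as.integer(ifelse(u < row$p_grade4, 4L,
                               ifelse(u < row$p_grade4 + row$p_grade3, 3L,
                                      sample(1:2, length(hit), replace = TRUE))))
    data.frame(patient_id = hit, arm = row$arm, term = row$term,
               grade = grade, drug_related = TRUE, treatment_emergent = TRUE)
  })
  ae <- do.call(rbind, ae_rows)
  if (is.null(ae))
    ae <- data.frame(patient_id = integer(), arm = character(),
                     term = character(), grade = integer(),
                     drug_related = logical(), treatment_emergent = logical())

  # ECG: draw each patient's maximum post-baseline QTcF change by category,
  # then back out QT from QTcF and RR (Fridericia)
  ids_e <- pts$patient_id[pts$arm == "experimental"]
  ne <- length(ids_e)
  u <- stats::runif(ne)
  p60 <- qtc_change_probs["cat_gt60"]
  p30 <- qtc_change_probs["cat_30_60"]
  dmax <- ifelse(u < p60, stats::runif(ne, 60.5, 80),
                 ifelse(u < p60 + p30, stats::runif(ne, 30.5, 60),
                        pmin(stats::rnorm(ne, 8, 9), 29.5)))
  qtcf0 <- stats::rnorm(ne, 400, 15)
  d2 <- dmax - abs(stats::rnorm(ne, 3, 3))        # day-2 change <= the max
  ecg_long <- data.frame(
    patient_id = rep(ids_e, 3),
    timepoint = rep(c("baseline", "day2", "day16"), each = ne),
    qtcf = c(qtcf0, qtcf0 + d2, qtcf0 + dmax)
  )
  ecg_long$rr_s <- stats::runif(nrow(ecg_long), 0.7, 1.1)
  ecg_long$qt_ms <- ecg_long$qtcf * ecg_long$rr_s^(1/3)
  ecg <- ecg_long[c("patient_id", "timepoint", "qt_ms", "rr_s")]
  list(ae = ae, ecg = ecg)
}
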