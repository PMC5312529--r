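# Synthetic trial generator: randomization, survival marginals, censoring
# bookkeeping, PK kinetics, AE/ECG plumbing.

test_that("block randomization realizes the configured ratio and datasets are seed-deterministic", {
  ds <- simulate_trial(trial_config(), seed = 7)
  tab <- table(ds$patients$arm)
  expect_equal(unname(tab[["experimental"]]), 66)
  expect_equal(unname(tab[["control"]]), 33)

  ds2 <- simulate_trial(trial_config(), seed = 7)
  expect_identical(ds$patients, ds2$patients)
  expect_identical(ds$pk, ds2$pk)
  expect_identical(ds$ae, ds2$ae)
  expect_identical(ds$ecg, ds2$ecg)

  ds3 <- simulate_trial(trial_config(), seed = 8)
  expect_false(identical(ds$patients$os_time, ds3$patients$os_time))

  # incomplete final block: sizes still within one block of the exact ratio
  ds4 <- simulate_trial(trial_config(n_total = 100), seed = 7,
                        tables = character(0))
  tab4 <- table(ds4$patients$arm)
  expect_equal(sum(tab4), 100)
  expect_true(abs(tab4[["experimental"]] - 200 / 3) < 2)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(response_probs_e = c(CR = 0.5, PR = 0.6, SD = 0,
                                                 PD = 0, NE = 0)),
               "summing to 1")
  expect_error(trial_config(n_total = 1))
  expect_error(trial_config(median_os_c = -1))
  expect_error(trial_config(median_pfs_c = 8))  # PFS median above OS median
})

test_that("uncensored control OS is exponential with the configured median", {
  cfg <- trial_config(n_total = 30000, accrual_duration = 0,
                      followup_duration = Inf, dropout_hazard = 0)
  ds <- simulate_trial(cfg, seed = 11, tables = character(0))
  ctl <- ds$patients[ds$patients$arm == "control", ]
  expect_true(all(ctl$os_event == 1))
  # large-sample median within 2% of 7 months
  expect_lt(abs(median(ctl$os_time) - 7) / 7, 0.02)
  # Kolmogorov-Smirnov against Exp(log 2 / 7) at n = 5000, alpha = 0.01
  ks <- suppressWarnings(
    ks.test(ctl$os_time[seq_len(5000)], "pexp", rate = log(2) / 7))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring bookkeeping and within-patient orderings hold", {
  cfg <- trial_config()
  ds <- simulate_trial(cfg, seed = 13, tables = "ca199")
  p <- ds$patients
  expect_true(all(p$os_event %in% c(0, 1)))
  expect_true(all(p$pfs_event %in% c(0, 1)))
  expect_true(all(p$os_time >= 0 & p$pfs_time >= 0))
  expect_true(all(p$pfs_time <= p$os_time + 1e-12))
  # censored patients stop at the administrative cutoff at the latest
  cutoff <- cfg$accrual_duration + cfg$followup_duration - p$entry_month
  cens <- p$os_event == 0
  expect_true(all(p$os_time[cens] <= cutoff[cens] + 1e-9))
  # responders shrink by week 8 (generator convention)
  resp <- p$best_response %in% c("CR", "PR")
  expect_true(all(p$week8_target_sum_mm[resp] < p$baseline_target_sum_mm[resp]))
})

test_that("best-response frequencies converge to the configured probabilities", {
  cfg <- trial_config(n_total = 20000, accrual_duration = 0,
                      followup_duration = Inf, dropout_hazard = 0)
  ds <- simulate_trial(cfg, seed = 17, tables = character(0))
  p <- ds$patients
  for (arm in c("experimental", "control")) {
    probs <- if (arm == "experimental") cfg$response_probs_e else
      cfg$response_probs_c
    obs <- table(p$best_response[p$arm == arm]) / sum(p$arm == arm)
    expect_lt(max(abs(obs[names(probs)] - probs)), 0.02)
  }
})

test_that("PK generator reduces to closed-form kinetics when variability is off", {
  pop <- population_pk(iiv_cv = c(cl = 0, vc = 0, vp = 0, q = 0),
                       iov_cv_cl = 0)
  prof <- simulate_pk_profiles(pop, n_patients = 3, seed = 1, days = 2)
  truth <- two_compartment_conc(pop$sampling_times, pop$dose,
                                pop$infusion_duration, pop$cl_geomean,
                                pop$vc_geomean, pop$vp_geomean, pop$q_geomean)
  truth[pop$sampling_times == 0] <- 0
  for (id in unique(prof$patient_id)) {
    obs <- prof$conc_ng_ml[prof$patient_id == id]
    expect_lt(max(abs(obs[-1] - truth[-1]) / truth[-1]), 1e-9)
    expect_identical(obs[1], 0)  # pre-dose sample
  }
})

test_that("PK inter-patient variability preserves geometric means", {
  pop <- population_pk()
  prof <- simulate_pk_profiles(pop, n_patients = 500, seed = 19, days = 2)
  pars <- attr(prof, "individual_params")
  # geometric mean CL within 10% of the configured truth (IOV included,
  # which is mean-preserving on the log scale)
  expect_lt(abs(exp(mean(log(pars$cl_ml_h))) - pop$cl_geomean) /
              pop$cl_geomean, 0.10)
  expect_true(all(prof$conc_ng_ml >= 0))
})

test_that("cohort geometric-mean Cmax brackets the observed exposure scale", {
  pop <- population_pk()
  prof <- simulate_pk_profiles(pop, n_patients = 500, seed = 23, days = 2)
  cmax <- vapply(split(prof$conc_ng_ml, prof$patient_id), max, numeric(1))
  gm <- exp(mean(log(cmax)))
  expect_gt(gm, 2500)
  expect_lt(gm, 4000)
})

test_that("adverse-event draws respect degenerate and calibrated incidences", {
  ds <- simulate_trial(trial_config(), seed = 29, tables = character(0))
  tab0 <- default_ae_incidence()
  tab0$prob <- 0
  none <- simulate_ae_and_ecg(ds, tab0, seed = 1)
  expect_equal(nrow(none$ae), 0)

  tab1 <- data.frame(term = "nausea", arm = "experimental", prob = 1)
  all_e <- simulate_ae_and_ecg(ds, tab1, seed = 1)
  expect_equal(nrow(all_e$ae), sum(ds$patients$arm == "experimental"))

  expect_error(simulate_ae_and_ecg(ds, data.frame(term = "x",
                                                  arm = "control",
                                                  prob = 1.2), seed = 1),
               "\\[0, 1\\]")

  # Bernoulli calibration: nausea at 0.338 in an arm of 66 -> mean count
  # near 22.3 over replicates
  tabn <- data.frame(term = "nausea", arm = "experimental", prob = 0.338)
  counts <- vapply(1:300, function(s)
    nrow(simulate_ae_and_ecg(ds, tabn, seed = s)$ae), numeric(1))
  n_e <- sum(ds$patients$arm == "experimental")
  expect_lt(abs(mean(counts) - 0.338 * n_e), 1.0)
})

test_that("ECG generator places the configured fraction in each QTcF change category", {
  ds <- simulate_trial(trial_config(n_total = 3000, accrual_duration = 0,
                                    followup_duration = Inf,
                                    dropout_hazard = 0),
                       seed = 31, tables = character(0))
  sae <- simulate_ae_and_ecg(ds, seed = 5,
                             qtc_change_probs = c(cat_30_60 = 0.3,
                                                  cat_gt60 = 0.1))
  qc <- qtcf_change_categories(sae$ecg)
  frac <- as.numeric(qc$counts) / sum(qc$counts)
  expect_lt(abs(frac[2] - 0.3), 0.03)
  expect_lt(abs(frac[3] - 0.1), 0.02)
})
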