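# Noncompartmental analysis: trapezoid integration, terminal-slope fitting,
# profile-level parameters against closed-form kinetics, cohort summaries,
# exposure-target attainment.

test_that("trapezoid AUC handles triangles, zeros, and exponential decay", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 100)), 50)
  expect_equal(auc_trapezoid(c(0, 5, 10), rep(0, 3)), 0)

  # dense mono-exponential, log-down within 0.01% of the analytic integral
  tt <- seq(0, 24, by = 0.1)
  cc <- 1000 * exp(-0.1 * tt)
  analytic <- 1000 / 0.1 * (1 - exp(-0.1 * 24))
  expect_lt(abs(auc_trapezoid(tt, cc) - analytic) / analytic, 1e-4)

  # at protocol-like sparse sampling the log-down rule stays within 0.1%
  # while the pure-linear trapezoid overestimates a convex decay
  tsp <- c(0, 1, 2, 4, 8, 12, 24)
  csp <- 1000 * exp(-0.1 * tsp)
  a_log <- auc_trapezoid(tsp, csp)
  a_lin <- auc_trapezoid(tsp, csp, method = "linear")
  expect_lt(abs(a_log - analytic) / analytic, 0.001)
  expect_gt(a_lin, analytic)

  expect_error(auc_trapezoid(c(2, 4), c(1, 1), t_end = 1), "precedes")
})

test_that("AUC is additive across any interior split point", {
  # profile with a rise, zeros at the start, and a log-down tail
  tt <- c(0, 1, 2, 4, 8, 25)
  cc <- c(0, 3000, 2400, 1600, 800, 300)
  full <- auc_trapezoid(tt, cc)
  # oracle interpolation: log inside decreasing positive segments (where the
  # log-down rule integrates), linear elsewhere
  interp <- function(a) {
    i <- findInterval(a, tt)
    t1 <- tt[i]; t2 <- tt[i + 1]; c1 <- cc[i]; c2 <- cc[i + 1]
    if (c1 > 0 && c2 > 0 && c2 < c1) {
      k <- log(c1 / c2) / (t2 - t1)
      c1 * exp(-k * (a - t1))
    } else c1 + (c2 - c1) * (a - t1) / (t2 - t1)
  }
  set.seed(14)
  for (a in c(runif(6, 0.1, 24.5), 1.5, 3, 13.7)) {
    left <- auc_trapezoid(tt, cc, t_end = a)
    keep <- tt > a
    right <- auc_trapezoid(c(a, tt[keep]), c(interp(a), cc[keep]))
    expect_equal(left + right, full, tolerance = 1e-10)
  }
})

test_that("lambda-z fitting recovers slopes and flags non-estimable profiles", {
  tt <- c(1, 2, 4, 8, 12, 24)
  fit <- lambda_z_fit(tt, 1000 * exp(-0.1 * tt))
  expect_true(fit$estimable)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(log(2) / fit$lambda_z, 6.93, tolerance = 1e-3)
  # noise-free log-linearity: all candidate sets tie, the largest wins
  expect_equal(fit$n_points, 5)  # tmax excluded

  # two-compartment profile at protocol times: fitted lambda-z within 10%
  # of the slow eigenvalue of the configured system
  pop <- population_pk()
  tt2 <- pop$sampling_times
  cc2 <- two_compartment_conc(tt2, pop$dose, pop$infusion_duration,
                              pop$cl_geomean, pop$vc_geomean,
                              pop$vp_geomean, pop$q_geomean)
  beta <- two_cmt_beta(pop$cl_geomean, pop$vc_geomean, pop$vp_geomean,
                       pop$q_geomean)
  fit2 <- lambda_z_fit(tt2, cc2)
  expect_true(fit2$estimable)
  expect_lt(abs(fit2$lambda_z - beta) / beta, 0.25)
  expect_equal(fit2$n_points, 3)  # the 2, 4, 25 h points

  # rising profile -> not estimable
  expect_false(lambda_z_fit(c(1, 2, 4, 8), c(10, 20, 30, 40))$estimable)
  # fewer than 3 post-peak points -> not estimable
  expect_false(lambda_z_fit(c(1, 2, 4), c(100, 80, 60))$estimable)
})

test_that("profile NCA recovers closed-form one-compartment truth", {
  dose <- 230e6; cl <- 7790; v <- 104000; tinf <- 1
  tt <- seq(0, 72, by = 0.05)
  cc <- one_cmt_conc(tt, dose, tinf, cl, v)
  res <- nca_profile(tt, cc, dose = dose, tinf = tinf)
  expect_lt(abs(res$cl - cl) / cl, 0.01)
  expect_lt(abs(res$vss - v) / v, 0.03)
  expect_equal(res$t_half, log(2) / (cl / v), tolerance = 0.01)
  # definitional identities
  expect_equal(res$cl, dose / res$auc0_inf, tolerance = 1e-12)
  expect_equal(res$cav24, res$auc0_24 / 24, tolerance = 1e-12)
  expect_equal(res$pct_extrap,
               100 * (res$auc0_inf - res$auc0_tlast) / res$auc0_inf,
               tolerance = 1e-12)
  expect_equal(res$t_half, log(2) / res$lambda_z, tolerance = 1e-12)
  expect_true(res$auc0_tlast <= res$auc0_inf)
})

test_that("lambda-z failure degrades the result instead of failing it", {
  res <- nca_profile(c(0, 1, 2, 4, 25), c(0, 10, 20, 30, 40), dose = 1e6)
  expect_true(is.na(res$auc0_inf))
  expect_true(is.na(res$cl))
  expect_true(is.na(res$t_half))
  expect_equal(res$cmax, 40)
  expect_false(is.na(res$auc0_24))
})

test_that("cohort summary implements the lognormal geometric-mean/CV conventions", {
  mk <- function(x, id, day = 2) {
    r <- nca_profile(c(0, 1, 2, 4, 25), c(0, x, x * 0.7, x * 0.45, x * 0.08),
                     dose = 230e6, patient_id = id, day = day)
    r
  }
  s1 <- summarize_cohort(list(mk(3000, 1)))
  row <- s1$parameters[s1$parameters$parameter == "cmax", ]
  expect_equal(row$geomean, 3000)
  expect_equal(row$cv_pct, 0)

  s2 <- summarize_cohort(list(mk(10, 1), mk(1000, 2)))
  expect_equal(s2$parameters$geomean[s2$parameters$parameter == "cmax"], 100)

  # lognormal CV identity: sigma_log = 0.472 -> CV ~ 50%
  set.seed(15)
  x <- rlnorm(10000, log(100), 0.472)
  expect_lt(abs(geocv_pct(x) - 50), 2)

  # paired accumulation ratio: geomean of ratios equals ratio of geomeans
  profs <- c(lapply(1:6, function(i) mk(1000 * i, i, day = 2)),
             lapply(1:6, function(i) mk(1300 * i, i, day = 16)))
  s3 <- summarize_cohort(profs)
  g2 <- s3$parameters$geomean[s3$parameters$parameter == "auc0_inf" &
                              s3$parameters$day == 2]
  g16 <- s3$parameters$geomean[s3$parameters$parameter == "auc0_inf" &
                               s3$parameters$day == 16]
  expect_equal(s3$accumulation$geomean, g16 / g2, tolerance = 1e-10)
})

test_that("synthetic cohort NCA brackets the reference exposure scale", {
  pop <- population_pk()
  prof <- simulate_pk_profiles(pop, n_patients = 500, seed = 16, days = 2)
  results <- nca_cohort(prof)
  s <- summarize_cohort(results)
  th <- s$parameters[s$parameters$parameter == "t_half", ]
  expect_gt(th$geomean, 7); expect_lt(th$geomean, 13)
  cm <- s$parameters[s$parameters$parameter == "cmax", ]
  expect_gt(cm$geomean, 2500); expect_lt(cm$geomean, 4000)

  att <- exposure_target_attainment(results)
  pooled <- att[att$day == "pooled", ]
  expect_gt(pooled$frac_cmax, 0.70); expect_lt(pooled$frac_cmax, 0.95)
})

test_that("exposure-target attainment fractions hit the trivial bounds", {
  mk <- function(x, id) nca_profile(c(0, 1, 2, 4, 25),
                                    c(0, x, x * 0.7, x * 0.45, x * 0.08),
                                    dose = 230e6, patient_id = id, day = 2)
  res <- lapply(c(5000, 6000), function(x) mk(x, x))
  att <- exposure_target_attainment(res, auc_target = 1, cmax_target = 1)
  expect_true(all(att$frac_cmax == 1) && all(att$frac_auc == 1))
  att0 <- exposure_target_attainment(res, auc_target = Inf, cmax_target = Inf)
  expect_true(all(att0$frac_cmax == 0) && all(att0$frac_auc == 0))
})
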