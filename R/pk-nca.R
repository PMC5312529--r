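# Noncompartmental pharmacokinetic analysis.  Model-free parameter
# estimation from concentration-time profiles: trapezoidal AUC/AUMC with
# the linear-up/log-down rule, terminal-slope (lambda-z) regression with
# best-adjusted-R2 point selection, and the derived parameters Cmax, tmax,
# AUC(0-24), AUC(0-inf), t1/2, CL, MRT (with infusion correction), Vss.

# internal: per-segment AUC and AUMC between consecutive samples.
# Log-down applies when both concentrations are positive and strictly
# decreasing; otherwise the linear trapezoid (which also covers zeros).
.segment_areas <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  logdown <- method == "linear-up/log-down" && c1 > 0 && c2 > 0 && c2 < c1
  if (logdown) {
    k <- log(c1 / c2) / dt
    auc <- (c1 - c2) / k
    aumc <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
  } else {
    auc <- (c1 + c2) / 2 * dt
    aumc <- (t1 * c1 + t2 * c2) / 2 * dt
  }
  c(auc = auc, aumc = aumc)
}

# internal: concentration interpolated at t inside segment [t1, t2],
# consistent with the integration rule of that segment (this consistency
# is what makes AUC additive across any interior split point)
.interp_conc <- function(t, t1, t2, c1, c2, method) {
  if (method == "linear-up/log-down" && c1 > 0 && c2 > 0 && c2 < c1) {
    k <- log(c1 / c2) / (t2 - t1)
    c1 * exp(-k * (t - t1))
  } else {
    c1 + (c2 - c1) * (t - t1) / (t2 - t1)
  }
}

#' Trapezoidal area under a concentration-time curve
#'
#' Piecewise trapezoidal AUC from the first sample to `t_end`.  Under the
#' default linear-up/log-down rule a segment is integrated on the log scale
#' when both endpoint concentrations are positive and decreasing, and
#' linearly otherwise; `method = "linear"` forces the linear trapezoid
#' everywhere.  When `t_end` falls between samples the concentration there
#' is interpolated consistently with the rule active in that segment, so
#' AUC is exactly additive across any interior split point.
#'
#' @param times strictly increasing sampling times, hours.
#' @param conc concentrations, ng/mL, same length.
#' @param method `"linear-up/log-down"` (default) or `"linear"`.
#' @param t_end end of integration; defaults to the last sample and must
#'   not precede the first or exceed the last.
#' @return AUC in ng*h/mL.
#' @examples
#' auc_trapezoid(c(0, 1), c(0, 100))  # 50
#' @export
auc_trapezoid <- function(times, conc,
                          method = c("linear-up/log-down", "linear"),
                          t_end = NULL) {
  method <- match.arg(method)
  .auc_aumc(times, conc, method, t_end)[["auc"]]
}

# internal: AUC and AUMC together (AUMC uses the matching rule flavor)
.auc_aumc <- function(times, conc, method, t_end = NULL) {
  stopifnot(length(times) >= 2, length(times) == length(conc),
            all(diff(times) > 0), all(conc >= 0))
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_end < times[1])
    stop("t_end precedes the first sample", call. = FALSE)
  if (t_end > times[length(times)])
    stop("t_end beyond the last sample; no extrapolation here", call. = FALSE)
  auc <- 0; aumc <- 0
  for (i in seq_len(length(times) - 1)) {
    t1 <- times[i]; t2 <- times[i + 1]
    if (t_end <= t1) break
    c1 <- conc[i]; c2 <- conc[i + 1]
    if (t_end < t2) {
      c2 <- .interp_conc(t_end, t1, t2, c1, c2, method)
      t2 <- t_end
    }
    a <- .segment_areas(t1, t2, c1, c2, method)
    auc <- auc + a["auc"]; aumc <- aumc + a["aumc"]
  }
  c(auc = unname(auc), aumc = unname(aumc))
}

#' Terminal elimination rate constant (lambda-z)
#'
#' Log-linear regression on the terminal phase.  Candidate point sets are
#' the `k` latest samples with positive concentration strictly after tmax,
#' for every `k >= 3`; the set with the best adjusted R-squared wins, with
#' ties (within 1e-4) going to the larger set.  The slope must be negative;
#' otherwise the result is flagged not estimable, and parameters that
#' depend on lambda-z are reported as missing downstream.
#'
#' @param times sampling times, hours.
#' @param conc concentrations, ng/mL.
#' @return list: `estimable`, `lambda_z` (1/h), `n_points`, `adj_r2`,
#'   `intercept` (log ng/mL at time 0 of the fit).
#' @examples
#' tt <- c(2, 4, 8, 12, 24)
#' lambda_z_fit(tt, 1000 * exp(-0.1 * tt))$lambda_z  # 0.1
#' @export
lambda_z_fit <- function(times, conc) {
  stopifnot(length(times) == length(conc), all(diff(times) > 0))
  not_est <- list(estimable = FALSE, lambda_z = NA_real_,
                  n_points = NA_integer_, adj_r2 = NA_real_,
                  intercept = NA_real_)
  imax <- which.max(conc)
  use <- which(seq_along(times) > imax & conc > 0)
  if (length(use) < 3) return(not_est)
  best <- NULL
  for (k in 3:length(use)) {
    idx <- use[(length(use) - k + 1):length(use)]
    x <- times[idx]; y <- log(conc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (slope >= 0) next
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (adj >= best$adj_r2 - 1e-4 && k > best$n_points)) {
      best <- list(estimable = TRUE, lambda_z = unname(-slope),
                   n_points = k, adj_r2 = unname(adj),
                   intercept = unname(fit$coefficients[1]))
    }
  }
  if (is.null(best)) not_est else best
}

#' Noncompartmental analysis of one concentration-time profile
#'
#' Computes the full NCA parameter set for a single-dose infusion profile:
#' Cmax and tmax from the observed samples; AUC(0-24) by interpolation to
#' 24 h from the start of infusion; AUC and AUMC to the last positive
#' concentration and, when lambda-z is estimable, extrapolated to infinity
#' (`AUC(0-inf) = AUC(0-tlast) + Clast / lambda_z`); t1/2 = ln 2 / lambda_z;
#' CL = dose / AUC(0-inf); MRT = AUMC(0-inf)/AUC(0-inf) - tinf/2 (infusion
#' correction); Vss = CL * MRT; Cav,24 = AUC(0-24)/24; percent of AUC
#' extrapolated.  When lambda-z is not estimable the dependent parameters
#' are `NA` while Cmax, tmax and AUC(0-24) are still reported.
#'
#' @param times hours from the start of infusion, strictly increasing.
#' @param conc concentrations, ng/mL.
#' @param dose administered dose, ng.
#' @param tinf infusion duration, hours.
#' @param patient_id,day optional labels carried into the result.
#' @param method integration rule, see [auc_trapezoid()].
#' @return object of class `nca_result` (a named list of parameters).
#' @export
nca_profile <- function(times, conc, dose, tinf = 1,
                        patient_id = NA, day = NA,
                        method = "linear-up/log-down") {
  stopifnot(length(times) >= 2, length(times) == length(conc),
            all(diff(times) > 0), all(conc >= 0), dose > 0, tinf > 0)
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- times[imax]
  pos <- which(conc > 0)
  tlast <- if (length(pos)) times[max(pos)] else NA_real_
  clast <- if (length(pos)) conc[max(pos)] else NA_real_

  auc24 <- if (max(times) >= 24)
    auc_trapezoid(times, conc, method, t_end = 24) else NA_real_

  out <- list(patient_id = patient_id, day = day,
              cmax = cmax, tmax = tmax,
              cav24 = if (is.na(auc24)) NA_real_ else auc24 / 24,
              auc0_24 = auc24,
              auc0_tlast = NA_real_, auc0_inf = NA_real_,
              pct_extrap = NA_real_, lambda_z = NA_real_,
              t_half = NA_real_, cl = NA_real_, mrt = NA_real_,
              vss = NA_real_,
              lambda_z_n_points = NA_integer_, lambda_z_adj_r2 = NA_real_,
              dose = dose, tinf = tinf)
  if (is.na(tlast)) return(structure(out, class = "nca_result"))

  areas <- .auc_aumc(times, conc, method, t_end = tlast)
  out$auc0_tlast <- areas[["auc"]]

  lz <- lambda_z_fit(times, conc)
  out$lambda_z_n_points <- lz$n_points
  out$lambda_z_adj_r2 <- lz$adj_r2
  if (lz$estimable) {
    l <- lz$lambda_z
    out$lambda_z <- l
    out$t_half <- log(2) / l
    out$auc0_inf <- areas[["auc"]] + clast / l
    aumc_inf <- areas[["aumc"]] + tlast * clast / l + clast / l^2
    out$pct_extrap <- 100 * (out$auc0_inf - out$auc0_tlast) / out$auc0_inf
    out$cl <- dose / out$auc0_inf
    out$mrt <- aumc_inf / out$auc0_inf - tinf / 2
    out$vss <- out$cl * out$mrt
  }
  structure(out, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("NCA result (patient %s, day %s): Cmax %.4g ng/mL at %.2g h\n",
              as.character(x$patient_id), as.character(x$day),
              x$cmax, x$tmax))
  if (!is.na(x$auc0_inf))
    cat(sprintf("  AUC(0-inf) %.4g ng*h/mL (%.1f%% extrapolated), t1/2 %.3g h, CL %.4g mL/h, Vss %.4g mL\n",
                x$auc0_inf, x$pct_extrap, x$t_half, x$cl, x$vss))
  else
    cat("  lambda-z not estimable; exposure parameters limited to AUC(0-24)\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(patient_id = x$patient_id, day = x$day, cmax = x$cmax,
             tmax = x$tmax, cav24 = x$cav24, auc0_24 = x$auc0_24,
             auc0_tlast = x$auc0_tlast, auc0_inf = x$auc0_inf,
             pct_extrap = x$pct_extrap, lambda_z = x$lambda_z,
             t_half = x$t_half, cl = x$cl, mrt = x$mrt, vss = x$vss,
             lambda_z_n_points = x$lambda_z_n_points,
             lambda_z_adj_r2 = x$lambda_z_adj_r2)
}

#' Run NCA over a long-format PK sample table
#'
#' Splits a table of samples (`patient_id, day, time_h, conc_ng_ml,
#' dose_ng, tinf_h`, as written by [simulate_pk_profiles()]) into profiles
#' and applies [nca_profile()] to each.
#'
#' @param pk long-format PK data frame.
#' @return list of `nca_result` objects.
#' @export
nca_cohort <- function(pk) {
  need <- c("patient_id", "day", "time_h", "conc_ng_ml", "dose_ng", "tinf_h")
  stopifnot(all(need %in% names(pk)))
  groups <- split(pk, interaction(pk$patient_id, pk$day, drop = TRUE))
  unname(lapply(groups, function(g) {
    g <- g[order(g$time_h), ]
    nca_profile(g$time_h, g$conc_ng_ml, dose = g$dose_ng[1],
                tinf = g$tinf_h[1], patient_id = g$patient_id[1],
                day = g$day[1])
  }))
}

#' Cohort summary of NCA parameters (geometric mean, CV%)
#'
#' Summarizes each NCA parameter per dosing day as geometric mean with
#' log-scale percent CV (`100 * sqrt(exp(s_log^2) - 1)`) and the number of
#' contributing profiles; tmax is summarized as median (range).  The
#' intra-cycle accumulation ratio is the per-patient ratio of day-16 to
#' day-2 AUC(0-inf), summarized the same way.  Nonpositive values cannot
#' enter a log-scale summary and are excluded with a recorded count.
#'
#' @param results list of `nca_result` objects (see [nca_cohort()]).
#' @return object of class `cohort_pk_summary`: data frame `parameters`
#'   (`parameter, day, geomean, cv_pct, n`), data frame `tmax`
#'   (`day, median, min, max, n`), data frame `accumulation`
#'   (geomean/CV of the day16/day2 ratio), `n_excluded_nonpositive`.
#' @export
summarize_cohort <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "nca_result")))
  df <- do.call(rbind, lapply(results, as.data.frame))
  params <- c("cmax", "cav24", "auc0_24", "auc0_tlast", "auc0_inf",
              "pct_extrap", "lambda_z", "t_half", "cl", "mrt", "vss")
  excluded <- 0L
  rows <- list()
  for (d in sort(unique(df$day))) {
    sub <- df[df$day == d, ]
    for (p in params) {
      x <- sub[[p]]
      x <- x[!is.na(x)]
      npos <- sum(x > 0)
      excluded <- excluded + sum(x <= 0)
      x <- x[x > 0]
      if (!length(x)) next
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, day = d, geomean = geomean(x),
        cv_pct = geocv_pct(x), n = npos)
    }
  }
  if (excluded > 0)
    warning(excluded, " nonpositive value(s) excluded from log-scale summaries")
  tmax_tab <- do.call(rbind, lapply(sort(unique(df$day)), function(d) {
    x <- df$tmax[df$day == d & !is.na(df$tmax)]
    data.frame(day = d, median = stats::median(x), min = min(x),
               max = max(x), n = length(x))
  }))
  wide <- df[!is.na(df$auc0_inf), c("patient_id", "day", "auc0_inf")]
  acc <- NULL
  if (all(c(2, 16) %in% wide$day)) {
    d2 <- wide[wide$day == 2, ]
    d16 <- wide[wide$day == 16, ]
    m <- merge(d2, d16, by = "patient_id", suffixes = c("_d2", "_d16"))
    if (nrow(m) >= 1) {
      ra <- m$auc0_inf_d16 / m$auc0_inf_d2
      acc <- data.frame(parameter = "ra_intracycle", geomean = geomean(ra),
                        cv_pct = geocv_pct(ra), n = length(ra))
    }
  }
  structure(list(parameters = do.call(rbind, rows), tmax = tmax_tab,
                 accumulation = acc,
                 n_excluded_nonpositive = excluded),
            class = "cohort_pk_summary")
}

#' @export
print.cohort_pk_summary <- function(x, ...) {
  cat("Cohort PK summary: geometric mean (CV%) by day\n")
  tab <- x$parameters
  for (d in unique(tab$day)) {
    cat(sprintf(" Day %g:\n", d))
    sub <- tab[tab$day == d, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-11s %.4g (%.0f)  n=%d\n", sub$parameter[i],
                  sub$geomean[i], sub$cv_pct[i], sub$n[i]))
    tm <- x$tmax[x$tmax$day == d, ]
    if (nrow(tm))
      cat(sprintf("  %-11s %.3g (%.3g-%.3g)  n=%d  [median (range)]\n",
                  "tmax", tm$median, tm$min, tm$max, tm$n))
  }
  if (!is.null(x$accumulation))
    cat(sprintf(" Intracycle accumulation ratio: %.3g (%.0f)  n=%d\n",
                x$accumulation$geomean, x$accumulation$cv_pct,
                x$accumulation$n))
  invisible(x)
}

#' Exposure-target attainment fractions
#'
#' Fraction of profiles meeting the systemic exposure targets (inclusive
#' thresholds) associated with maximal pharmacodynamic effect:
#' `AUC(0-inf) >= auc_target` and `Cmax >= cmax_target`, reported per
#' dosing day and pooled.
#'
#' @param results list of `nca_result`s.
#' @param auc_target ng*h/mL (default 21000).
#' @param cmax_target ng/mL (default 2000).
#' @return data frame `day, n_cmax, frac_cmax, n_auc, frac_auc` with a
#'   final `"pooled"` row.
#' @export
exposure_target_attainment <- function(results, auc_target = 21000,
                                       cmax_target = 2000) {
  df <- do.call(rbind, lapply(results, as.data.frame))
  one <- function(sub, label) {
    cm <- sub$cmax[!is.na(sub$cmax)]
    au <- sub$auc0_inf[!is.na(sub$auc0_inf)]
    data.frame(day = label,
               n_cmax = length(cm),
               frac_cmax = if (length(cm)) mean(cm >= cmax_target) else NA_real_,
               n_auc = length(au),
               frac_auc = if (length(au)) mean(au >= auc_target) else NA_real_)
  }
  out <- do.call(rbind, lapply(sort(unique(df$day)),
                               function(d) one(df[df$day == d, ],
                                               as.character(d))))
  rbind(out, one(df, "pooled"))
}
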