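# End-to-end orchestration: dataset I/O as CSV, the demographics table, and
# the full pipeline producing a report bundle shaped like a clinical study
# report (demographics, efficacy, safety, PK, Bayesian decision block).

#' Write / read a trial dataset as plain CSV tables
#'
#' `write_trial_dataset()` writes `patients.csv`, `pk_samples.csv`,
#' `ae.csv`, `ecg.csv`, `ca199.csv` into `dir`; `read_trial_dataset()`
#' reads them back into a `trial_dataset` (the config is not round-tripped;
#' analyses only need the tables).
#'
#' @param dataset a `trial_dataset`.
#' @param dir target directory (created if missing).
#' @return `write_trial_dataset()` returns `dir` invisibly;
#'   `read_trial_dataset()` returns a `trial_dataset`.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$pk))
    utils::write.csv(dataset$pk, file.path(dir, "pk_samples.csv"),
                     row.names = FALSE)
  if (!is.null(dataset$ae))
    utils::write.csv(dataset$ae, file.path(dir, "ae.csv"), row.names = FALSE)
  if (!is.null(dataset$ecg))
    utils::write.csv(dataset$ecg, file.path(dir, "ecg.csv"), row.names = FALSE)
  if (!is.null(dataset$ca199))
    utils::write.csv(dataset$ca199, file.path(dir, "ca199.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(dir) {
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  patients <- read_opt("patients.csv")
  if (is.null(patients)) stop("patients.csv not found in ", dir, call. = FALSE)
  patients$arm <- factor(patients$arm, levels = ARM_LEVELS)
  if ("best_response" %in% names(patients))
    patients$best_response <- factor(patients$best_response,
                                     levels = c("CR", "PR", "SD", "PD", "NE"))
  if ("stage" %in% names(patients))
    patients$stage <- factor(patients$stage,
                             levels = c("II", "III", "IV", "Unknown"))
  structure(list(patients = patients, ca199 = read_opt("ca199.csv"),
                 pk = read_opt("pk_samples.csv"), ae = read_opt("ae.csv"),
                 ecg = read_opt("ecg.csv"), config = NULL, seed = NA),
            class = "trial_dataset")
}

#' Baseline demographics and disease characteristics table
#'
#' Per-arm n (%) for sex, disease stage and ECOG performance status, and
#' mean/SD/median/range for age and body surface area, plus the pooled
#' Stage IV proportion.  With a single patient in an arm the SD is `NA`.
#'
#' @param dataset a `trial_dataset` (or a list with a `patients` table
#'   holding `arm, age_years, sex, bsa_m2, stage, ecog`).
#' @return object of class `demographics_table`: `continuous` (data frame),
#'   `categorical` (data frame of counts and percentages),
#'   `pooled_stage_iv_pct`.
#' @export
demographics_table <- function(dataset) {
  pts <- if (inherits(dataset, "trial_dataset")) dataset$patients else
    dataset$patients
  stopifnot(!is.null(pts), all(c("arm", "age_years", "sex", "bsa_m2",
                                 "stage", "ecog") %in% names(pts)))
  arms <- c("experimental", "control")
  cont <- do.call(rbind, lapply(arms, function(a) {
    sub <- pts[pts$arm == a, ]
    do.call(rbind, lapply(c("age_years", "bsa_m2"), function(v) {
      x <- sub[[v]]
      data.frame(arm = a, variable = v, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 median = stats::median(x), min = min(x), max = max(x))
    }))
  }))
  cat_rows <- list()
  for (a in arms) {
    sub <- pts[pts$arm == a, ]
    for (v in c("sex", "stage", "ecog")) {
      tab <- table(sub[[v]])
      for (l in names(tab)) {
        cat_rows[[length(cat_rows) + 1]] <- data.frame(
          arm = a, variable = v, level = l, n = as.integer(tab[[l]]),
          pct = 100 * tab[[l]] / nrow(sub))
      }
    }
  }
  categorical <- do.call(rbind, cat_rows)
  pooled_iv <- 100 * sum(pts$stage == "IV") / nrow(pts)
  structure(list(continuous = cont, categorical = categorical,
                 pooled_stage_iv_pct = pooled_iv),
            class = "demographics_table")
}

#' @export
print.demographics_table <- function(x, ...) {
  cat("Baseline demographics\n")
  for (i in seq_len(nrow(x$continuous))) {
    r <- x$continuous[i, ]
    cat(sprintf("  %-12s %-12s mean %.1f (SD %s), median %.1f, range %.4g-%.4g\n",
                r$arm, r$variable, r$mean,
                if (is.na(r$sd)) "NA" else sprintf("%.1f", r$sd),
                r$median, r$min, r$max))
  }
  cat(sprintf("  pooled Stage IV: %s%%\n",
              fmt_pct1(x$pooled_stage_iv_pct / 100)))
  invisible(x)
}

#' Run the complete analysis pipeline on a trial dataset
#'
#' Executes every analysis stage in order -- Kaplan-Meier OS/PFS by arm,
#' one-sided log-rank sensitivity test, Bayesian augmented-control decision,
#' response/clinical-benefit endpoints, tumor-size change test, CA19-9
#' response, noncompartmental PK cohort summary with exposure-target
#' attainment, safety incidence tables (all-grade >= 10%, grade-3/4 >= 5%),
#' and QTcF change categories -- and collects the results into a report
#' bundle.  Sections whose input tables are absent are marked absent rather
#' than failing.  Re-running on the same dataset gives an identical bundle.
#'
#' @param dataset a `trial_dataset` from [simulate_trial()] or
#'   [read_trial_dataset()]; alternatively `NULL` to simulate one from
#'   `config` and `seed`.
#' @param config,seed used only when `dataset` is `NULL`.
#' @param historical,a0,threshold Bayesian analysis settings (see
#'   [bayes_os_analysis()]).
#' @return object of class `report_bundle`: `demographics`, `km_os`,
#'   `km_pfs` (per-arm `km_curve`s), `logrank`, `bayes`, `response`,
#'   `tumor_change`, `ca199`, `pk_summary`, `pk_attainment`, `safety_all`,
#'   `safety_g34`, `qtcf`, `meta`.
#' @export
run_pipeline <- function(dataset = NULL, config = trial_config(), seed = 1,
                         historical = default_historical_control(),
                         a0 = 0.15, threshold = 0.8) {
  if (is.null(dataset)) dataset <- simulate_trial(config, seed)
  stopifnot(inherits(dataset, "trial_dataset"))
  pts <- dataset$patients
  e <- pts$arm == "experimental"
  arm_sizes <- c(experimental = sum(e), control = sum(!e))

  km_arm <- function(time, status) list(
    experimental = km_estimate(time[e], status[e]),
    control = km_estimate(time[!e], status[!e]))
  km_os <- km_arm(pts$os_time, pts$os_event)
  km_pfs <- km_arm(pts$pfs_time, pts$pfs_event)
  lr <- logrank_one_sided(pts$os_time[e], pts$os_event[e],
                          pts$os_time[!e], pts$os_event[!e])
  bayes <- bayes_os_analysis(pts, historical = historical, a0 = a0,
                             threshold = threshold)
  resp <- response_summary(pts)
  deltas <- 100 * (pts$week8_target_sum_mm - pts$baseline_target_sum_mm) /
    pts$baseline_target_sum_mm
  tumor <- tumor_change_test(deltas[e], deltas[!e])
  ca <- if (!is.null(dataset$ca199)) ca199_summary(dataset) else NULL

  pk_summary <- NULL; pk_att <- NULL
  if (!is.null(dataset$pk) && nrow(dataset$pk)) {
    results <- nca_cohort(dataset$pk)
    pk_summary <- summarize_cohort(results)
    pk_att <- exposure_target_attainment(results)
  }
  safety_all <- NULL; safety_g34 <- NULL
  if (!is.null(dataset$ae)) {
    safety_all <- teae_table(dataset$ae, arm_sizes, min_incidence_pct = 10)
    safety_g34 <- teae_table(dataset$ae, arm_sizes, min_incidence_pct = 5,
                             grade_filter = c(3, 4))
  }
  qt <- if (!is.null(dataset$ecg) && nrow(dataset$ecg))
    qtcf_change_categories(dataset$ecg) else NULL

  structure(
    list(demographics = demographics_table(dataset),
         km_os = km_os, km_pfs = km_pfs, logrank = lr, bayes = bayes,
         response = resp, tumor_change = tumor, ca199 = ca,
         pk_summary = pk_summary, pk_attainment = pk_att,
         safety_all = safety_all, safety_g34 = safety_g34, qtcf = qt,
         meta = list(seed = dataset$seed, arm_sizes = arm_sizes,
                     a0 = a0, threshold = threshold)),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("=== Trial analysis report ===\n")
  cat(sprintf("Arms: experimental n = %d, control n = %d\n",
              x$meta$arm_sizes["experimental"], x$meta$arm_sizes["control"]))
  cat("\n-- Overall survival --\n")
  cat("  experimental median (range):", format_km_range(x$km_os$experimental), "\n")
  cat("  control      median (range):", format_km_range(x$km_os$control), "\n")
  if (x$logrank$estimable)
    cat(sprintf("  one-sided log-rank p = %.4f\n", x$logrank$p_one_sided))
  print(x$bayes$result)
  cat("\n-- Progression-free survival --\n")
  cat("  experimental median (range):", format_km_range(x$km_pfs$experimental), "\n")
  cat("  control      median (range):", format_km_range(x$km_pfs$control), "\n")
  cat("\n-- Response --\n")
  print(x$response)
  cat(sprintf("\n-- Tumor-size change (week 8): rank-sum p = %.4f (%s) --\n",
              x$tumor_change$p_value, x$tumor_change$method))
  if (!is.null(x$pk_summary)) {
    cat("\n-- Pharmacokinetics --\n")
    print(x$pk_summary)
  }
  if (!is.null(x$qtcf)) {
    cat("\n-- QTcF --\n")
    print(x$qtcf)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Renders the bundle as a directory of CSV tables plus a JSON decision
#' block (`bayes_decision.json`) and a plain-text summary (`report.txt`).
#' Regeneration from the same dataset is byte-identical.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(bundle$demographics$continuous, "demographics_continuous.csv")
  w(bundle$demographics$categorical, "demographics_categorical.csv")
  eff <- do.call(rbind, lapply(c("experimental", "control"), function(a) {
    r <- bundle$response[[a]]
    data.frame(arm = a, n = r$n,
               cr = r$counts[["CR"]], pr = r$counts[["PR"]],
               sd = r$counts[["SD"]], pd = r$counts[["PD"]],
               ne = r$counts[["NE"]],
               orr = format_binomial_endpoint(r$orr),
               cbr = format_binomial_endpoint(r$cbr),
               os_median_range = format_km_range(bundle$km_os[[a]]),
               pfs_median_range = format_km_range(bundle$km_pfs[[a]]))
  }))
  w(eff, "efficacy.csv")
  w(bundle$safety_all, "safety_all_grades.csv")
  w(bundle$safety_g34, "safety_grade34.csv")
  if (!is.null(bundle$pk_summary)) {
    w(bundle$pk_summary$parameters, "pk_parameters.csv")
    w(bundle$pk_attainment, "pk_target_attainment.csv")
  }
  if (!is.null(bundle$qtcf))
    w(as.data.frame(bundle$qtcf$counts), "qtcf_categories.csv")
  bayes <- bundle$bayes
  jsonlite::write_json(
    list(posterior_experimental = list(shape = bayes$posterior_e$shape,
                                       rate = bayes$posterior_e$rate),
         posterior_control = list(shape = bayes$posterior_c$shape,
                                  rate = bayes$posterior_c$rate),
         posterior_prob_superiority = bayes$prob,
         threshold = bayes$result$threshold,
         superior = bayes$result$decision,
         logrank_one_sided_p = bundle$logrank$p_one_sided,
         seed = bundle$meta$seed),
    file.path(dir, "bayes_decision.json"), auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(bundle))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
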