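# Secondary efficacy endpoints: exact binomial response rates, clinical
# benefit, duration of response, tumor-size change, CA19-9 response.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' `lower = qbeta(alpha/2; x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2; x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n denominator, `>= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' round(100 * clopper_pearson(14, 65), 1)  # 12.3 33.5
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n >= 1,
            x >= 0, x <= n, x == as.integer(x), n == as.integer(n),
            level > 0, level < 1)
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Binomial endpoint with exact interval
#'
#' @inheritParams clopper_pearson
#' @return object of class `binomial_endpoint`: `x`, `n`,
#'   `point_estimate`, `ci_low`, `ci_high`, `level`.
#' @export
binomial_endpoint <- function(x, n, level = 0.95) {
  ci <- clopper_pearson(x, n, level)
  structure(list(x = x, n = n, point_estimate = x / n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 level = level),
            class = "binomial_endpoint")
}

#' Render a binomial endpoint as a clinical-table cell
#'
#' Produces `"x (p%; lo-hi)"` with percentages rounded half-up to one
#' decimal, e.g. `"14 (21.5%; 12.3-33.5)"`.
#'
#' @param be a [binomial_endpoint()].
#' @return character scalar.
#' @export
format_binomial_endpoint <- function(be) {
  stopifnot(inherits(be, "binomial_endpoint"))
  sprintf("%d (%s%%; %s-%s)", be$x, fmt_pct1(be$point_estimate),
          fmt_pct1(be$ci_low), fmt_pct1(be$ci_high))
}

#' @export
print.binomial_endpoint <- function(x, ...) {
  cat(format_binomial_endpoint(x), sprintf("[%g%% CI]\n", 100 * x$level))
  invisible(x)
}

#' Best-response and clinical-benefit summary by arm
#'
#' Tallies RECIST best-response categories per arm and builds exact
#' binomial endpoints for the overall response rate (ORR = CR + PR) and the
#' clinical benefit rate (CBR = CR + PR + SD, no minimum SD duration),
#' plus a duration-of-response Kaplan-Meier summary among responders.
#'
#' @param patients data frame with `arm`, `best_response` and (for the
#'   duration summary) `dor_time`, `dor_event`.
#' @param level confidence level for the intervals.
#' @return object of class `response_summary`: per arm a list with
#'   `counts`, `n`, `orr`, `cbr` ([binomial_endpoint()]s) and `dor`
#'   (see [duration_of_response()]).
#' @export
response_summary <- function(patients, level = 0.95) {
  stopifnot(all(c("arm", "best_response") %in% names(patients)))
  cats <- c("CR", "PR", "SD", "PD", "NE")
  labs <- as.character(patients$best_response)
  bad <- setdiff(unique(labs), cats)
  if (length(bad))
    stop("unknown best_response category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  per_arm <- lapply(c(experimental = "experimental", control = "control"),
                    function(a) {
    sub <- patients[patients$arm == a, , drop = FALSE]
    counts <- table(factor(as.character(sub$best_response), levels = cats))
    n <- nrow(sub)
    dor <- if (all(c("dor_time", "dor_event") %in% names(sub)))
      duration_of_response(sub) else NULL
    list(n = n, counts = counts,
         orr = binomial_endpoint(sum(counts[c("CR", "PR")]), n, level),
         cbr = binomial_endpoint(sum(counts[c("CR", "PR", "SD")]), n, level),
         dor = dor)
  })
  structure(per_arm, class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  for (a in names(x)) {
    cat(sprintf("%s arm (n = %d):\n", a, x[[a]]$n))
    cnt <- x[[a]]$counts
    cat("  best response:",
        paste(sprintf("%s %d", names(cnt), cnt), collapse = ", "), "\n")
    cat("  ORR:", format_binomial_endpoint(x[[a]]$orr), "\n")
    cat("  CBR:", format_binomial_endpoint(x[[a]]$cbr), "\n")
    if (!is.null(x[[a]]$dor) && x[[a]]$dor$estimable)
      cat("  duration of response:", format_km_range(x[[a]]$dor$km), "\n")
  }
  invisible(x)
}

#' Duration of response among responders
#'
#' Kaplan-Meier summary of response duration (response onset to
#' progression/death, censored at last assessment) restricted to patients
#' with best response CR or PR.
#'
#' @param patients data frame with `best_response`, `dor_time`, `dor_event`.
#' @return list: `estimable` (FALSE with `n_responders = 0` when no
#'   responders), `n_responders`, `km` (a `km_curve`), `median`, and the raw
#'   range with censoring flag.
#' @export
duration_of_response <- function(patients) {
  stopifnot(all(c("best_response", "dor_time", "dor_event") %in%
                names(patients)))
  resp <- patients[as.character(patients$best_response) %in% c("CR", "PR") &
                   !is.na(patients$dor_time), , drop = FALSE]
  if (nrow(resp) == 0)
    return(list(estimable = FALSE, n_responders = 0L, km = NULL,
                median = NA_real_))
  km <- km_estimate(resp$dor_time, resp$dor_event)
  list(estimable = TRUE, n_responders = nrow(resp), km = km,
       median = km$median, range_min = km$range_min,
       range_max = km$range_max,
       range_max_censored = km$range_max_censored)
}

#' Wilcoxon rank-sum test of tumor-size change between arms
#'
#' Two-sided rank-sum comparison of percent change in target-lesion sums.
#' For combined sample sizes up to 20 the permutation distribution of the
#' rank sum is enumerated exhaustively (ties handled by mid-ranks, the
#' two-sided p-value defined by distance of the rank sum from its null
#' mean); larger samples use the normal approximation with tie-corrected
#' variance and no continuity correction.
#'
#' @param deltas_e,deltas_c percent changes from baseline, one per patient;
#'   each arm needs at least 2 values.
#' @param method `"auto"` (exact when the combined n is at most 20),
#'   `"exact"`, or `"normal"`.
#' @return list: `p_value`, `method` (`"exact"` or `"normal"`), `rank_sum`
#'   (experimental arm), `n_e`, `n_c`.
#' @examples
#' tumor_change_test(c(-30, -20, -10), c(5, 10, 15))$p_value  # 0.1 exact
#' @export
tumor_change_test <- function(deltas_e, deltas_c,
                              method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  deltas_e <- deltas_e[!is.na(deltas_e)]
  deltas_c <- deltas_c[!is.na(deltas_c)]
  stopifnot(length(deltas_e) >= 2, length(deltas_c) >= 2)
  n1 <- length(deltas_e); n2 <- length(deltas_c); N <- n1 + n2
  pooled <- c(deltas_e, deltas_c)
  if (length(unique(pooled)) == 1)
    return(list(p_value = 1, method = "degenerate",
                rank_sum = n1 * (N + 1) / 2, n_e = n1, n_c = n2))
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  use_exact <- switch(method, auto = N <= 20, exact = TRUE, normal = FALSE)
  if (use_exact && N > 22)
    stop("exact enumeration limited to combined n <= 22", call. = FALSE)
  if (use_exact) {
    splits <- utils::combn(N, n1)
    ws <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    list(p_value = p, method = "exact", rank_sum = w, n_e = n1, n_c = n2)
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - mu) / sqrt(sig2)
    list(p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal",
         rank_sum = w, n_e = n1, n_c = n2)
  }
}

#' CA19-9 biomarker response for one patient
#'
#' A patient is evaluable when the baseline level exceeds the upper limit
#' of normal; a responder when the on-treatment nadir falls strictly below
#' half the baseline (a > 50% reduction).
#'
#' @param baseline baseline CA19-9, U/mL (> 0).
#' @param series on-treatment values by cycle, U/mL (non-empty,
#'   non-negative).
#' @param uln upper limit of normal, U/mL (default 37).
#' @return list `evaluable`, `responder` (`NA` when not evaluable).
#' @examples
#' ca199_response(100, c(80, 49, 60), uln = 37)
#' @export
ca199_response <- function(baseline, series, uln = 37) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline CA19-9 must be positive", call. = FALSE)
  if (!length(series) || any(!is.finite(series)) || any(series < 0))
    stop("CA19-9 series must be non-empty and non-negative", call. = FALSE)
  evaluable <- baseline > uln
  list(evaluable = evaluable,
       responder = if (evaluable) min(series) < 0.5 * baseline else NA)
}

#' CA19-9 response proportions by arm for a trial dataset
#'
#' Applies [ca199_response()] to every patient with a CA19-9 series and
#' reports, per arm, the number evaluable and the responder fraction among
#' evaluable patients.
#'
#' @param dataset a `trial_dataset`.
#' @return data frame `arm, n_evaluable, n_responders, responder_frac`.
#' @export
ca199_summary <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  pts <- dataset$patients
  res <- lapply(pts$patient_id, function(id) {
    ser <- dataset$ca199$ca199_u_ml[dataset$ca199$patient_id == id]
    if (!length(ser)) return(NULL)
    i <- match(id, pts$patient_id)
    r <- ca199_response(pts$ca199_baseline_u_ml[i], ser,
                        pts$uln_ca199_u_ml[i])
    data.frame(arm = as.character(pts$arm[i]), evaluable = r$evaluable,
               responder = isTRUE(r$responder))
  })
  res <- do.call(rbind, res)
  out <- do.call(rbind, lapply(split(res, res$arm), function(d) {
    ev <- d[d$evaluable, , drop = FALSE]
    data.frame(arm = d$arm[1], n_evaluable = nrow(ev),
               n_responders = sum(ev$responder),
               responder_frac = if (nrow(ev)) mean(ev$responder) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
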