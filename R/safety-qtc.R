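# Safety tabulation (CTCAE-style incidence tables) and Fridericia-corrected
# QT change categorization.

#' Treatment-emergent adverse-event incidence table
#'
#' Patient-level incidence (a patient counts once per preferred term no
#' matter how many records), per arm, with percentages of the safety
#' population.  A term is retained when its incidence reaches
#' `min_incidence_pct` in at least one arm.  Restricting to
#' `grade_filter = c(3, 4)` with `min_incidence_pct = 5` reproduces the
#' usual grade-3/4 table shape.  Rows are ordered by descending pooled
#' incidence.  Term matching is case-insensitive.
#'
#' @param records AE data frame: `patient_id, arm, term, grade` (extra
#'   columns ignored).
#' @param arm_sizes named vector `c(experimental = , control = )` -- the
#'   safety-population denominators.
#' @param min_incidence_pct retention threshold, percent (default 10).
#' @param grade_filter optional integer vector of grades to keep.
#' @return data frame `term, n_experimental, pct_experimental, n_control,
#'   pct_control` sorted by pooled incidence.
#' @export
teae_table <- function(records, arm_sizes, min_incidence_pct = 10,
                       grade_filter = NULL) {
  stopifnot(all(c("patient_id", "arm", "term", "grade") %in% names(records)),
            all(c("experimental", "control") %in% names(arm_sizes)),
            all(arm_sizes >= 1))
  bad <- setdiff(unique(as.character(records$arm)), names(arm_sizes))
  if (length(bad))
    stop("records reference unknown arm(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(grade_filter))
    records <- records[records$grade %in% grade_filter, , drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(term = character(), n_experimental = integer(),
                      pct_experimental = numeric(), n_control = integer(),
                      pct_control = numeric()))
  records$term <- tolower(as.character(records$term))
  # one row per patient-term-arm
  uu <- unique(records[c("patient_id", "arm", "term")])
  count <- function(a) {
    tab <- table(uu$term[uu$arm == a])
    tab
  }
  te <- count("experimental"); tc <- count("control")
  terms <- sort(unique(uu$term))
  n_e <- as.integer(te[terms]); n_e[is.na(n_e)] <- 0L
  n_c <- as.integer(tc[terms]); n_c[is.na(n_c)] <- 0L
  pct_e <- 100 * n_e / arm_sizes[["experimental"]]
  pct_c <- 100 * n_c / arm_sizes[["control"]]
  keep <- pct_e >= min_incidence_pct | pct_c >= min_incidence_pct
  out <- data.frame(term = terms, n_experimental = n_e,
                    pct_experimental = pct_e, n_control = n_c,
                    pct_control = pct_c)[keep, , drop = FALSE]
  pooled <- (out$n_experimental + out$n_control) / sum(arm_sizes)
  out <- out[order(-pooled, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fridericia-corrected QT interval
#'
#' `QTcF = QT / RR^(1/3)` with QT in milliseconds and RR in seconds; at
#' RR = 1 s (60 bpm) the correction is the identity.
#'
#' @param qt_ms QT interval, ms (> 0).
#' @param rr_s RR interval, seconds (> 0).
#' @return QTcF in ms.
#' @examples
#' qtcf(400, 0.64)
#' @export
qtcf <- function(qt_ms, rr_s) {
  if (any(!is.finite(rr_s)) || any(rr_s <= 0))
    stop("RR interval must be positive", call. = FALSE)
  stopifnot(all(qt_ms > 0))
  qt_ms / rr_s^(1/3)
}

#' QTcF change-from-baseline categories per patient
#'
#' Each patient's maximum post-baseline QTcF change is classified into the
#' partition `<= 30`, `(30, 60]`, `> 60` ms (half-open edges, so exactly
#' 60 ms falls in the middle category).  Patients without a baseline or
#' without any post-baseline ECG are excluded and counted.
#'
#' @param ecg data frame `patient_id, timepoint, qt_ms, rr_s`; the baseline
#'   rows are those with `timepoint == baseline_label`.
#' @param baseline_label timepoint label marking baseline (default
#'   `"baseline"`).
#' @return object of class `qtcf_categories`: data frame `per_patient`
#'   (`patient_id, max_delta_ms, category`), `counts` (table over the three
#'   categories), `n_excluded`.
#' @export
qtcf_change_categories <- function(ecg, baseline_label = "baseline") {
  stopifnot(all(c("patient_id", "timepoint", "qt_ms", "rr_s") %in% names(ecg)))
  ecg$qtcf <- qtcf(ecg$qt_ms, ecg$rr_s)
  levs <- c("<=30", "(30,60]", ">60")
  rows <- list()
  excluded <- 0L
  for (id in unique(ecg$patient_id)) {
    sub <- ecg[ecg$patient_id == id, ]
    base <- sub$qtcf[sub$timepoint == baseline_label]
    post <- sub$qtcf[sub$timepoint != baseline_label]
    if (length(base) != 1 || !length(post)) {
      excluded <- excluded + 1L
      next
    }
    dmax <- max(post - base)
    cat_i <- if (dmax <= 30) levs[1] else if (dmax <= 60) levs[2] else levs[3]
    rows[[length(rows) + 1]] <- data.frame(patient_id = id,
                                           max_delta_ms = dmax,
                                           category = cat_i)
  }
  per_patient <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = integer(), max_delta_ms = numeric(),
               category = character())
  per_patient$category <- factor(per_patient$category, levels = levs)
  structure(list(per_patient = per_patient,
                 counts = table(per_patient$category),
                 n_excluded = excluded),
            class = "qtcf_categories")
}

#' @export
print.qtcf_categories <- function(x, ...) {
  cat("QTcF maximum change from baseline:\n")
  for (l in names(x$counts))
    cat(sprintf("  %-8s %d patients\n", paste0(l, " ms"), x$counts[[l]]))
  if (x$n_excluded)
    cat(sprintf("  (%d patient(s) excluded: no baseline or no post-baseline ECG)\n",
                x$n_excluded))
  invisible(x)
}
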