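# Independent oracles: deliberately naive implementations used only to
# check the package's results, never sharing code with them.

# product-limit estimator by direct risk-set arithmetic
hand_km <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & status == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv,
       median = if (any(surv <= 0.5 + 1e-12))
         ut[which(surv <= 0.5 + 1e-12)[1]] else NA_real_)
}

hand_km_surv_at <- function(hk, t) {
  idx <- which(hk$time <= t)
  if (!length(idx)) 1 else hk$surv[max(idx)]
}

# log-rank O-E and hypergeometric variance by a direct loop over event times
# (group 1 = experimental)
hand_logrank <- function(time1, status1, time0, status0) {
  time <- c(time1, time0)
  status <- c(status1, status0)
  grp <- rep(c(1, 0), c(length(time1), length(time0)))
  ut <- sort(unique(time[status == 1]))
  u <- 0; v <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & grp == 1)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(u = u, v = v, z = u / sqrt(v))
}

# one-compartment constant-rate infusion concentration (closed form)
one_cmt_conc <- function(times, dose, tinf, cl, v) {
  k <- cl / v
  r0 <- dose / tinf
  css <- r0 / cl
  ifelse(times <= tinf,
         css * (1 - exp(-k * times)),
         css * (1 - exp(-k * tinf)) * exp(-k * (times - tinf)))
}

# slow macro-rate (terminal eigenvalue) of the two-compartment system
two_cmt_beta <- function(cl, vc, vp, q) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  s <- k10 + k12 + k21
  (s - sqrt(s^2 - 4 * k10 * k21)) / 2
}

# fixture: patients table with exact best-response counts per arm
response_fixture <- function(counts_e, counts_c) {
  mk <- function(counts, arm, offset) {
    labs <- rep(names(counts), counts)
    n <- length(labs)
    data.frame(patient_id = offset + seq_len(n), arm = arm,
               best_response = factor(labs,
                                      levels = c("CR", "PR", "SD", "PD", "NE")),
               dor_time = ifelse(labs %in% c("CR", "PR"), 3.5, NA),
               dor_event = ifelse(labs %in% c("CR", "PR"), 1L, NA))
  }
  rbind(mk(counts_e, "experimental", 0), mk(counts_c, "control", 1000))
}
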