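# Exact binomial endpoints, response summaries, duration of response,
# tumor-size change test, CA19-9 response.

test_that("Clopper-Pearson matches the independent binom.test oracle and boundary rules", {
  for (case in list(c(0, 20), c(1, 7), c(14, 65), c(3, 34), c(19, 34),
                    c(36, 65), c(22, 34), c(65, 65))) {
    ci <- clopper_pearson(case[1], case[2])
    oracle <- binom.test(case[1], case[2])$conf.int
    expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-12)
  }
  expect_identical(clopper_pearson(0, 20)[["lower"]], 0)
  expect_identical(clopper_pearson(20, 20)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4))
})

test_that("Clopper-Pearson coverage is at least nominal in simulation", {
  level <- 0.95
  for (case in list(c(65, 0.2), c(34, 0.1))) {
    n <- case[1]; p <- case[2]
    bounds <- t(vapply(0:n, function(x) clopper_pearson(x, n, level),
                       numeric(2)))
    set.seed(8)
    x <- rbinom(10000, n, p)
    covered <- bounds[x + 1, 1] <= p & p <= bounds[x + 1, 2]
    expect_gte(mean(covered), 0.95)
  }
})

test_that("interval width shrinks with n at a fixed proportion", {
  widths <- vapply(c(10, 50, 250, 1250), function(n) {
    ci <- clopper_pearson(round(0.2 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("response summary reproduces the reference table strings and tallies", {
  pts <- response_fixture(c(CR = 0, PR = 14, SD = 22, PD = 25, NE = 4),
                          c(CR = 0, PR = 3, SD = 19, PD = 10, NE = 2))
  rs <- response_summary(pts)
  expect_equal(rs$experimental$n, 65)
  expect_equal(format_binomial_endpoint(rs$experimental$orr),
               "14 (21.5%; 12.3-33.5)")
  expect_equal(format_binomial_endpoint(rs$experimental$cbr),
               "36 (55.4%; 42.5-67.7)")
  expect_equal(format_binomial_endpoint(rs$control$orr),
               "3 (8.8%; 1.9-23.7)")
  expect_equal(format_binomial_endpoint(rs$control$cbr),
               "22 (64.7%; 46.5-80.3)")
  # SD row intervals (best-overall-response table)
  expect_equal(round_half_up(100 * clopper_pearson(22, 65), 1),
               c(lower = 22.6, upper = 46.6))
  expect_equal(round_half_up(100 * clopper_pearson(19, 34), 1),
               c(lower = 37.9, upper = 72.8))

  # random multinomial fixture cross-checked by direct tally
  set.seed(9)
  labs <- sample(c("CR", "PR", "SD", "PD", "NE"), 200, replace = TRUE,
                 prob = c(0.02, 0.2, 0.35, 0.35, 0.08))
  pts2 <- data.frame(patient_id = 1:200,
                     arm = rep(c("experimental", "control"), 100),
                     best_response = labs)
  rs2 <- response_summary(pts2)
  for (a in c("experimental", "control")) {
    sub <- labs[pts2$arm == a]
    expect_equal(as.integer(rs2[[a]]$counts),
                 as.integer(table(factor(sub, c("CR", "PR", "SD", "PD", "NE")))))
    expect_equal(rs2[[a]]$orr$x, sum(sub %in% c("CR", "PR")))
    expect_equal(rs2[[a]]$cbr$x, sum(sub %in% c("CR", "PR", "SD")))
  }
  # unknown category rejected with the offending label
  pts_bad <- data.frame(arm = "control", best_response = "MR")
  expect_error(response_summary(pts_bad), "MR")
})

test_that("duration of response follows the product-limit conventions", {
  one <- data.frame(best_response = "PR", dor_time = 4, dor_event = 1)
  d <- duration_of_response(one)
  expect_true(d$estimable)
  expect_equal(d$median, 4)

  three <- data.frame(best_response = rep("PR", 3),
                      dor_time = c(3, 5, 7), dor_event = c(1, 0, 1))
  d3 <- duration_of_response(three)
  # S(3) = 2/3, S(7) = 0 -> median 7
  expect_equal(d3$median, 7)

  none <- data.frame(best_response = c("SD", "PD"),
                     dor_time = c(NA, NA), dor_event = c(NA, NA))
  d0 <- duration_of_response(none)
  expect_false(d0$estimable)
  expect_equal(d0$n_responders, 0L)
})

test_that("tumor-change rank-sum test: exact path, degenerate input, oracle agreement", {
  expect_equal(tumor_change_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  res <- tumor_change_test(c(-30, -20, -10), c(5, 10, 15))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)

  # exact path equals wilcox.test's exact two-sided p on tie-free samples
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(8, 0.5)
    mine <- tumor_change_test(x, y)
    oracle <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-10)
  }

  # normal approximation close to the exact path at combined n = 20
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  expect_lt(abs(tumor_change_test(x, y, method = "exact")$p_value -
                tumor_change_test(x, y, method = "normal")$p_value), 0.02)
})

test_that("CA19-9 response applies the eligibility and strict-reduction rules", {
  r <- ca199_response(100, c(80, 49, 60), uln = 37)
  expect_true(r$evaluable); expect_true(r$responder)
  r2 <- ca199_response(30, c(10, 5), uln = 37)
  expect_false(r2$evaluable); expect_true(is.na(r2$responder))
  r3 <- ca199_response(100, c(50, 70), uln = 37)  # nadir exactly half
  expect_false(r3$responder)
  expect_error(ca199_response(-1, c(1)), "positive")
  expect_error(ca199_response(100, numeric(0)))
})
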