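test_that("endpoint construction follows the calendar-day and censoring rules", {
  cohort <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    rt1_start = as.Date("2008-01-01") + c(0, 0, 0),
    rert_start = as.Date("2008-01-01") + c(642, 173, 300),
    death_date = as.Date("2008-01-01") + c(642 + 265, NA, NA),
    progression_date = as.Date("2008-01-01") + c(642 + 100, NA, NA),
    last_followup = as.Date("2008-01-01") + c(642 + 265, 173 + 100, 300 + 50)
  )
  ep <- compute_endpoints(cohort)
  expect_equal(ep$prs_days, c(265, 100, 50))
  expect_equal(ep$prs_event, c(1L, 0L, 0L))
  expect_equal(ep$pfs_days, c(100, 100, 50))
  expect_equal(ep$pfs_event, c(1L, 0L, 0L))
  expect_equal(ep$os_days, c(642 + 265, 273, 350))
  expect_equal(ep$interval_days, c(642, 173, 300))
  # 30 days/month convention on the printed pairs
  expect_equal(ep$interval_months, c(21.4, 5.8, 10.0))

  bad <- cohort
  bad$death_date[2] <- bad$rert_start[2] - 1
  expect_error(compute_endpoints(bad), "precedes re-irradiation")
})

test_that("Kaplan-Meier estimate matches hand product-limit values and median convention", {
  # all events: S = 3/4, 1/2, 1/4, 0; median = smallest t with S <= 0.5
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1)
  f <- km_estimate(d, "time", "event")
  expect_equal(tidy(f)$survival, c(0.75, 0.5, 0.25, 0), tolerance = 1e-9)
  expect_equal(glance(f)$median, 2)

  # censoring: times (1, 2+, 3) -> S(1) = 2/3, S(3) = 0; median 3
  d2 <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  f2 <- km_estimate(d2, "time", "event")
  s2 <- tidy(f2)
  expect_equal(s2$survival[s2$time == 1], 2 / 3, tolerance = 1e-9)
  expect_equal(s2$survival[s2$time == 3], 0, tolerance = 1e-9)
  expect_equal(glance(f2)$median, 3)

  # all censored: S stays 1, median not reached
  d3 <- tibble::tibble(time = c(5, 10), event = 0)
  f3 <- km_estimate(d3, "time", "event")
  expect_true(all(tidy(f3)$survival == 1))
  expect_true(is.na(glance(f3)$median))

  # no censoring: KM equals the empirical survival function
  set.seed(37)
  t <- sample(1:500, 60, replace = TRUE)
  f4 <- km_estimate(tibble::tibble(time = t, event = 1), "time", "event")
  s4 <- tidy(f4)
  emp <- vapply(s4$time, function(u) mean(t > u), numeric(1))
  expect_equal(s4$survival, emp, tolerance = 1e-12)

  expect_error(km_estimate(tibble::tibble(time = numeric(), event = integer()),
                           "time", "event"), "no survival records")
})

test_that("log-rank test matches the hand-computed statistic and its symmetries", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                      group = c("A", "A", "B", "B"))
  lr <- logrank(d, "time", "event", "group")
  expect_equal(lr$chisq, 2.882353, tolerance = 1e-6)
  expect_equal(lr$p, 1 - pchisq(2.882353, 1), tolerance = 1e-6)

  # identical groups: chi-square 0, p = 1
  d0 <- tibble::tibble(time = rep(c(3, 6, 9), 2), event = 1,
                       group = rep(c("A", "B"), each = 3))
  lr0 <- logrank(d0, "time", "event", "group")
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # label swap leaves the statistic unchanged
  d_sw <- dplyr::mutate(d, group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank(d_sw, "time", "event", "group")$chisq, lr$chisq)

  # invariant under strictly monotone time transformation
  d_tr <- dplyr::mutate(d, time = exp(time))
  expect_equal(logrank(d_tr, "time", "event", "group")$chisq, lr$chisq,
               tolerance = 1e-12)

  # zero events in both groups: statistic 0 path, no division error
  dz <- tibble::tibble(time = c(1, 2, 3, 4), event = 0,
                       group = c("A", "A", "B", "B"))
  expect_equal(logrank(dz, "time", "event", "group")$p, 1)
})

test_that("univariate Cox reports HR with Wald CI and agrees with the log-rank direction", {
  d <- tibble::tibble(time = c(1, 3, 2, 4), event = 1,
                      group = c("A", "A", "B", "B"))
  fit <- cox_univariate(d, "time", "event", "group")
  td <- tidy(fit)
  expect_true(all(c("hr", "conf_low", "conf_high", "p_value") %in% names(td)))
  # group A tends to die earlier, so B has lower hazard: HR(B vs A) < 1
  expect_lt(td$hr, 1)
  # score test equals the log-rank chi-square for an untied two-level covariate
  sc <- summary(fit$coxph)$sctest[["test"]]
  lr <- logrank(d, "time", "event", "group")
  expect_equal(sc, lr$chisq, tolerance = 1e-9)

  expect_error(cox_univariate(dplyr::mutate(d, group = "A"),
                              "time", "event", "group"), "constant")
  # fully separated groups: monotone partial likelihood, explicit error
  sep <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                        group = c("A", "A", "B", "B"))
  expect_error(suppressWarnings(cox_univariate(sep, "time", "event", "group")),
               "converge")
})

test_that("null-covariate Cox CIs cover 1 at the nominal rate", {
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    d <- tibble::tibble(time = rexp(200), event = 1,
                        covariate = rnorm(200))
    td <- tidy(cox_univariate(d, "time", "event", "covariate"))
    td$conf_low <= 1 && 1 <= td$conf_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("Cox recovers a true hazard ratio of 2 between performance-status groups", {
  est <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    poor <- rbinom(n, 1, 0.3)
    t_event <- rexp(n, rate = 0.01 * ifelse(poor == 1, 2, 1))
    t_cens <- rexp(n, rate = 0.01 * 0.25 * ifelse(poor == 1, 2, 1))  # ~20% censored
    d <- tibble::tibble(time = pmin(t_event, t_cens),
                        event = as.integer(t_event <= t_cens),
                        covariate = poor)
    tidy(cox_univariate(d, "time", "event", "covariate"))$hr
  }, numeric(1))
  expect_gte(median(est), 1.8)
  expect_lte(median(est), 2.2)
})

test_that("two-sample and contingency tests give two-sided p-values with degenerate cases handled", {
  # exact hypergeometric enumeration for the diagonal 2x2 table gives 1/3
  ft <- two_sample_tests(table = matrix(c(2, 0, 0, 2), 2),
                         method = "fisher_exact")
  expect_equal(ft$p, 1 / 3, tolerance = 1e-12)

  x <- c(1, 2, 3, 4, 5)
  mw <- two_sample_tests(x, x, method = "mann_whitney")
  expect_gt(mw$p, 0.99)

  wp <- two_sample_tests(x, x, method = "wilcoxon_paired")
  expect_equal(wp$statistic, 0)
  expect_equal(wp$p, 1)

  expect_error(two_sample_tests(numeric(), x, method = "mann_whitney"),
               "non-empty")
  expect_error(two_sample_tests(x, x[-1], method = "wilcoxon_paired"),
               "equal length")
  expect_error(two_sample_tests(table = matrix(1:6, 2),
                                method = "fisher_exact"), "2x2")
})

test_that("univariate table reports every covariate-endpoint pair and flags inestimable ones", {
  coh <- generate_cohort(cohort_config(n_patients = 40, rng_seed = 2),
                         dvhs = FALSE)
  patients <- dplyr::mutate(coh$patients, always = 1)
  ep <- compute_endpoints(patients)
  tab <- univariate_table(patients, ep,
                          covariates = c("kps_ge70", "age", "always"),
                          endpoint_names = c("prs", "os"))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$note[tab$variable == "always"] == "not estimable"))
  est <- tab[tab$variable != "always", ]
  expect_true(all(is.finite(est$hr)))
  expect_true(all(est$conf_low <= est$hr & est$hr <= est$conf_high))
})
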