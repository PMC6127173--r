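test_that("sacrifice rule records grid-time events and end-of-study censoring", {
  v <- c(rep(0.5, 41), 1.9, 2.05, 2.5)  # crosses 2 between day 41 and 42
  traj <- data.frame(mouse_id = 1, arm = "control", day = 0:43,
                     volume_cm3 = v)
  rec <- derive_survival(traj)
  expect_equal(rec$time_days, 42)
  expect_equal(rec$status, "event")

  traj2 <- data.frame(mouse_id = 1, arm = "control", day = 0:84,
                      volume_cm3 = seq(0.1, 1.9, length.out = 85))
  rec2 <- derive_survival(traj2)
  expect_equal(rec2$time_days, 84)
  expect_equal(rec2$status, "censored")

  traj3 <- data.frame(mouse_id = 1, arm = "control", day = 0:5,
                      volume_cm3 = rep(2.5, 6))
  expect_equal(derive_survival(traj3)$time_days, 0)  # degenerate: first grid time
  expect_error(derive_survival(traj3[0, ]), class = "angiotrial_domain_error")
})

test_that("product-limit estimate matches hand computation and survfit", {
  rec <- surv_records(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  km <- km_estimate(rec)
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0), tolerance = 1e-12)

  allc <- surv_records(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(km_estimate(allc)), 0)  # S stays at 1 throughout

  tied <- surv_records(rep(5, 4), rep(TRUE, 4))
  kmt <- km_estimate(tied)
  expect_equal(kmt$survival, 0)

  cohort <- gen_survival_cohort(60, c(1, 2), censor_time = 2, seed = 13)
  g1 <- cohort[cohort$group == "g1", ]
  km1 <- km_estimate(g1)
  br <- km_brute(g1$time_days, g1$status == "event")
  expect_equal(km1$survival, br$survival, tolerance = 1e-12)
  sf <- survival::survfit(
    survival::Surv(time_days, status == "event") ~ 1, data = g1)
  expect_equal(km1$survival, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  # no censoring: KM equals the empirical survival function
  nc <- surv_records(c(3, 1, 4, 1, 5), rep(TRUE, 5))
  kmn <- km_estimate(nc)
  emp <- vapply(kmn$time, function(t) mean(nc$time_days > t), 0)
  expect_equal(kmn$survival, emp, tolerance = 1e-12)
})

test_that("median survival follows the midpoint convention", {
  mk <- function(time, survival)
    structure(data.frame(time = time, n_risk = NA, n_event = NA,
                         survival = survival),
              class = c("km_curve", "data.frame"))
  expect_equal(median_survival(mk(c(40, 53, 60), c(0.8, 0.45, 0.2))), 53)
  expect_equal(median_survival(mk(c(44, 45, 50), c(0.5, 0.3, 0.1))), 44.5)
  expect_true(is.na(median_survival(mk(c(40, 90), c(0.8, 0.6)))))
  expect_true(is.na(median_survival(km_estimate(
    surv_records(c(2, 4), c(FALSE, FALSE))))))
})

test_that("log-rank matches brute-force accumulation and survdiff", {
  a <- surv_records(c(2, 5, 6, 9), c(TRUE, FALSE, TRUE, TRUE), group = "a")
  b <- surv_records(c(3, 7, 7, 11), c(TRUE, TRUE, FALSE, TRUE), group = "b")
  lr <- logrank_test(a, b)
  br <- logrank_brute(a$time_days, a$status == "event",
                      b$time_days, b$status == "event")
  expect_equal(lr$statistic, br$statistic, tolerance = 1e-12)
  expect_equal(lr$p_value, br$p_value, tolerance = 1e-12)
  sd <- survival::survdiff(
    survival::Surv(time_days, status == "event") ~ group, data = rbind(a, b))
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)

  # identical groups: zero statistic, p = 1
  same <- logrank_test(a, a)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  # zero events overall
  cens <- surv_records(c(2, 3), c(FALSE, FALSE))
  expect_identical(logrank_test(cens, cens)$p_value, 1)
  expect_error(logrank_test(a[0, ], b), class = "angiotrial_domain_error")
})

test_that("log-rank has power against a five-fold hazard difference", {
  for (s in 1:5) {
    cohort <- gen_survival_cohort(200, c(1, 5), censor_time = 3, seed = s)
    lr <- logrank_test(cohort[cohort$group == "g1", ],
                       cohort[cohort$group == "g2", ])
    expect_lt(lr$p_value, 1e-6)
  }
})

test_that("MH hazard ratio matches a brute-force stratified computation", {
  a <- surv_records(c(2, 4, 7, 9, 12, 15),
                    c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), group = "a")
  b <- surv_records(c(1, 3, 3, 6, 10, 14),
                    c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), group = "b")
  mh <- hazard_ratio_mh(a, b)
  expect_equal(mh$hr, mh_brute(a$time_days, a$status == "event",
                               b$time_days, b$status == "event"),
               tolerance = 1e-12)
  expect_true(mh$ci_lower <= mh$hr && mh$hr <= mh$ci_upper)
  expect_gt(mh$hr, 0)

  # identical groups: HR exactly 1; relabelling inverts exactly
  expect_equal(hazard_ratio_mh(a, a)$hr, 1, tolerance = 1e-12)
  expect_equal(hazard_ratio_mh(a, b)$hr * hazard_ratio_mh(b, a)$hr, 1,
               tolerance = 1e-12)

  # no events in one group: flagged undefined
  cens <- surv_records(c(5, 6), c(FALSE, FALSE))
  expect_true(hazard_ratio_mh(cens, b)$undefined)
})

test_that("MH estimate recovers known hazard ratios and tracks Cox", {
  for (h in c(0.25, 0.5, 1, 2)) {
    cohort <- gen_survival_cohort(500, c(h, 1), censor_time = 5,
                                  seed = round(100 * h))
    a <- cohort[cohort$group == "g1", ]; b <- cohort[cohort$group == "g2", ]
    mh <- hazard_ratio_mh(a, b)
    expect_equal(mh$hr, h, tolerance = 0.1)
    d <- rbind(a, b)
    cox <- survival::coxph(
      survival::Surv(time_days, status == "event") ~ I(group == "g1"),
      data = d)
    expect_equal(log(mh$hr), unname(stats::coef(cox)), tolerance = 0.05)
  }
  # 95% CI coverage over 20 replicates at true HR 0.5
  cover <- 0
  for (s in 1:20) {
    cohort <- gen_survival_cohort(300, c(1, 2), censor_time = 3, seed = s)
    mh <- hazard_ratio_mh(cohort[cohort$group == "g1", ],
                          cohort[cohort$group == "g2", ])
    if (mh$ci_lower <= 0.5 && 0.5 <= mh$ci_upper) cover <- cover + 1
  }
  expect_gte(cover, 17)
})
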