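test_that("growth datasets honour the noise model and the seed", {
  truth <- growth_params(8e-6, 5e-7, ang0 = fix_ang0())
  d0 <- gen_growth_dataset(truth, sigma = 0, seed = 1, model = fix_ode())
  expect_equal(d0$volume_cm3, attr(d0, "noiseless")$volume_cm3,
               tolerance = 1e-12)
  d1 <- gen_growth_dataset(truth, sigma = 0.1, seed = 5, model = fix_ode())
  d2 <- gen_growth_dataset(truth, sigma = 0.1, seed = 5, model = fix_ode())
  expect_identical(d1$volume_cm3, d2$volume_cm3)
  expect_false(identical(
    d1$volume_cm3,
    gen_growth_dataset(truth, sigma = 0.1, seed = 6,
                       model = fix_ode())$volume_cm3))

  # 1000 replicates at one day: sample SD of log volume within 10% of sigma
  dr <- gen_growth_dataset(truth, days = c(10, 12), sigma = 0.1, seed = 2,
                           model = fix_ode(), n_rep = 500)
  lv <- log(dr$volume_cm3[dr$day == 10])
  expect_equal(sd(lv), 0.1, tolerance = 0.1)

  out_of_bounds <- growth_params(5e-2, 5e-7, ang0 = fix_ang0())
  expect_warning(gen_growth_dataset(out_of_bounds, sigma = 0, seed = 1,
                                    model = fix_ode()),
                 "bounds")
})

test_that("generated case ranges straddle the target ratio interval", {
  rng <- gen_case_ranges(6, seed = 1)
  expect_length(rng, 6)
  for (r in rng) {
    span <- c(r$k0_range[1] / r$k1_range[2], r$k0_range[2] / r$k1_range[1])
    expect_lte(span[1], 9.757)
    expect_gte(span[2], 17.982)
  }
  expect_identical(gen_case_ranges(3, seed = 2)[[2]]$k0_range,
                   gen_case_ranges(3, seed = 2)[[2]]$k0_range)
  # degenerate spans give degenerate (but valid) ranges
  deg <- gen_case_ranges(1, seed = 1, k1_low_span = c(3e-7, 3e-7),
                         k1_high_span = c(6e-7, 6e-7))
  expect_equal(deg[[1]]$k1_range, c(3e-7, 6e-7))
})

test_that("survival cohorts encode the requested hazards and censoring", {
  rec <- gen_survival_cohort(200, c(1, 2), censor_time = 3, seed = 3)
  expect_equal(nrow(rec), 400)
  g1 <- rec[rec$group == "g1", ]; g2 <- rec[rec$group == "g2", ]
  # mean uncensored exponential lifetimes reflect the 2:1 hazard ratio
  expect_gt(mean(g1$time_days), mean(g2$time_days))
  expect_true(all(rec$time_days <= 3))
  all_cens <- gen_survival_cohort(50, c(1, 2), censor_time = 0, seed = 1)
  expect_true(all(all_cens$status == "censored"))
  expect_identical(gen_survival_cohort(50, c(1, 2), seed = 9),
                   gen_survival_cohort(50, c(1, 2), seed = 9))
  expect_error(gen_survival_cohort(10, c(0, 1)),
               class = "angiotrial_domain_error")
})

test_that("planted-threshold populations are reproducible and guarded", {
  p1 <- gen_planted_threshold_population(n = 100, seed = 4)
  p2 <- gen_planted_threshold_population(n = 100, seed = 4)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "r_star"), 13.87)
  expect_error(gen_planted_threshold_population(n = 10, r_star = 1e6),
               class = "angiotrial_domain_error")
  # zero effect: hazards equal above and below the plant
  p0 <- gen_planted_threshold_population(n = 100, hazard_low = 0.05,
                                         hazard_high = 0.05, seed = 1)
  expect_s3_class(p0, "data.frame")
})
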