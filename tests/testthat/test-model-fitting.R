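test_that("ssr is exact, symmetric under pairing permutations", {
  expect_identical(ssr(c(1, 2), c(1, 2)), 0)
  expect_identical(ssr(c(1, 2), c(0, 0)), 5)
  o <- runif(6); s <- runif(6)
  perm <- sample(6)
  expect_equal(ssr(o, s), ssr(o[perm], s[perm]), tolerance = 1e-15)
  expect_error(ssr(1:3, 1:4), class = "angiotrial_domain_error")
})

test_that("fit configuration validates bounds", {
  cfg <- fit_config()
  expect_equal(unname(cfg$lower), c(1e-8, 1e-8, 1e-16))
  expect_equal(unname(cfg$upper), c(1e-2, 1e-2, 1e-14))
  expect_error(fit_config(lower = c(k0 = 1e-2, k1 = 1e-8, ang0 = 1e-16)),
               class = "angiotrial_domain_error")
  expect_error(fit_config(lower = c(k0 = 1e-8)),
               class = "angiotrial_domain_error")
})

test_that("noise-free synthetic data are recovered to high precision", {
  truth <- growth_params(8e-6, 5e-7, ang0 = fix_ang0())
  d <- gen_growth_dataset(truth, sigma = 0, seed = 1, model = fix_ode())
  cfg <- fit_config(n_starts = 14, n_refine = 3)
  fits <- suppressWarnings(
    fit_control(d, cfg, model = fix_ode(), seed = 2))
  best <- fits[1, ]
  expect_lt(best$ssr, 1e-8 * sum(d$volume_cm3^2))
  expect_equal(best$k0 / best$k1, truth$k0 / truth$k1, tolerance = 0.05)
  # bounds respected for every returned fit
  expect_true(all(fits$k0 >= 1e-8 & fits$k0 <= 1e-2))
  expect_true(all(fits$k1 >= 1e-8 & fits$k1 <= 1e-2))
  expect_true(all(fits$ang0 >= 1e-16 & fits$ang0 <= 1e-14))

  # reported SSR is consistent with an independent resimulation
  gbest <- growth_params(best$k0, best$k1, 20, best$ang0)
  traj <- simulate_trajectory(fix_ode(), gbest, horizon = max(d$day),
                              state0 = fix_state(),
                              out_times = sort(unique(c(0, d$day))))
  sim <- traj$volume[match(d$day, traj$time)]
  expect_equal(best$ssr, ssr(d$volume_cm3, sim), tolerance = 1e-10)

  # determinism under the seed
  fits2 <- suppressWarnings(
    fit_control(d, cfg, model = fix_ode(), seed = 2))
  expect_identical(as.data.frame(fits), as.data.frame(fits2))
})

test_that("degenerate fitting inputs are rejected", {
  d0 <- data.frame(day = c(3, 7, 12), volume_cm3 = c(0, 0, 0))
  expect_error(fit_control(d0, model = fix_ode()),
               class = "angiotrial_domain_error")
  expect_error(fit_control(d0[1:2, ], model = fix_ode()),
               class = "angiotrial_domain_error")
})

test_that("validation ranks by combined control+treatment error", {
  truth <- growth_params(8e-6, 5e-7, ang0 = fix_ang0())
  ctrl <- gen_growth_dataset(truth, sigma = 0, seed = 1, model = fix_ode())
  proto <- make_protocol("A")
  trt_traj <- simulate_trajectory(fix_ode(), truth, protocol = proto,
                                  state0 = fix_state(),
                                  horizon = max(ctrl$day))
  trt <- data.frame(day = ctrl$day[ctrl$day %in% trt_traj$time],
                    volume_cm3 = trt_traj$volume[
                      match(ctrl$day[ctrl$day %in% trt_traj$time],
                            trt_traj$time)])
  cfg <- fit_config(n_starts = 10, n_refine = 3)
  fits <- suppressWarnings(fit_control(ctrl, cfg, model = fix_ode(),
                                       seed = 3))
  sel <- validate_and_select(fits, ctrl, trt, proto, k = 2,
                             model = fix_ode())
  expect_equal(nrow(sel), 2)
  expect_true(all(diff(sel$ssr_combined) >= 0))
  expect_warning(validate_and_select(fits, ctrl, trt, proto, k = 50,
                                     model = fix_ode()),
                 "returning all")
  rng <- fit_ranges(sel)
  expect_s3_class(rng, "case_ranges")
  expect_true(rng$k0_range[1] <= rng$k0_range[2])
})
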