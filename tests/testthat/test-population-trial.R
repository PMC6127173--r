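test_that("population sampling is uniform, independent and reproducible", {
  r <- case_ranges("c", c(5e-6, 1.5e-5), c(3e-7, 7e-7), ang0 = 5e-15)
  pop <- sample_population(r, 400, seed = 7)
  expect_equal(nrow(pop), 400)
  expect_true(all(pop$k0 >= 5e-6 & pop$k0 <= 1.5e-5))
  expect_true(all(pop$k1 >= 3e-7 & pop$k1 <= 7e-7))
  expect_true(all(pop$ang0 == 5e-15))
  pop2 <- sample_population(r, 400, seed = 7)
  expect_identical(pop, pop2)
  expect_false(identical(pop, sample_population(r, 400, seed = 8)))
  # k0 and k1 sampled independently: negligible correlation at n = 400
  expect_lt(abs(cor(pop$k0, pop$k1)), 0.15)

  deg <- case_ranges("d", c(1e-5, 1e-5), c(5e-7, 5e-7), ang0 = 5e-15)
  dp <- sample_population(deg, 10, seed = 1)
  expect_true(all(dp$k0 == 1e-5) && all(dp$k1 == 5e-7))
  expect_error(sample_population(r, 0, seed = 1),
               class = "angiotrial_domain_error")
})

test_that("exclusion filter keeps fast growers and drops slow ones", {
  traj <- rbind(
    data.frame(mouse_id = 1, day = 0:12,
               volume_cm3 = 0.004 * exp(0.55 * (0:12))),  # crosses ~day 6
    data.frame(mouse_id = 2, day = 0:12,
               volume_cm3 = seq(0.004, 0.1, length.out = 13)))  # V(10)=0.084
  out <- exclusion_filter(traj)
  expect_true(out$retained[out$mouse_id == 1])
  expect_false(out$retained[out$mouse_id == 2])
  expect_match(out$reason[out$mouse_id == 2], "0.1")
  expect_error(exclusion_filter(traj[0, ]),
               class = "angiotrial_domain_error")
})

test_that("a trial with only slow growers raises an empty-population error", {
  r <- case_ranges("slow", c(1e-7, 2e-7), c(3e-7, 7e-7),
                   ang0 = fix_ang0())  # k0 ~ 0.01/day: never reaches 0.1
  pop <- sample_population(r, 2, seed = 5)
  expect_error(run_trial(pop, make_protocol("A"), model = fix_model()),
               class = "angiotrial_domain_error")
})

test_that("paired arms share grid and parameters, treated never exceeds control", {
  trial <- fix_trial()
  tr <- trial$trajectories
  expect_setequal(unique(tr$arm), c("control", "treated"))
  for (id in trial$params$mouse_id) {
    c_ <- tr[tr$mouse_id == id & tr$arm == "control", ]
    t_ <- tr[tr$mouse_id == id & tr$arm == "treated", ]
    expect_identical(c_$day, t_$day)
    expect_equal(c_$volume_cm3[1], t_$volume_cm3[1])
    expect_true(all(t_$volume_cm3 <= c_$volume_cm3 * (1 + 1e-8)))
    expect_true(all(t_$ang_signal <= c_$ang_signal * (1 + 1e-6)))
  }
  # control arm carries no drug
  expect_true(all(tr$drug_plasma[tr$arm == "control"] == 0))
})

test_that("a vanishing dose reproduces the control arm", {
  r <- gen_case_ranges(1, seed = 3)[[1]]
  pop <- sample_population(r, 2, seed = 21)
  null_proto <- protocol("null", dose_mg_kg = 1e-9, trigger_volume = 0.1)
  trial <- run_trial(pop, null_proto, model = fix_model())
  tr <- trial$trajectories
  for (id in trial$params$mouse_id) {
    c_ <- tr[tr$mouse_id == id & tr$arm == "control", "volume_cm3"]
    t_ <- tr[tr$mouse_id == id & tr$arm == "treated", "volume_cm3"]
    expect_equal(t_, c_, tolerance = 1e-6)
  }
})

test_that("trials are deterministic given (population, protocol, config)", {
  r <- gen_case_ranges(1, seed = 3)[[1]]
  pop <- sample_population(r, 2, seed = 22)
  t1 <- run_trial(pop, make_protocol("A"), model = fix_model(), seed = 1)
  t2 <- run_trial(pop, make_protocol("A"), model = fix_model(), seed = 1)
  expect_identical(t1$trajectories, t2$trajectories)
  expect_identical(t1$triggers, t2$triggers)
})
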