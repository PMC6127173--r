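test_that("default network carries the full species roster", {
  m <- fix_model()
  sp <- m$species$name
  # isoforms in every compartment
  for (v in c("hv121", "hv165", "mv120", "mv164"))
    expect_true(all(paste0(v, c("_n", "_b", "_t")) %in% sp))
  # receptors on luminal and abluminal pools at both interfaces
  for (r in c("R1", "R2", "N1", "N2"))
    expect_true(all(paste0(r, c("_nab", "_nlu", "_tlu", "_tab")) %in% sp))
  expect_true(all(c("sR1_n", "sR1_b", "sR1_t", "a2m_b", "bev_b") %in% sp))
  # bevacizumab binds human isoforms only
  expect_true(all(c("hv121_bev_b", "hv165_bev_b") %in% sp))
  expect_false(any(grepl("^mv1(20|64)_bev", sp)))
})

test_that("signal complexes are the tumour-endothelium VEGF-VEGFR pool", {
  m <- fix_model()
  sig <- m$signal_complexes
  # all tumour-abluminal, all VEGFR1/R2-ligated (with or without NRP1)
  expect_true(all(grepl("_tab$", sig)))
  expect_true(all(grepl("_(R1|R2|R2N1)_", sig)))
  # neither soluble-receptor sequestration nor blood complexes count
  expect_false(any(grepl("sR1", sig)))
  comp <- m$species$compartment[match(sig, m$species$name)]
  expect_true(all(comp == "tumour"))
  # every tumour-abluminal R1/R2 complex is included
  sp <- m$species$name
  tab_rx <- sp[grepl("_(R1|R2|R2N1)_tab$", sp) & grepl("^.v1", sp)]
  expect_setequal(sig, tab_rx)
})

test_that("schema violations are rejected with classed errors", {
  m <- fix_model()
  bad <- m
  bad$reactions <- rbind(bad$reactions,
                         data.frame(a = "X", b = "R1_tab", c = "hv121_R1_tab",
                                    kf = 1, kr = 1))
  expect_error(validate_model(bad), class = "angiotrial_schema_error")

  cfg <- default_network_config()
  cfg$kon_R1 <- NULL
  expect_error(build_default_network(cfg), class = "angiotrial_config_error")
  expect_error(build_default_network(cfg), "kon_R1")
})

test_that("all-zero rates freeze the dynamics", {
  cfg <- default_network_config()
  for (nm in names(cfg))
    if (grepl("^(kon|koff|ps|lymph|clear|q)_", nm)) cfg[[nm]] <- 0
  m <- build_default_network(cfg)
  ode <- assemble_ode(m)
  gp <- growth_params(1e-9, 1e-9, ang0 = 1)  # k0 ~ 0: no growth either
  y0 <- ode$y0; y0[length(y0)] <- 0.004
  traj <- simulate_trajectory(ode, gp, horizon = 20, state0 = y0)
  expect_equal(max(abs(traj$volume - 0.004)), 0, tolerance = 1e-10)
  expect_lt(max(abs(sweep(traj$conc, 2, traj$conc[1, ]))), 1e-20)
})

test_that("derivative evaluator conserves a closed binding pair", {
  m <- pair_model(kon = 1e14, koff = 10, L0 = 1e-13, R0 = 2e-13)
  ode <- assemble_ode(m)
  gp <- growth_params(1e-9, 1e-9, ang0 = 1)
  for (C in c(0, 2e-14, 7e-14)) {
    st <- c(1e-13 - C, 2e-13 - C, C, 0.004)
    d <- ode_eval(ode, 0, st, gp, growth_on = FALSE)
    # total ligand (free + complexed) and receptor are conserved
    expect_equal(unname(d[["L_t"]] + d[["C_t"]]), 0, tolerance = 1e-25)
    expect_equal(unname(d[["R_t"]] + d[["C_t"]]), 0, tolerance = 1e-25)
  }
})

test_that("pure clearance decays linearly and matches the closed form", {
  m <- clearance_model(rate = 0.1, s0 = 1e-12)
  ode <- assemble_ode(m)
  gp <- growth_params(1e-9, 1e-9, ang0 = 1)
  d <- ode_eval(ode, 0, c(1e-12, 0.004), gp, growth_on = FALSE)
  expect_equal(unname(d[["s_b"]]), -0.1 * 1e-12, tolerance = 1e-20)
  y0 <- ode$y0; y0[length(y0)] <- 0.004
  traj <- simulate_trajectory(ode, gp, horizon = 10, state0 = y0)
  ratio <- traj$conc[traj$time == 10, "s_b"] / 1e-12
  expect_equal(unname(ratio), exp(-1), tolerance = 1e-6)
})

test_that("binding-pair steady state matches the analytic Kd solution", {
  # kon 1e6, koff 1e-3 => Kd 1e-9, totals L = R = 1e-9
  m <- pair_model(kon = 1e6, koff = 1e-3, L0 = 1e-9, R0 = 1e-9)
  ode <- assemble_ode(m)
  gp <- growth_params(1e-9, 1e-9, ang0 = 1)
  y0 <- ode$y0; y0[length(y0)] <- 0.004
  traj <- simulate_trajectory(ode, gp, horizon = 50000, state0 = y0,
                              out_times = c(0, 50000))
  n <- nrow(traj$conc)
  L <- traj$conc[n, "L_t"]; R <- traj$conc[n, "R_t"]; C <- traj$conc[n, "C_t"]
  expect_equal(unname(L * R / C), 1e-3 / 1e6, tolerance = 1e-6)
  exact <- pair_equilibrium(1e-9, 1e-9, 1e-9)
  expect_equal(unname(C), exact$C, tolerance = 1e-6)
})

test_that("mole totals are conserved along a transport-free trajectory", {
  cfg <- default_network_config()
  for (nm in names(cfg))
    if (grepl("^(ps|lymph|clear|q)_", nm)) cfg[[nm]] <- 0
  m <- build_default_network(cfg)
  ode <- assemble_ode(m)
  gp <- growth_params(1e-9, 1e-9, ang0 = 1)  # volume frozen at v0
  y0 <- ode$y0
  y0[seq_len(ode$nsp)][m$species$kind == "ligand"] <- 2e-13
  y0[length(y0)] <- 0.004
  traj <- simulate_trajectory(ode, gp, horizon = 30, state0 = y0)
  comp <- composition_matrix(m)
  vol <- ifelse(m$species$compartment == "normal", 3,
                ifelse(m$species$compartment == "blood", 1, 0.5 * 0.004))
  totals <- apply(traj$conc, 1, function(cc) comp %*% (cc * vol))
  drift <- apply(totals, 1, function(x) max(abs(x - x[1])) / max(x[1], 1e-30))
  expect_lt(max(drift), 1e-6)
})

test_that("angiogenic signal sums tumour complexes and excludes blood", {
  m <- fix_model()
  st <- setNames(rep(0, nrow(m$species)), m$species$name)
  expect_identical(compute_angiogenic_signal(st, m), 0)
  st[m$signal_complexes[1]] <- 1.0e-15
  st[m$signal_complexes[2]] <- 2.0e-15
  expect_equal(compute_angiogenic_signal(st, m), 3.0e-15)
  st[] <- 0
  st["hv165_R1_nlu"] <- 5e-14  # blood-compartment complex
  st["hv165_bev_b"] <- 5e-14
  expect_identical(compute_angiogenic_signal(st, m), 0)
})

test_that("simulated species stay nonnegative to tolerance", {
  traj <- simulate_trajectory(fix_ode(), gp_day(0.6, 0.04),
                              horizon = 60, state0 = fix_state())
  expect_gte(min(traj$conc), -1e-18)
})

test_that("drug appears only after the trigger crossing", {
  traj <- simulate_trajectory(fix_ode(), gp_day(0.7, 0.045),
                              protocol = make_protocol("A"),
                              state0 = fix_state())
  expect_true(is.finite(traj$trigger))
  before <- traj$time < traj$trigger
  expect_true(all(traj$drug[before] == 0))
  expect_true(all(traj$drug[traj$time > traj$trigger + 0.01] > 0))
  # the trigger is located accurately: volume there is the trigger volume
  vtrig <- traj$volume[which.min(abs(traj$time - traj$trigger))]
  expect_equal(vtrig, 0.1, tolerance = 1e-4)
})

test_that("bevacizumab never increases the angiogenic signal", {
  gp <- gp_day(0.7, 0.045)
  ctrl <- simulate_trajectory(fix_ode(), gp, horizon = 90,
                              state0 = fix_state())
  trt <- simulate_trajectory(fix_ode(), gp, protocol = make_protocol("A"),
                             state0 = fix_state(), horizon = 90)
  shared <- intersect(ctrl$time, trt$time)
  a_c <- ctrl$ang[match(shared, ctrl$time)]
  a_t <- trt$ang[match(shared, trt$time)]
  expect_true(all(a_t <= a_c * (1 + 1e-6)))
})
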