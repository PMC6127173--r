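# shared fixtures, built lazily once per test run

.fix <- new.env(parent = emptyenv())

fix_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_default_network()
  .fix$model
}

fix_ode <- function() {
  if (is.null(.fix$ode)) .fix$ode <- assemble_ode(fix_model())
  .fix$ode
}

fix_state <- function() {
  if (is.null(.fix$state)) .fix$state <- equilibrate_model(fix_ode())
  .fix$state
}

fix_ang0 <- function() fix_model()$params$ang0

# small paired trial reused by the metrics/survival/trial tests
fix_trial <- function() {
  if (is.null(.fix$trial)) {
    rngs <- gen_case_ranges(1, seed = 3)[[1]]
    pop <- sample_population(rngs, 8, seed = 11)
    .fix$trial <- run_trial(pop, make_protocol("A"), model = fix_model(),
                            seed = 11)
  }
  .fix$trial
}

# minimal one-binding-pair network: L + R <-> C in a single compartment
pair_model <- function(kon, koff, L0, R0, comp = "tumour",
                       signal = (comp == "tumour")) {
  tag <- c(normal = "n", blood = "b", tumour = "t")[[comp]]
  nm <- function(s) paste0(s, "_", tag)
  vegf_model(
    compartments = data.frame(name = c("normal", "blood", "tumour"),
                              fluid_volume = c(1, 1, NA)),
    species = data.frame(
      name = nm(c("L", "R", "C")),
      compartment = comp,
      kind = c("ligand", "surface_receptor", "complex"),
      initial = c(L0, R0, 0), stringsAsFactors = FALSE),
    reactions = data.frame(a = nm("L"), b = nm("R"), c = nm("C"),
                           kf = kon, kr = koff, stringsAsFactors = FALSE),
    transports = data.frame(species = character(0), from = character(0),
                            to = character(0), mechanism = character(0),
                            rate = numeric(0), vscale = logical(0)),
    signal_complexes = if (signal) nm("C") else character(0))
}

# network with a single cleared species in blood
clearance_model <- function(rate, s0 = 1e-12) {
  vegf_model(
    compartments = data.frame(name = c("normal", "blood", "tumour"),
                              fluid_volume = c(1, 1, NA)),
    species = data.frame(name = "s_b", compartment = "blood",
                         kind = "ligand", initial = s0,
                         stringsAsFactors = FALSE),
    reactions = data.frame(a = character(0), b = character(0),
                           c = character(0), kf = numeric(0),
                           kr = numeric(0)),
    transports = data.frame(species = "s_b", from = "blood", to = NA,
                            mechanism = "clearance", rate = rate,
                            vscale = FALSE, stringsAsFactors = FALSE),
    signal_complexes = character(0))
}

# analytic equilibrium of L + R <-> C with totals Lt, Rt and Kd
pair_equilibrium <- function(Lt, Rt, Kd) {
  b <- Lt + Rt + Kd
  C <- (b - sqrt(b^2 - 4 * Lt * Rt)) / 2
  list(L = Lt - C, R = Rt - C, C = C)
}

# growth params helper in per-second units from per-day magnitudes
gp_day <- function(k0_day, k1_day, psi = 20, ang0 = fix_ang0()) {
  growth_params(k0_day / 86400, k1_day / 86400, psi = psi, ang0 = ang0)
}

# brute-force product-limit estimator (independent oracle)
km_brute <- function(time, event) {
  et <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0))
  for (t in et) {
    n <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# brute-force log-rank accumulation over 2x2 tables (independent oracle)
logrank_brute <- function(ta, ea, tb, eb) {
  et <- sort(unique(c(ta[ea], tb[eb])))
  oe <- 0; v <- 0; o <- 0; e <- 0
  for (t in et) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t)
    d1 <- sum(ta == t & ea); d2 <- sum(tb == t & eb)
    n <- n1 + n2; d <- d1 + d2
    e1 <- d * n1 / n
    oe <- oe + d1 - e1
    o <- o + d1; e <- e + e1
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) oe^2 / v else 0
  list(statistic = stat,
       p_value = if (v > 0) pchisq(stat, 1, lower.tail = FALSE) else 1,
       o_minus_e = oe, var = v)
}

# brute-force Mantel-Haenszel common odds ratio over event-time strata
mh_brute <- function(ta, ea, tb, eb) {
  et <- sort(unique(c(ta[ea], tb[eb])))
  num <- 0; den <- 0
  for (t in et) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t)
    d1 <- sum(ta == t & ea); d2 <- sum(tb == t & eb)
    n <- n1 + n2
    num <- num + d1 * (n2 - d2) / n
    den <- den + d2 * (n1 - d1) / n
  }
  num / den
}
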