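## ODE assembly and integration --------------------------------------------
##
## assemble_ode() packs a validated model into flat index/rate arrays.
## Before each integration the arrays are loaded into the compiled core
## (C_set_model), and deSolve's lsoda/lsodar then call the compiled
## right-hand side directly, so stiff integration (including the
## numerically generated Jacobian) stays at C level.

#' Assemble the mass-action derivative evaluator for a model
#'
#' Packs the network into the flat arrays consumed by the compiled
#' right-hand side and returns an evaluator object. The evaluator maps
#' `(t, state)` to time-derivatives implementing mass-action kinetics,
#' volume-scaled transport, clearance, secretion and (when dosing is
#' configured at simulation time) intravenous infusion inputs; it is
#' deterministic and side-effect-free as a map from state to derivative.
#'
#' @param model a validated `vegf_model`.
#' @return an object of class `vegf_ode`; use [ode_eval()] to evaluate
#'   derivatives and [simulate_trajectory()] to integrate.
#' @export
assemble_ode <- function(model) {
  validate_model(model)
  sp <- model$species
  comp_id <- c(normal = 1L, blood = 2L, tumour = 3L)
  spi <- function(x) {
    i <- match(x, sp$name)
    if (anyNA(i))
      .schema_error("undeclared species: %s",
                    paste(x[is.na(i)], collapse = ", "))
    as.integer(i)
  }
  rx <- model$reactions
  tr <- model$transports
  sec <- tr[tr$mechanism == "secretion", , drop = FALSE]
  mv <- tr[tr$mechanism != "secretion", , drop = FALSE]

  vols <- c(model$compartments$fluid_volume[model$compartments$name == "normal"],
            model$compartments$fluid_volume[model$compartments$name == "blood"],
            model$interstitial_fraction)
  if (length(vols) != 3 || anyNA(vols[1:2]))
    .schema_error("normal and blood compartments need fixed fluid volumes")

  structure(list(
    model = model,
    nsp = nrow(sp),
    sp_comp = comp_id[sp$compartment],
    rx_a = if (nrow(rx)) spi(rx$a) else integer(0),
    rx_b = if (nrow(rx)) spi(rx$b) else integer(0),
    rx_c = if (nrow(rx)) spi(rx$c) else integer(0),
    rx_kf = as.numeric(rx$kf), rx_kr = as.numeric(rx$kr),
    tr_src = if (nrow(mv)) spi(mv$species) else integer(0),
    tr_dst = if (nrow(mv)) {
      dst <- integer(nrow(mv))
      has_to <- mv$mechanism != "clearance"
      dst[has_to] <- spi(.retag(mv$species[has_to], mv$to[has_to]))
      dst
    } else integer(0),
    tr_vs = as.integer(if (nrow(mv)) mv$vscale else logical(0)),
    tr_rate = as.numeric(mv$rate),
    sec_idx = if (nrow(sec)) spi(sec$species) else integer(0),
    sec_vs = as.integer(if (nrow(sec)) sec$vscale else logical(0)),
    sec_rate = as.numeric(sec$rate),
    sig_idx = spi(model$signal_complexes),
    vols = as.numeric(vols),
    drug_idx = {
      i <- match("bev_b", sp$name)
      if (is.na(i)) 0L else as.integer(i)
    },
    y0 = c(sp$initial, V = NA_real_)
  ), class = "vegf_ode")
}

## transported species are named for their *source* compartment; the
## destination twin carries the same stem with the destination tag
.retag <- function(species, to) {
  if (!length(species)) return(character(0))
  stem <- sub("_[nbt]$", "", species)
  paste0(stem, "_", vapply(to, .ctag, ""))
}

.growth_day <- function(growth, on = TRUE) {
  c(growth$k0 * .seconds_per_day, growth$k1 * .seconds_per_day,
    growth$psi, growth$ang0, as.numeric(on))
}

.activate <- function(ode, growth, growth_on = TRUE,
                      dose_times = numeric(0), dose_rate = 0,
                      dose_dur = 1 / 1440, root_vol = -1) {
  invisible(.Call("C_set_model",
                  as.integer(ode$sp_comp),
                  ode$rx_a, ode$rx_b, ode$rx_c, ode$rx_kf, ode$rx_kr,
                  ode$tr_src, ode$tr_dst, ode$tr_vs, ode$tr_rate,
                  ode$sec_idx, ode$sec_vs, ode$sec_rate,
                  ode$sig_idx, ode$vols,
                  .growth_day(growth, growth_on),
                  ode$drug_idx, as.numeric(dose_times),
                  as.numeric(dose_rate), as.numeric(dose_dur),
                  as.numeric(root_vol),
                  PACKAGE = "angiotrial"))
}

#' Evaluate the assembled derivative once
#'
#' @param ode a `vegf_ode` from [assemble_ode()].
#' @param t time (days).
#' @param state numeric vector: species concentrations followed by the
#'   total tumour volume.
#' @param growth a [growth_params()] object.
#' @param growth_on logical; `FALSE` freezes the volume equation.
#' @return derivative vector of the same length as `state`.
#' @export
ode_eval <- function(ode, t, state, growth, growth_on = TRUE) {
  .activate(ode, growth, growth_on = growth_on)
  d <- .Call("C_eval_rhs", as.numeric(t), as.numeric(state),
             PACKAGE = "angiotrial")
  names(d) <- c(ode$model$species$name, "V")
  d
}

.atol_for <- function(ode, conc_scale = 1e-21) {
  c(rep(conc_scale, ode$nsp), 1e-9)
}

.integrate <- function(ode, y0, times, rtol = 1e-7, atol = NULL,
                       maxsteps = 50000) {
  if (is.null(atol)) atol <- .atol_for(ode)
  out <- deSolve::lsoda(y = y0, times = times, func = "vegf_derivs",
                        parms = NULL, dllname = "angiotrial",
                        initfunc = NULL, nout = 0,
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (nrow(out) < length(times))
    .err("angiotrial_integration_error",
         "integration failed at t = %.4f (last valid state attached)",
         out[nrow(out), 1], data = out[nrow(out), ])
  out
}

## integrate with infusion windows; chunked at window boundaries so the
## adaptive integrator cannot step over a 1-minute infusion
.integrate_dosed <- function(ode, y0, times, dose_times, dose_dur, ...) {
  t0 <- times[1]; tend <- times[length(times)]
  bnd <- sort(unique(c(t0, tend,
                       dose_times[dose_times > t0 & dose_times < tend],
                       (dose_times + dose_dur)[dose_times + dose_dur > t0 &
                                               dose_times + dose_dur < tend])))
  rows <- NULL
  y <- y0
  for (i in seq_len(length(bnd) - 1)) {
    a <- bnd[i]; b <- bnd[i + 1]
    tt <- sort(unique(c(a, times[times > a & times < b], b)))
    seg <- .integrate(ode, y, tt, ...)
    y <- seg[nrow(seg), -1]
    keep <- seg[, 1] %in% times
    if (!is.null(rows)) keep <- keep & !(seg[, 1] %in% rows[, 1])
    rows <- rbind(rows, seg[keep, , drop = FALSE])
  }
  rows
}

#' Pre-equilibrate a model at fixed tumour volume
#'
#' Integrates the network with the volume equation frozen until the
#' species pools settle; used to start every simulation from the basal
#' (steady) state so that the angiogenic signal at t = 0 equals the
#' basal signal.
#'
#' @param ode a `vegf_ode`.
#' @param v0 initial total tumour volume (cm^3).
#' @param days equilibration horizon.
#' @return named state vector (species concentrations plus `V`).
#' @export
equilibrate_model <- function(ode, v0 = 0.004, days = 60) {
  growth <- growth_params(k0 = 1e-9, k1 = 1e-9, ang0 = 1)
  .activate(ode, growth, growth_on = FALSE)
  y0 <- ode$y0; y0[length(y0)] <- v0
  out <- .integrate(ode, y0, c(0, days / 2, days))
  st <- out[nrow(out), -1]
  names(st) <- c(ode$model$species$name, "V")
  st
}

#' Basal angiogenic signal of a model
#'
#' The angiogenic signal of the equilibrated (pre-treatment) state; the
#' natural default for the `Ang0` growth parameter.
#'
#' @inheritParams equilibrate_model
#' @return scalar signal (mol/cm^3).
#' @export
basal_angiogenic_signal <- function(ode, v0 = 0.004, days = 60) {
  if (inherits(ode, "vegf_model")) ode <- assemble_ode(ode)
  st <- equilibrate_model(ode, v0 = v0, days = days)
  compute_angiogenic_signal(st, ode$model)
}

#' Simulate a trajectory of the coupled species + volume system
#'
#' Integrates the full model with stiff-aware adaptive integration
#' (`deSolve::lsoda` on the compiled right-hand side). When a protocol
#' is given, treatment is trigger-started: the volume-threshold crossing
#' is located with root finding (`lsodar`), doses are scheduled from the
#' crossing time, and 1-minute intravenous infusions into the blood
#' compartment are integrated exactly (chunked at infusion windows).
#'
#' @param model a `vegf_model` or pre-assembled `vegf_ode`.
#' @param growth a [growth_params()] object (`k0` in 1/s, `k1` in
#'   cm^3/s).
#' @param horizon simulation end (days). Default for treated runs:
#'   trigger time + protocol horizon.
#' @param protocol optional [protocol()]; `NULL` simulates a control.
#' @param v0 initial tumour volume (cm^3).
#' @param state0 optional pre-equilibrated state (from
#'   [equilibrate_model()]); computed on the fly when missing.
#' @param out_times output grid (days); default daily from 0 to horizon.
#' @param body_mass_kg,molar_mass dosing conversion parameters.
#' @param max_trigger_wait give up locating the trigger crossing after
#'   this many days (mouse flagged untriggered and simulated drug-free).
#' @param neg_tol integrity tolerance on negative concentrations.
#' @return object of class `vegf_trajectory`: list with elements `time`,
#'   `volume`, `ang`, `drug`, `conc` (time x species matrix), `trigger`,
#'   `doses`, `untriggered`.
#' @export
simulate_trajectory <- function(model, growth, horizon = NULL,
                                protocol = NULL, v0 = 0.004,
                                state0 = NULL, out_times = NULL,
                                body_mass_kg = 0.02, molar_mass = 1.49e5,
                                max_trigger_wait = 120, neg_tol = 1e-18) {
  ode <- if (inherits(model, "vegf_ode")) model else assemble_ode(model)
  if (is.null(horizon) && is.null(protocol))
    .domain_error("horizon required for control simulations")
  if (!is.null(horizon) && horizon <= 0)
    .domain_error("horizon must be positive")
  if (is.null(state0)) state0 <- equilibrate_model(ode, v0 = v0)
  y0 <- state0
  y0[length(y0)] <- v0

  trigger <- NA_real_; doses <- numeric(0); untriggered <- FALSE
  dose_dur <- 1 / 1440; dose_rate <- 0
  if (!is.null(protocol)) {
    tw <- if (is.null(horizon)) max_trigger_wait else horizon
    trig <- .find_trigger(ode, growth, y0, protocol$trigger_volume, tw)
    trigger <- trig$time
    if (is.na(trigger)) {
      untriggered <- TRUE
      if (is.null(horizon)) horizon <- max_trigger_wait
    } else {
      doses <- schedule_doses(protocol, trigger)
      if (is.null(horizon)) horizon <- trigger + protocol$horizon_weeks * 7
      inf <- dose_to_infusion(protocol$dose_mg_kg, body_mass_kg, molar_mass,
                              protocol$infusion_minutes)
      dose_dur <- protocol$infusion_minutes / 1440
      dose_rate <- inf$rate_mol_per_min * 1440  # mol/day
    }
  }
  if (is.null(out_times)) out_times <- 0:ceiling(horizon)
  out_times <- sort(unique(c(out_times, if (!is.na(trigger)) trigger)))
  out_times <- out_times[out_times <= horizon + 1e-9]

  .activate(ode, growth, dose_times = doses, dose_rate = dose_rate,
            dose_dur = dose_dur)
  out <- if (length(doses))
    .integrate_dosed(ode, y0, out_times, doses, dose_dur)
  else .integrate(ode, y0, out_times)

  conc <- out[, 1 + seq_len(ode$nsp), drop = FALSE]
  colnames(conc) <- ode$model$species$name
  if (min(conc) < -neg_tol)
    .err("angiotrial_integrity_error",
         "negative concentration beyond tolerance (min %.3e)", min(conc))
  ang <- if (length(ode$sig_idx))
    rowSums(conc[, ode$sig_idx, drop = FALSE]) else rep(0, nrow(out))
  structure(list(
    time = out[, 1],
    volume = out[, 1 + ode$nsp + 1],
    ang = ang,
    drug = if (ode$drug_idx > 0) conc[, ode$drug_idx] else rep(0, nrow(out)),
    conc = conc,
    trigger = trigger,
    doses = doses,
    untriggered = untriggered
  ), class = "vegf_trajectory")
}

## locate the first upward crossing of the trigger volume (lsodar root)
.find_trigger <- function(ode, growth, y0, trigger_volume, tmax) {
  V0 <- y0[length(y0)]
  if (V0 >= trigger_volume) return(list(time = 0, state = y0))
  .activate(ode, growth, root_vol = trigger_volume)
  out <- deSolve::lsodar(y = y0, times = c(0, tmax), func = "vegf_derivs",
                         parms = NULL, dllname = "angiotrial",
                         initfunc = NULL, nout = 0,
                         rootfunc = "vegf_root", nroot = 1,
                         rtol = 1e-7, atol = .atol_for(ode),
                         maxsteps = 50000)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0 || is.na(troot[1]))
    return(list(time = NA_real_, state = NULL))
  list(time = troot[1], state = out[nrow(out), -1])
}

#' Tumour interstitial fluid volume
#'
#' The pluggable coupling between total tumour volume and interstitial
#' fluid volume; the packaged form is a constant fraction.
#'
#' @param model a `vegf_model`.
#' @param V total tumour volume (cm^3).
#' @return interstitial fluid volume (cm^3).
#' @export
interstitial_volume <- function(model, V) model$interstitial_fraction * V

#' Convert a trajectory to a tidy table
#'
#' @param traj a `vegf_trajectory`.
#' @param mouse_id,arm identifiers attached to every row.
#' @return data.frame with columns `mouse_id`, `arm`, `day`,
#'   `volume_cm3`, `ang_signal`, `drug_plasma`.
#' @export
trajectory_table <- function(traj, mouse_id = 1L, arm = "control") {
  data.frame(mouse_id = mouse_id, arm = arm, day = traj$time,
             volume_cm3 = traj$volume, ang_signal = traj$ang,
             drug_plasma = traj$drug, stringsAsFactors = FALSE)
}
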