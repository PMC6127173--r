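## population_trial: virtual populations and paired control/treated runs ---

#' Per-case sampling ranges for the growth kinetics
#'
#' @param case_label label of the training case the ranges derive from.
#' @param k0_range,k1_range length-2 numeric `c(min, max)` (k0 in 1/s,
#'   k1 in cm^3/s).
#' @param ang0 fixed basal signal for the case (the median of its
#'   fitted values).
#' @param psi switch sharpness (held constant).
#' @return object of class `case_ranges`.
#' @export
case_ranges <- function(case_label, k0_range, k1_range, ang0, psi = 20) {
  for (r in list(k0_range, k1_range)) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      .domain_error("ranges must be positive finite c(min, max)")
  }
  if (ang0 <= 0) .domain_error("ang0 must be positive")
  structure(list(case_label = case_label,
                 k0_range = as.numeric(k0_range),
                 k1_range = as.numeric(k1_range),
                 ang0 = ang0, psi = psi),
            class = "case_ranges")
}

#' Sample a virtual mouse population
#'
#' `k0` and `k1` are drawn i.i.d. uniform on their case ranges,
#' independently of each other; `Ang0` and `psi` are fixed per case.
#'
#' @param ranges a [case_ranges()].
#' @param n population size (>= 1).
#' @param seed integer seed (reproducible sampling).
#' @return data.frame with columns `mouse_id`, `case_label`, `k0`, `k1`,
#'   `psi`, `ang0`.
#' @export
sample_population <- function(ranges, n, seed = 1L) {
  if (!is.numeric(n) || n < 1) .domain_error("n must be >= 1")
  n <- as.integer(n)
  rng <- .with_seed(seed, {
    list(k0 = runif(n, ranges$k0_range[1], ranges$k0_range[2]),
         k1 = runif(n, ranges$k1_range[1], ranges$k1_range[2]))
  })
  data.frame(mouse_id = seq_len(n), case_label = ranges$case_label,
             k0 = rng$k0, k1 = rng$k1, psi = ranges$psi, ang0 = ranges$ang0,
             stringsAsFactors = FALSE)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Engraftment exclusion filter
#'
#' A mouse is retained iff its control tumour reaches the threshold
#' volume within the window after engraftment: tumours that do not
#' reach 0.1 cm^3 within 10 days (from an initial volume of 0.004 cm^3)
#' are excluded as unrealistically slow. Applied to the control arm
#' only, before any treatment assignment.
#'
#' @param control either a long trajectory table (columns `mouse_id`,
#'   `day`, `volume_cm3`; treated rows, if present, are ignored) or a
#'   data.frame with columns `mouse_id`, `t_cross` (first crossing time,
#'   `NA` if never).
#' @param threshold volume threshold (cm^3).
#' @param window days allowed to reach the threshold.
#' @return data.frame `mouse_id`, `retained`, `reason` (`""` when
#'   retained).
#' @export
exclusion_filter <- function(control, threshold = 0.1, window = 10) {
  if (!nrow(control)) .domain_error("empty population")
  if ("t_cross" %in% names(control)) {
    cross <- control[, c("mouse_id", "t_cross")]
  } else {
    if (!all(c("mouse_id", "day", "volume_cm3") %in% names(control)))
      .schema_error("control trajectories need mouse_id, day, volume_cm3")
    if ("arm" %in% names(control))
      control <- control[control$arm == "control", , drop = FALSE]
    cross <- do.call(rbind, lapply(split(control, control$mouse_id), function(d) {
      d <- d[order(d$day), ]
      hit <- which(d$volume_cm3 >= threshold)
      data.frame(mouse_id = d$mouse_id[1],
                 t_cross = if (length(hit)) d$day[hit[1]] else NA_real_)
    }))
  }
  retained <- !is.na(cross$t_cross) & cross$t_cross <= window
  data.frame(mouse_id = cross$mouse_id, retained = retained,
             reason = ifelse(retained, "",
                             sprintf("did not reach %g cm3 within %g days",
                                     threshold, window)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a paired control/treated in silico trial
#'
#' For every sampled mouse, a control simulation (no dosing) and a
#' treated simulation (protocol-triggered dosing) are run over the same
#' absolute horizon, so the paired trajectories share parameters,
#' initial volume and output grid and differ only in dosing events. The
#' common horizon is 12 weeks (the protocol horizon) past the latest
#' trigger among retained mice. The engraftment exclusion filter is
#' applied from the control dynamics before treatment simulation.
#'
#' @param population data.frame from [sample_population()].
#' @param protocol a [protocol()].
#' @param model a `vegf_model` (default packaged network).
#' @param v0 initial tumour volume (cm^3).
#' @param exclude apply the engraftment filter.
#' @param seed recorded into the result for provenance (the simulations
#'   themselves are deterministic).
#' @param max_trigger_wait days to wait for the dosing trigger.
#' @return object of class `vegf_trial`: list with `params` (retained
#'   mice), `trajectories` (long table: mouse_id, arm, day, volume_cm3,
#'   ang_signal, drug_plasma), `triggers`, `excluded`, `failures`,
#'   `horizon`, `protocol`, `seed`.
#' @export
run_trial <- function(population, protocol, model = NULL, v0 = 0.004,
                      exclude = TRUE, seed = NA_integer_,
                      max_trigger_wait = 120) {
  if (!nrow(population)) .domain_error("empty population")
  if (is.null(model)) model <- build_default_network()
  ode <- assemble_ode(model)
  state0 <- equilibrate_model(ode, v0 = v0)

  gp <- function(row) growth_params(row$k0, row$k1, row$psi, row$ang0)

  ## pass 1: exclusion crossing + dosing trigger from the control dynamics
  cross <- numeric(nrow(population)); trig <- numeric(nrow(population))
  fail <- character(0)
  y0 <- state0; y0[length(y0)] <- v0
  for (i in seq_len(nrow(population))) {
    p <- gp(population[i, ])
    res <- tryCatch({
      cx <- .find_trigger(ode, p, y0, 0.1, max_trigger_wait)
      tg <- if (protocol$trigger_volume == 0.1) cx
      else .find_trigger(ode, p, y0, protocol$trigger_volume,
                         max_trigger_wait)
      c(cx$time, tg$time)
    }, angiotrial_error = function(e) {
      fail <<- c(fail, sprintf("mouse %s: %s", population$mouse_id[i],
                               conditionMessage(e)))
      c(NA_real_, NA_real_)
    })
    cross[i] <- res[1]; trig[i] <- res[2]
  }

  excl <- exclusion_filter(data.frame(mouse_id = population$mouse_id,
                                      t_cross = cross))
  keep <- if (exclude) excl$retained else rep(TRUE, nrow(population))
  keep <- keep & !population$mouse_id %in% .failed_ids(fail)
  if (!any(keep)) .domain_error("empty population after exclusion")

  pop <- population[keep, , drop = FALSE]
  trig_keep <- trig[keep]
  horizon <- ceiling(max(trig_keep, 0, na.rm = TRUE)) +
    protocol$horizon_weeks * 7
  grid <- 0:horizon

  rows <- vector("list", 2 * nrow(pop))
  triggers <- data.frame(mouse_id = pop$mouse_id, trigger_day = trig_keep,
                         untriggered = is.na(trig_keep))
  ok <- rep(TRUE, nrow(pop))
  for (i in seq_len(nrow(pop))) {
    p <- gp(pop[i, ])
    res <- tryCatch({
      ctrl <- simulate_trajectory(ode, p, horizon = horizon, v0 = v0,
                                  state0 = state0, out_times = grid)
      doses <- schedule_doses(protocol, trig_keep[i])
      trt <- if (length(doses)) {
        inf <- dose_to_infusion(protocol$dose_mg_kg)
        .simulate_with_doses(ode, p, state0, v0, grid, doses,
                             inf$rate_mol_per_min * 1440,
                             protocol$infusion_minutes / 1440)
      } else ctrl
      list(ctrl = ctrl, trt = trt)
    }, angiotrial_error = function(e) {
      fail <<- c(fail, sprintf("mouse %s: %s", pop$mouse_id[i],
                               conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { ok[i] <- FALSE; next }
    rows[[2 * i - 1]] <- .traj_rows(res$ctrl, pop$mouse_id[i], "control", grid)
    rows[[2 * i]] <- .traj_rows(res$trt, pop$mouse_id[i], "treated", grid)
  }

  structure(list(
    params = pop[ok, , drop = FALSE],
    trajectories = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
    triggers = triggers[ok, , drop = FALSE],
    excluded = excl[!excl$retained, , drop = FALSE],
    failures = fail,
    horizon = horizon,
    protocol = protocol,
    seed = seed
  ), class = "vegf_trial")
}

.failed_ids <- function(fail) {
  as.integer(sub("^mouse (\\S+):.*$", "\\1", fail))
}

.simulate_with_doses <- function(ode, growth, state0, v0, grid, doses,
                                 dose_rate, dose_dur) {
  y0 <- state0; y0[length(y0)] <- v0
  .activate(ode, growth, dose_times = doses, dose_rate = dose_rate,
            dose_dur = dose_dur)
  out <- .integrate_dosed(ode, y0, grid, doses, dose_dur)
  conc <- out[, 1 + seq_len(ode$nsp), drop = FALSE]
  colnames(conc) <- ode$model$species$name
  structure(list(
    time = out[, 1], volume = out[, 1 + ode$nsp + 1],
    ang = rowSums(conc[, ode$sig_idx, drop = FALSE]),
    drug = if (ode$drug_idx > 0) conc[, ode$drug_idx] else 0,
    conc = conc, trigger = doses[1], doses = doses, untriggered = FALSE
  ), class = "vegf_trajectory")
}

.traj_rows <- function(traj, mouse_id, arm, grid) {
  keep <- traj$time %in% grid
  data.frame(mouse_id = mouse_id, arm = arm, day = traj$time[keep],
             volume_cm3 = traj$volume[keep], ang_signal = traj$ang[keep],
             drug_plasma = traj$drug[keep], stringsAsFactors = FALSE)
}
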