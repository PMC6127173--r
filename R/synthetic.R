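## synthetic_data: generators for every pipeline input ---------------------
##
## All generators are pure functions of (spec, seed). The growth-curve
## generator emulates noisy MDA-MB-231-like xenograft volume series with
## known ground-truth kinetics; the survival and planted-threshold
## generators provide oracle inputs with known hazard structure.

#' Generate a noisy tumour growth dataset with known ground truth
#'
#' Simulates the full mechanistic model at the true parameters, samples
#' the volume at the requested days, and applies multiplicative
#' log-normal noise (`V * exp(N(0, sigma))`): tumour volume measurement
#' errors scale with size. The hidden truth is attached as an
#' attribute.
#'
#' @param truth a [growth_params()] (the ground-truth kinetics).
#' @param days sampling days (strictly increasing). The default is a
#'   twice-weekly schedule from day 3 to day 24 that spans the
#'   exponential phase, the growth-law switch and the linear phase --
#'   both rates are identifiable only when the design covers the
#'   curvature around the switch volume.
#' @param sigma log-scale noise SD (>= 0).
#' @param seed integer seed.
#' @param model a `vegf_model` (default packaged network).
#' @param v0 initial volume.
#' @param n_rep replicate noisy mice sharing the same truth.
#' @param warn_bounds warn when the truth lies outside the default
#'   fitting bounds (recovery tests require an interior truth).
#' @return data.frame `mouse_id`, `arm` (`"control"`), `day`,
#'   `volume_cm3`; attributes `truth` (the [growth_params()]) and
#'   `noiseless` (the clean series).
#' @export
gen_growth_dataset <- function(truth, days = c(3, 5, 7, 9, 12, 16, 20, 24),
                               sigma = 0.1, seed = 1L, model = NULL,
                               v0 = 0.004, n_rep = 1, warn_bounds = TRUE) {
  if (sigma < 0) .domain_error("sigma must be >= 0")
  if (is.unsorted(days, strictly = TRUE))
    .domain_error("days must be strictly increasing")
  if (warn_bounds) {
    cfg <- fit_config()
    th <- c(truth$k0, truth$k1, truth$ang0)
    if (any(th <= cfg$lower) || any(th >= cfg$upper))
      warning("ground truth lies outside the default fitting bounds")
  }
  if (is.null(model)) model <- build_default_network()
  ode <- if (inherits(model, "vegf_ode")) model else assemble_ode(model)
  state0 <- equilibrate_model(ode, v0 = v0)
  clean <- .sim_volumes(ode, state0, truth, days, v0)
  noisy <- .with_seed(seed, {
    vapply(seq_len(n_rep), function(i)
      clean * exp(rnorm(length(days), 0, sigma)), numeric(length(days)))
  })
  out <- data.frame(
    mouse_id = rep(seq_len(n_rep), each = length(days)),
    arm = "control",
    day = rep(days, n_rep),
    volume_cm3 = as.vector(noisy),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  attr(out, "noiseless") <- data.frame(day = days, volume_cm3 = clean)
  out
}

#' Generate per-case sampling ranges
#'
#' Emulates a set of training cases' fitted parameter ranges: per-case
#' uniform-sampling ranges for `k0` (1/s) and `k1` (cm^3/s) with a
#' fixed `Ang0`, constructed so that every case's attainable
#' `k0/k1`-ratio interval straddles a configurable target interval
#' (default the common threshold range 9.757-17.982 cm^-3).
#'
#' @param n_cases number of cases.
#' @param seed integer seed.
#' @param target_ratio_interval interval every case's ratio span must
#'   contain.
#' @param k1_low_span,k1_high_span sampling windows for the k1 range
#'   endpoints (cm^3/s).
#' @param ang0 fixed basal signal (default: the packaged network's
#'   basal signal).
#' @return list of [case_ranges()] named `case1`, `case2`, ...
#' @export
gen_case_ranges <- function(n_cases = 6, seed = 1L,
                            target_ratio_interval = c(9.757, 17.982),
                            k1_low_span = c(2.6e-7, 3.4e-7),
                            k1_high_span = c(6e-7, 7.5e-7),
                            ang0 = NULL) {
  if (is.null(ang0)) ang0 <- default_network_config()$ang0
  tlo <- target_ratio_interval[1]; thi <- target_ratio_interval[2]
  .with_seed(seed, {
    out <- lapply(seq_len(n_cases), function(i) {
      a <- runif(1, k1_low_span[1], k1_low_span[2])    # k1 min
      b <- runif(1, k1_high_span[1], k1_high_span[2])  # k1 max
      k0lo <- tlo * b * runif(1, 0.6, 0.95)  # ratio floor below target low
      k0hi <- max(thi * a * runif(1, 1.1, 1.6), k0lo * 1.3)
      case_ranges(sprintf("case%d", i), c(k0lo, k0hi), c(a, b), ang0)
    })
    names(out) <- vapply(out, `[[`, "", "case_label")
    out
  })
}

#' Generate an exponential survival cohort with known hazards
#'
#' Exponential event times per group with administrative censoring at a
#' fixed time; the true hazard ratio of group 1 vs group 2 is
#' `hazards[1] / hazards[2]` (e.g. hazards (1, 2) give a true HR of
#' 0.5: the first group's death rate is half the second's).
#'
#' @param n_per_arm subjects per group (scalar or length-2).
#' @param hazards positive event rates, one per group.
#' @param censor_time administrative censoring time (0 censors
#'   everyone).
#' @param seed integer seed.
#' @param labels group labels.
#' @return survival records data.frame (see [surv_records()]).
#' @export
gen_survival_cohort <- function(n_per_arm = 500, hazards = c(1, 2),
                                censor_time = 3, seed = 1L,
                                labels = paste0("g", seq_along(hazards))) {
  if (any(hazards <= 0)) .domain_error("hazards must be positive")
  if (censor_time < 0) .domain_error("censor time must be >= 0")
  n <- rep_len(n_per_arm, length(hazards))
  .with_seed(seed, {
    recs <- lapply(seq_along(hazards), function(g) {
      tt <- rexp(n[g], rate = hazards[g])
      event <- tt <= censor_time
      surv_records(time = pmin(tt, censor_time), status = event,
                   group = labels[g],
                   mouse_id = paste0(labels[g], "_", seq_len(n[g])))
    })
    do.call(rbind, recs)
  })
}

#' Generate a planted-threshold population
#'
#' Mice with uniform `(k0, k1)`; the event hazard is low for mice whose
#' `k0/k1` ratio exceeds the planted threshold `r_star` and high
#' otherwise, so a threshold sweep should recover an interval
#' containing `r_star`. The truth is attached as an attribute.
#'
#' @param n population size.
#' @param r_star planted ratio threshold (must be interior to the
#'   generated ratio span).
#' @param hazard_low,hazard_high event rates (per day) above/below the
#'   threshold; equal rates give a null population.
#' @param censor_time administrative censoring (days).
#' @param seed integer seed.
#' @param k0_range,k1_range sampling ranges (1/s, cm^3/s).
#' @return records data.frame with columns `mouse_id`, `time_days`,
#'   `status`, `group` (`"treated"`), `k0`, `k1`; attribute `r_star`.
#' @export
gen_planted_threshold_population <- function(n = 400, r_star = 13.87,
                                             hazard_low = 0.012,
                                             hazard_high = 0.08,
                                             censor_time = 84, seed = 1L,
                                             k0_range = c(5e-6, 1.5e-5),
                                             k1_range = c(3e-7, 7e-7)) {
  span <- c(k0_range[1] / k1_range[2], k0_range[2] / k1_range[1])
  if (r_star <= span[1] || r_star >= span[2])
    .domain_error("r_star %.4g outside the attainable ratio span [%.4g, %.4g]",
                  r_star, span[1], span[2])
  .with_seed(seed, {
    k0 <- runif(n, k0_range[1], k0_range[2])
    k1 <- runif(n, k1_range[1], k1_range[2])
    ratio <- k0 / k1
    haz <- ifelse(ratio > r_star, hazard_low, hazard_high)
    tt <- rexp(n, rate = haz)
    event <- tt <= censor_time
    out <- cbind(surv_records(time = pmin(tt, censor_time), status = event,
                              group = "treated", mouse_id = seq_len(n)),
                 k0 = k0, k1 = k1)
    attr(out, "r_star") <- r_star
    out
  })
}
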