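## model_fitting: bounded multistart least squares for (k0, k1, Ang0) ------

#' Sum of squared residuals
#'
#' @param observed,simulated matched volume series (equal length, same
#'   time points).
#' @return `sum((observed - simulated)^2)`.
#' @export
ssr <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    .domain_error("observed and simulated series differ in length")
  sum((observed - simulated)^2)
}

#' Fitting configuration
#'
#' Bounds, multistart count and objective for [fit_control()]. The
#' default bounds span at least two orders of magnitude per parameter:
#' 1e-8 to 1e-2 for `k0` (1/s) and `k1` (cm^3/s) and 1e-16 to 1e-14 for
#' `Ang0` (mol/cm^3).
#'
#' @param lower,upper named bounds for `k0`, `k1`, `ang0`.
#' @param n_starts number of multistart points (log-uniform over the
#'   bounds).
#' @param n_refine number of local optimizations: the objective is
#'   evaluated once at every start point and the Levenberg-Marquardt
#'   refinement runs from the `n_refine` best (screening keeps the
#'   multistart cheap on a multimodal landscape).
#' @param objective `"absolute"` fits raw volumes; `"normalized"` fits
#'   series normalized to `reference_day` (for datasets reported only
#'   relative to a fixed day, which also require the tumour
#'   interstitial-volume coupling of the supplied model).
#' @param reference_day normalization day for the normalized objective.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(lower = c(k0 = 1e-8, k1 = 1e-8, ang0 = 1e-16),
                       upper = c(k0 = 1e-2, k1 = 1e-2, ang0 = 1e-14),
                       n_starts = 50, n_refine = 8,
                       objective = c("absolute", "normalized"),
                       reference_day = 8, maxiter = 60) {
  objective <- match.arg(objective)
  nm <- c("k0", "k1", "ang0")
  if (!all(nm %in% names(lower)) || !all(nm %in% names(upper)))
    .domain_error("bounds must name k0, k1, ang0")
  lower <- lower[nm]; upper <- upper[nm]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower >= upper))
    .domain_error("bounds must be finite with 0 < lower < upper")
  structure(list(lower = lower, upper = upper, n_starts = n_starts,
                 n_refine = min(n_refine, n_starts), objective = objective,
                 reference_day = reference_day, maxiter = maxiter),
            class = "fit_config")
}

## simulate the control volume series of the full model at given growth
## parameters, sampled at the data days
.sim_volumes <- function(ode, state0, growth, days, v0) {
  tt <- sort(unique(c(0, days)))
  y0 <- state0; y0[length(y0)] <- v0
  .activate(ode, growth)
  out <- .integrate(ode, y0, tt)
  out[match(days, out[, 1]), ncol(out)]
}

#' Fit growth kinetics to control tumour volume data
#'
#' Bounded multistart nonlinear least squares: for each of `n_starts`
#' log-uniform start points over the bounds, the full mechanistic model
#' is simulated at the proposed `(k0, k1, Ang0)` and the sum of squared
#' residuals against the observed control volumes is minimized with the
#' Levenberg-Marquardt algorithm (box-constrained, on log10-transformed
#' parameters). Results are sorted by SSR; ties break on the lowest
#' start index.
#'
#' @param data data.frame with columns `day` and `volume_cm3` (>= 3
#'   time points; a long table with an `arm` column is filtered to the
#'   control arm and averaged per day).
#' @param config a [fit_config()].
#' @param model a `vegf_model` (default packaged network).
#' @param seed integer seed for the start points.
#' @param v0 initial tumour volume.
#' @param psi switch sharpness (held constant during fitting).
#' @return data.frame of class `fit_results`: `start_id`, `k0`, `k1`,
#'   `ang0`, `ssr`, `converged`, sorted by `ssr`.
#' @export
fit_control <- function(data, config = fit_config(), model = NULL,
                        seed = 1L, v0 = 0.004, psi = 20) {
  data <- .control_series(data)
  if (nrow(data) < 3) .domain_error("need at least 3 time points")
  if (all(data$volume_cm3 <= 0)) .domain_error("degenerate data: all zero")
  if (is.null(model)) model <- build_default_network()
  ode <- if (inherits(model, "vegf_ode")) model else assemble_ode(model)
  state0 <- equilibrate_model(ode, v0 = v0)

  obs <- data$volume_cm3
  days <- data$day
  if (config$objective == "normalized")
    obs <- normalize_to_reference_day(obs, days, config$reference_day)

  lo <- log10(config$lower); hi <- log10(config$upper)
  resid_fn <- function(u) {
    th <- 10^u
    growth <- growth_params(th[1], th[2], psi, th[3])
    sim <- tryCatch(.sim_volumes(ode, state0, growth, days, v0),
                    angiotrial_error = function(e) rep(NA_real_, length(days)))
    if (anyNA(sim)) return(rep(1e6, length(obs)))
    if (config$objective == "normalized")
      sim <- tryCatch(normalize_to_reference_day(sim, days,
                                                 config$reference_day),
                      angiotrial_error = function(e) rep(1e6, length(obs)))
    obs - sim
  }

  starts <- .with_seed(seed, {
    matrix(runif(3 * config$n_starts), ncol = 3)
  })
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")

  ## screen: one objective evaluation per start, refine from the best
  screen <- vapply(seq_len(config$n_starts),
                   function(i) sum(resid_fn(starts[i, ])^2), numeric(1))
  refine <- order(screen)[seq_len(config$n_refine)]

  fits <- lapply(refine, function(i) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    th <- 10^res$par
    data.frame(start_id = i, k0 = th[1], k1 = th[2], ang0 = th[3],
               ssr = sum(res$fvec^2), converged = res$info %in% 1:4)
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
  if (is.null(fits) || !nrow(fits))
    .err("angiotrial_fit_error", "all %d starts failed", config$n_starts)
  fits <- fits[order(fits$ssr, fits$start_id), ]
  rownames(fits) <- NULL
  structure(fits, config = config, class = c("fit_results", "data.frame"))
}

.control_series <- function(data) {
  if ("arm" %in% names(data)) data <- data[data$arm == "control", ]
  if (!all(c("day", "volume_cm3") %in% names(data)))
    .schema_error("fit data needs columns day, volume_cm3")
  agg <- stats::aggregate(volume_cm3 ~ day, data = data, FUN = mean)
  agg[order(agg$day), ]
}

#' Validate fits against treatment data and select the best sets
#'
#' Each candidate fit is validated by simulating the treatment protocol
#' and scoring the combined control + treatment sum of squared
#' residuals on the objective scale (day-normalized volumes for the
#' normalized objective). The `k` parameter sets with the smallest
#' combined error are returned (the "best" sets); their parameter
#' ranges feed [case_ranges()] for population generation via
#' [fit_ranges()].
#'
#' @param fits a `fit_results` from [fit_control()].
#' @param control_data,treatment_data data.frames `day`, `volume_cm3`.
#' @param protocol a [protocol()] (or explicit dose day vector via
#'   `dose_days`).
#' @param k number of sets to select (default 12).
#' @param model,v0,psi as in [fit_control()].
#' @param config a [fit_config()] (objective scale); defaults to the
#'   one attached to `fits`.
#' @param dose_days optional explicit dosing days overriding the
#'   trigger logic (e.g. fixed weekly cycles from day 5).
#' @return `fit_results` of the `k` selected sets with an added
#'   `ssr_combined` column, sorted nondecreasing.
#' @export
validate_and_select <- function(fits, control_data, treatment_data,
                                protocol = NULL, k = 12, model = NULL,
                                v0 = 0.004, psi = 20, config = NULL,
                                dose_days = NULL) {
  if (is.null(config)) config <- attr(fits, "config")
  if (is.null(config)) config <- fit_config()
  control_data <- .control_series(control_data)
  trt <- treatment_data
  if (!all(c("day", "volume_cm3") %in% names(trt)))
    .schema_error("treatment data needs columns day, volume_cm3")
  if (is.null(model)) model <- build_default_network()
  ode <- if (inherits(model, "vegf_ode")) model else assemble_ode(model)
  state0 <- equilibrate_model(ode, v0 = v0)

  scale_fn <- function(v, days) {
    if (config$objective == "normalized")
      normalize_to_reference_day(v, days, config$reference_day)
    else v
  }
  obs_c <- scale_fn(control_data$volume_cm3, control_data$day)
  obs_t <- scale_fn(trt$volume_cm3, trt$day)

  combined <- vapply(seq_len(nrow(fits)), function(i) {
    growth <- growth_params(fits$k0[i], fits$k1[i], psi, fits$ang0[i])
    sim_c <- tryCatch(.sim_volumes(ode, state0, growth, control_data$day, v0),
                      angiotrial_error = function(e) NULL)
    if (is.null(sim_c)) return(Inf)
    doses <- if (!is.null(dose_days)) dose_days else {
      y0 <- state0; y0[length(y0)] <- v0
      tg <- .find_trigger(ode, growth, y0, protocol$trigger_volume,
                          max(trt$day))
      schedule_doses(protocol, tg$time)
    }
    sim_t <- tryCatch({
      if (length(doses)) {
        inf <- dose_to_infusion(if (!is.null(protocol)) protocol$dose_mg_kg
                                else 10)
        y0 <- state0; y0[length(y0)] <- v0
        .activate(ode, growth, dose_times = doses,
                  dose_rate = inf$rate_mol_per_min * 1440,
                  dose_dur = 1 / 1440)
        tt <- sort(unique(c(0, trt$day)))
        out <- .integrate_dosed(ode, y0, tt, doses, 1 / 1440)
        out[match(trt$day, out[, 1]), ncol(out)]
      } else .sim_volumes(ode, state0, growth, trt$day, v0)
    }, angiotrial_error = function(e) NULL)
    if (is.null(sim_t) || anyNA(sim_t)) return(Inf)
    ssr(obs_c, scale_fn(sim_c, control_data$day)) +
      ssr(obs_t, scale_fn(sim_t, trt$day))
  }, numeric(1))

  fits$ssr_combined <- combined
  ord <- order(combined, fits$start_id)
  if (nrow(fits) < k) {
    warning(sprintf("only %d fits available (< k = %d); returning all",
                    nrow(fits), k))
    k <- nrow(fits)
  }
  out <- fits[ord[seq_len(k)], ]
  rownames(out) <- NULL
  structure(out, config = config, class = c("fit_results", "data.frame"))
}

#' Case ranges from selected fits
#'
#' The parameter ranges of the selected best fits, as sampling ranges
#' for population generation; `Ang0` is fixed at the median of its
#' estimates.
#'
#' Because the growth law depends on the kinetics only through
#' `(k0/Ang0, k1/Ang0)` scaling (the modulation is linear in
#' `Ang/Ang0`), least-squares fits are identified up to a common
#' rescaling of `(k0, k1, Ang0)`. Taking raw per-parameter ranges
#' across fits would therefore mix incommensurable ridge points; by
#' default every fit is first re-expressed at the common (median)
#' `Ang0` before the ranges are taken.
#'
#' @param fits selected `fit_results`.
#' @param case_label label for the derived case.
#' @param normalize_ang0 re-express each fit at the median `Ang0`
#'   (recommended; see Details).
#' @return a [case_ranges()].
#' @export
fit_ranges <- function(fits, case_label = "fitted",
                       normalize_ang0 = TRUE) {
  a0 <- median(fits$ang0)
  k0 <- fits$k0; k1 <- fits$k1
  if (normalize_ang0) {
    scale <- a0 / fits$ang0
    k0 <- k0 * scale; k1 <- k1 * scale
  }
  case_ranges(case_label, k0_range = range(k0), k1_range = range(k1),
              ang0 = a0)
}
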