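## tumour_growth: switching exponential-to-linear growth law ---------------

#' Tumour growth kinetic parameters
#'
#' @param k0 exponential growth rate. Canonical user-facing unit: 1/s
#'   (the time unit cancels wherever only the `k0/k1` ratio matters; the
#'   formula functions [growth_rate()] and [modulation()] are
#'   unit-neutral).
#' @param k1 linear growth rate (cm^3/s canonically).
#' @param psi sharpness of the exponential-to-linear switch
#'   (dimensionless, >= 1). Held constant by default: a sensitivity
#'   analysis motivating this model showed it does not materially
#'   influence tumour volume.
#' @param ang0 basal angiogenic signal at t = 0 (mol/cm^3).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(k0, k1, psi = 20, ang0) {
  if (!is.finite(k0) || !is.finite(k1) || !is.finite(psi) || !is.finite(ang0))
    .domain_error("growth parameters must be finite")
  if (k0 <= 0 || k1 <= 0 || ang0 <= 0)
    .domain_error("k0, k1 and ang0 must be positive")
  if (psi < 1)
    .domain_error("psi must be >= 1")
  structure(list(k0 = k0, k1 = k1, psi = psi, ang0 = ang0),
            class = "growth_params")
}

#' Angiogenic modulation factor
#'
#' Linear scaling of VEGF-mediated growth by the angiogenic signal
#' relative to its basal value: `max(Ang/Ang0, 0)`; equals 1 at the
#' basal signal and 0 when the signal is fully suppressed.
#'
#' @param ang angiogenic signal.
#' @param ang0 basal signal (> 0).
#' @return dimensionless factor.
#' @export
modulation <- function(ang, ang0) {
  if (any(!is.finite(ang0)) || any(ang0 <= 0))
    .domain_error("ang0 must be positive")
  pmax(ang / ang0, 0)
}

## overflow-safe [1 + q^psi]^(1/psi)
.switch_denom <- function(q, psi) {
  ifelse(q <= 1,
         (1 + q^psi)^(1 / psi),
         q * (q^(-psi) + 1)^(1 / psi))
}

#' Tumour growth rate dV/dt
#'
#' The switching growth law
#' `m(Ang) * k0 * V / (1 + (k0 V / k1)^psi)^(1/psi)` with angiogenic
#' modulation `m(Ang) = max(Ang/Ang0, 0)`: exponential growth at rate
#' `k0` for small volumes, saturating to linear growth at rate `k1`
#' above the switch volume `k1/k0`, with sharpness `psi`. The rate is
#' never negative: anti-VEGF treatment limits growth, it does not shrink
#' the tumour.
#'
#' The formula is unit-neutral: the returned rate carries whatever
#' volume-per-time unit `k1` is supplied in.
#'
#' @param V tumour volume (>= 0).
#' @param ang angiogenic signal (>= 0 scale; negative signals are
#'   rejected).
#' @param p a [growth_params()] object.
#' @return growth rate dV/dt (same units as `k1`).
#' @export
growth_rate <- function(V, ang, p) {
  if (any(!is.finite(V)) || any(!is.finite(ang)))
    .domain_error("V and ang must be finite")
  if (any(V < 0) || any(ang < 0))
    .domain_error("V and ang must be nonnegative")
  m <- modulation(ang, p$ang0)
  q <- p$k0 * V / p$k1
  m * p$k0 * V / .switch_denom(q, p$psi)
}

#' Integrate the growth law alone
#'
#' Solves `dV/dt = growth_rate(V, ang, p)` with a constant angiogenic
#' signal (defaults to the basal signal, i.e. modulation 1). Useful for
#' analytic cross-checks and fast synthetic curves; the full coupled
#' system is integrated by [simulate_trajectory()].
#'
#' @param p a [growth_params()] with `k0` in 1/s and `k1` in cm^3/s.
#' @param v0 initial volume (cm^3).
#' @param days output times (days).
#' @param ang constant signal (default `p$ang0`).
#' @return data.frame with columns `day`, `volume_cm3`.
#' @export
simulate_growth <- function(p, v0 = 0.004, days = 0:84, ang = NULL) {
  if (is.null(ang)) ang <- p$ang0
  k0d <- p$k0 * .seconds_per_day
  k1d <- p$k1 * .seconds_per_day
  m <- modulation(ang, p$ang0)
  rhs <- function(t, y, parms) {
    q <- k0d * y[1] / k1d
    list(m * k0d * y[1] / .switch_denom(q, p$psi))
  }
  out <- deSolve::lsoda(c(V = v0), times = days, func = rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  data.frame(day = out[, 1], volume_cm3 = out[, 2])
}
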