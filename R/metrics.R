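## endpoint_metrics: relative tumour volume and per-day comparisons --------

#' Relative tumour volume time course
#'
#' `RTV(t)` is the ratio between the mean tumour volume of the treated
#' group and that of the control group at each shared time point; a
#' value below one means the treatment limits growth. The endpoint RTV
#' is the value at the final shared time. Because the paired arms share
#' mice, a per-mouse RTV (treated/control per mouse) is also summarized:
#' its standard deviation is reported as the dispersion measure.
#'
#' @param trial a `vegf_trial` or long trajectory table with both arms.
#' @return data.frame `day`, `mean_treated`, `mean_control`, `rtv`,
#'   `rtv_sd`, `n`; attribute `endpoint` holds the final-day row.
#' @export
rtv_timecourse <- function(trial) {
  tr <- if (inherits(trial, "vegf_trial")) trial$trajectories else trial
  if (is.null(tr) || !nrow(tr)) .domain_error("empty population")
  ctrl <- tr[tr$arm == "control", ]
  trt <- tr[tr$arm == "treated", ]
  if (!nrow(ctrl) || !nrow(trt))
    .domain_error("need both control and treated arms")
  days <- sort(intersect(unique(ctrl$day), unique(trt$day)))
  cw <- .vol_matrix(ctrl, days)
  tw <- .vol_matrix(trt, days)
  common <- intersect(rownames(cw), rownames(tw))
  cw <- cw[common, , drop = FALSE]; tw <- tw[common, , drop = FALSE]
  mc <- colMeans(cw); mt <- colMeans(tw)
  if (any(mc <= 0)) .domain_error("RTV undefined where mean control <= 0")
  per_mouse <- tw / cw
  out <- data.frame(day = days, mean_treated = mt, mean_control = mc,
                    rtv = mt / mc, rtv_sd = apply(per_mouse, 2, sd),
                    n = nrow(cw), row.names = NULL)
  attr(out, "endpoint") <- out[nrow(out), ]
  out
}

## mice x days volume matrix on a fixed day grid
.vol_matrix <- function(d, days) {
  ids <- sort(unique(d$mouse_id))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(days),
              dimnames = list(ids, days))
  m[cbind(match(d$mouse_id, ids), match(d$day, days))] <- d$volume_cm3
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Normalize a volume series to a reference day
#'
#' Divides every volume by the value at the reference day (the
#' convention used by studies that only report volumes relative to a
#' fixed day, e.g. day 8); the result is invariant under rescaling the
#' raw series by any positive constant.
#'
#' @param volumes numeric volumes.
#' @param days matching day vector.
#' @param reference_day day to normalize to (must be present with a
#'   positive volume).
#' @return normalized series (value 1 at the reference day).
#' @export
normalize_to_reference_day <- function(volumes, days, reference_day) {
  i <- match(reference_day, days)
  if (is.na(i)) .domain_error("reference day %s not in series",
                              format(reference_day))
  if (!is.finite(volumes[i]) || volumes[i] <= 0)
    .domain_error("volume at reference day must be positive")
  volumes / volumes[i]
}

#' Per-day two-sample comparison between arms
#'
#' Welch's unequal-variance two-sample t-test between treated and
#' control volumes at each shared day; the flag marks days where the
#' difference is statistically significant (p < alpha). Identical
#' (degenerate-variance) arms are never flagged. No multiple-testing
#' correction is applied across days.
#'
#' @param trial a `vegf_trial` or long trajectory table.
#' @param alpha significance level.
#' @return data.frame `day`, `p_value`, `significant`.
#' @export
timepoint_comparison <- function(trial, alpha = 0.05) {
  tr <- if (inherits(trial, "vegf_trial")) trial$trajectories else trial
  ctrl <- tr[tr$arm == "control", ]
  trt <- tr[tr$arm == "treated", ]
  days <- sort(intersect(unique(ctrl$day), unique(trt$day)))
  if (length(unique(ctrl$mouse_id)) < 2 || length(unique(trt$mouse_id)) < 2)
    .domain_error("need >= 2 mice per arm")
  p <- vapply(days, function(d) {
    x <- trt$volume_cm3[trt$day == d]
    y <- ctrl$volume_cm3[ctrl$day == d]
    if (isTRUE(all.equal(x, y)) || (sd(x) == 0 && sd(y) == 0)) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(day = days, p_value = p, significant = p < alpha)
}
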