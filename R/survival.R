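## survival_analysis: sacrifice rule, Kaplan-Meier, log-rank, MH HR --------
##
## The product-limit estimator, the Mantel-Cox log-rank test and the
## Mantel-Haenszel hazard ratio are implemented directly (the threshold
## sweep evaluates the log-rank test tens of thousands of times, so the
## implementation is vectorised over the pooled risk table); the test
## suite cross-checks them against the survival package and against
## brute-force hand computations.

#' Construct/validate survival records
#'
#' @param time event/censor times (days, > 0).
#' @param status `"event"` or `"censored"` (or logical/0-1, TRUE =
#'   event).
#' @param group group label.
#' @param mouse_id optional identifiers.
#' @return data.frame `mouse_id`, `time_days`, `status`, `group`.
#' @export
surv_records <- function(time, status, group = "all",
                         mouse_id = seq_along(time)) {
  if (!length(time)) .domain_error("no survival records")
  if (any(!is.finite(time)) || any(time < 0))
    .domain_error("survival times must be finite and nonnegative")
  if (is.logical(status) || is.numeric(status))
    status <- ifelse(as.logical(status), "event", "censored")
  if (!all(status %in% c("event", "censored")))
    .domain_error("status must be 'event' or 'censored'")
  data.frame(mouse_id = mouse_id, time_days = time, status = status,
             group = group, stringsAsFactors = FALSE)
}

#' Derive survival records from tumour volume trajectories
#'
#' An in silico mouse is "sacrificed" (event) at the first sampled time
#' its tumour volume reaches the cutoff (2 cm^3, as typically done in
#' experimental studies); if the cutoff is never reached the mouse is
#' censored at the last simulated time. Event-time resolution is the
#' sampling grid.
#'
#' @param trajectories a `vegf_trial` or long table with columns
#'   `mouse_id`, `arm`, `day`, `volume_cm3`.
#' @param cutoff sacrifice volume (cm^3).
#' @return data.frame `mouse_id`, `time_days`, `status`, `group` (the
#'   arm).
#' @export
derive_survival <- function(trajectories, cutoff = 2) {
  if (inherits(trajectories, "vegf_trial"))
    trajectories <- trajectories$trajectories
  if (is.null(trajectories) || !nrow(trajectories))
    .domain_error("empty trajectory table")
  key <- interaction(trajectories$mouse_id, trajectories$arm, drop = TRUE)
  recs <- lapply(split(trajectories, key), function(d) {
    d <- d[order(d$day), ]
    hit <- which(d$volume_cm3 >= cutoff)
    if (length(hit))
      data.frame(mouse_id = d$mouse_id[1], time_days = d$day[hit[1]],
                 status = "event", group = d$arm[1],
                 stringsAsFactors = FALSE)
    else
      data.frame(mouse_id = d$mouse_id[1], time_days = max(d$day),
                 status = "censored", group = d$arm[1],
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(out$group, out$mouse_id), ]
}

## pooled risk table at the distinct event times of two groups; exact
## integer accounting (no floating-point fuzz): censored-at-event-time
## subjects count as at risk for that event time
.risk_table <- function(ta, ea, tb, eb) {
  all_t <- sort(unique(c(ta, tb)))
  cnt_a <- tabulate(match(ta, all_t), nbins = length(all_t))
  cnt_b <- tabulate(match(tb, all_t), nbins = length(all_t))
  atrisk_a <- rev(cumsum(rev(cnt_a)))
  atrisk_b <- rev(cumsum(rev(cnt_b)))
  d_a <- tabulate(match(ta[ea], all_t), nbins = length(all_t))
  d_b <- tabulate(match(tb[eb], all_t), nbins = length(all_t))
  ev <- (d_a + d_b) > 0
  list(time = all_t[ev], n1 = atrisk_a[ev], n2 = atrisk_b[ev],
       d1 = d_a[ev], d2 = d_b[ev])
}

.split_records <- function(records) {
  list(time = records$time_days, event = records$status == "event")
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#'
#' @param records survival records (see [surv_records()]); group labels
#'   are ignored (estimate one group at a time).
#' @return object of class `km_curve`: data.frame `time`, `n_risk`,
#'   `n_event`, `survival` (rows at distinct event times), with
#'   attributes `n` (subjects) and `max_time`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) .domain_error("no survival records")
  t <- records$time_days
  ev <- records$status == "event"
  all_t <- sort(unique(t))
  cnt <- tabulate(match(t, all_t), nbins = length(all_t))
  atrisk <- rev(cumsum(rev(cnt)))
  d <- tabulate(match(t[ev], all_t), nbins = length(all_t))
  keep <- d > 0
  s <- cumprod(1 - d[keep] / atrisk[keep])
  structure(data.frame(time = all_t[keep], n_risk = atrisk[keep],
                       n_event = d[keep], survival = s),
            n = nrow(records), max_time = max(t), class = c("km_curve",
                                                            "data.frame"))
}

#' Median survival of a Kaplan-Meier curve
#'
#' The smallest time at which the survival estimate falls below 0.5.
#' If the estimate lands exactly on 0.5 and stays there over an
#' interval before dropping, the midpoint of that interval is returned
#' (hence half-day medians on a daily grid). `NA` when the estimate
#' never reaches below 50%: the median survival cannot be estimated.
#'
#' @param curve a `km_curve`.
#' @return days, or `NA` (undefined).
#' @export
median_survival <- function(curve) {
  eps <- 1e-12
  below <- which(curve$survival < 0.5 - eps)
  at <- which(abs(curve$survival - 0.5) <= eps)
  if (length(at)) {
    t_at <- curve$time[at[1]]
    if (length(below)) return((t_at + curve$time[below[1]]) / 2)
    return(NA_real_)
  }
  if (length(below)) return(curve$time[below[1]])
  NA_real_
}

#' Mantel-Cox log-rank test
#'
#' Accumulates observed-minus-expected events over the distinct event
#' times of the two groups; the statistic is chi-squared with 1 df,
#' two-sided p. Zero events overall gives p = 1 by convention.
#'
#' @param a,b survival records for the two groups.
#' @return list `statistic`, `p_value`, `observed` (group a events),
#'   `expected` (group a expectation), `o_minus_e`, `var`.
#' @export
logrank_test <- function(a, b) {
  if (!nrow(a) || !nrow(b)) .domain_error("both groups must be nonempty")
  sa <- .split_records(a); sb <- .split_records(b)
  rt <- .risk_table(sa$time, sa$event, sb$time, sb$event)
  if (!length(rt$time))
    return(list(statistic = 0, p_value = 1, observed = 0, expected = 0,
                o_minus_e = 0, var = 0))
  n <- rt$n1 + rt$n2
  d <- rt$d1 + rt$d2
  e1 <- d * rt$n1 / n
  v <- ifelse(n > 1, d * (rt$n1 / n) * (rt$n2 / n) * (n - d) / (n - 1), 0)
  oe <- sum(rt$d1 - e1)
  vs <- sum(v)
  if (vs <= 0)
    return(list(statistic = 0, p_value = 1, observed = sum(rt$d1),
                expected = sum(e1), o_minus_e = oe, var = 0))
  stat <- oe^2 / vs
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sum(rt$d1), expected = sum(e1), o_minus_e = oe, var = vs)
}

#' Mantel-Haenszel hazard ratio with 95% confidence interval
#'
#' Stratifies the comparison over the distinct event times (one 2x2
#' table per event time: events vs at-risk-minus-events by group) and
#' combines them with the Mantel-Haenszel estimator
#' `sum(d1 (n2 - d2) / n) / sum(d2 (n1 - d1) / n)`, which is consistent
#' for the common hazard ratio under proportional hazards. The
#' confidence interval is `exp(log HR +/- 1.96 SE)` with the
#' Robins-Breslow-Greenland variance for the log MH estimate. An HR
#' below one means the first group has the lower death rate. The
#' p-value reported alongside is the Mantel-Cox log-rank p.
#'
#' @param a,b survival records for the two groups (a relative to b).
#' @param conf_level confidence level.
#' @return list `hr`, `ci_lower`, `ci_upper`, `se_log_hr`, `p_value`,
#'   `undefined` (TRUE when a group has no events so the ratio is 0 or
#'   infinite).
#' @export
hazard_ratio_mh <- function(a, b, conf_level = 0.95) {
  if (!nrow(a) || !nrow(b)) .domain_error("both groups must be nonempty")
  sa <- .split_records(a); sb <- .split_records(b)
  rt <- .risk_table(sa$time, sa$event, sb$time, sb$event)
  lr <- logrank_test(a, b)
  if (!length(rt$time))
    return(list(hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                se_log_hr = NA_real_, p_value = 1, undefined = TRUE))
  n <- rt$n1 + rt$n2
  aa <- rt$d1; bb <- rt$n1 - rt$d1; cc <- rt$d2; dd <- rt$n2 - rt$d2
  R <- aa * dd / n; S <- bb * cc / n
  sR <- sum(R); sS <- sum(S)
  if (sR == 0 || sS == 0) {
    hr <- if (sS == 0 && sR > 0) Inf else 0
    return(list(hr = hr, ci_lower = NA_real_, ci_upper = NA_real_,
                se_log_hr = NA_real_, p_value = lr$p_value,
                undefined = TRUE))
  }
  hr <- sR / sS
  P <- (aa + dd) / n; Q <- (bb + cc) / n
  v <- sum(P * R) / (2 * sR^2) + sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(hr = hr, ci_lower = hr * exp(-z * sqrt(v)),
       ci_upper = hr * exp(z * sqrt(v)), se_log_hr = sqrt(v),
       p_value = lr$p_value, undefined = FALSE)
}

#' Two-group survival comparison
#'
#' Log-rank test plus Mantel-Haenszel hazard ratio, in the shape used
#' by the comparison tables (label, HR, CI bounds, p).
#'
#' @param a,b survival records.
#' @param label comparison label.
#' @return one-row data.frame `comparison`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n_a`, `n_b`.
#' @export
survival_comparison <- function(a, b, label = "a vs b") {
  mh <- hazard_ratio_mh(a, b)
  data.frame(comparison = label, hr = mh$hr, ci_lower = mh$ci_lower,
             ci_upper = mh$ci_upper, p_value = mh$p_value,
             n_a = nrow(a), n_b = nrow(b), stringsAsFactors = FALSE)
}
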