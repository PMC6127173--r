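## threshold_discovery: biomarker sweep over growth kinetic parameters -----

#' Sweep candidate threshold values for a growth kinetic parameter
#'
#' Every observed value of the selected parameter (k0, k1, or the k0/k1
#' ratio) is tested as a split point: the chosen arm is divided into
#' mice with the parameter above vs below the candidate, the two
#' subgroups' survival is compared with the Mantel-Cox log-rank test,
#' and the p-value and direction of benefit are recorded. Candidates
#' leaving fewer than `min_group_size` mice on either side are skipped.
#'
#' @param records survival records carrying per-mouse parameters:
#'   data.frame with columns `mouse_id`, `time_days`, `status`, `group`,
#'   `k0`, `k1`. A `vegf_trial` may be given instead, in which case
#'   records are derived with [derive_survival()] (cutoff 2 cm^3) and
#'   joined to its parameters.
#' @param selector `"ratio"` (k0/k1), `"k0"` or `"k1"`.
#' @param alpha significance level for the split.
#' @param min_group_size smallest admissible subgroup.
#' @param arm which arm to sweep (`"treated"` by default; `"control"`
#'   or `"all"` are available).
#' @return object of class `threshold_scan`: data.frame `candidate`,
#'   `p_value`, `n_above`, `n_below`, `direction` (`"above"` or
#'   `"below"`: which side survives longer), `significant`, `skipped`;
#'   attributes `selector`, `alpha`.
#' @export
threshold_scan <- function(records, selector = c("ratio", "k0", "k1"),
                           alpha = 0.05, min_group_size = 10,
                           arm = "treated") {
  selector <- match.arg(selector)
  records <- .records_with_params(records, arm)
  param <- switch(selector,
                  ratio = records$k0 / records$k1,
                  k0 = records$k0,
                  k1 = records$k1)
  if (nrow(records) < 2 * min_group_size)
    .domain_error("need at least %d mice for the sweep", 2 * min_group_size)
  cand <- sort(unique(param))
  time <- records$time_days
  ev <- records$status == "event"
  res <- lapply(cand, function(cv) {
    above <- param > cv; below <- param < cv
    if (sum(above) < min_group_size || sum(below) < min_group_size)
      return(data.frame(candidate = cv, p_value = NA_real_,
                        n_above = sum(above), n_below = sum(below),
                        direction = NA_character_, significant = FALSE,
                        skipped = TRUE))
    lr <- .logrank_raw(time[above], ev[above], time[below], ev[below])
    data.frame(candidate = cv, p_value = lr$p_value,
               n_above = sum(above), n_below = sum(below),
               direction = if (lr$o_minus_e < 0) "above" else "below",
               significant = lr$p_value < alpha, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), selector = selector, alpha = alpha,
            class = c("threshold_scan", "data.frame"))
}

## log-rank on raw vectors (no data.frame assembly; the sweep calls this
## hundreds of times per population)
.logrank_raw <- function(ta, ea, tb, eb) {
  rt <- .risk_table(ta, ea, tb, eb)
  if (!length(rt$time))
    return(list(p_value = 1, o_minus_e = 0))
  n <- rt$n1 + rt$n2
  d <- rt$d1 + rt$d2
  e1 <- d * rt$n1 / n
  v <- ifelse(n > 1, d * (rt$n1 / n) * (rt$n2 / n) * (n - d) / (n - 1), 0)
  oe <- sum(rt$d1 - e1); vs <- sum(v)
  if (vs <= 0) return(list(p_value = 1, o_minus_e = oe))
  list(p_value = pchisq(oe^2 / vs, df = 1, lower.tail = FALSE),
       o_minus_e = oe)
}

.records_with_params <- function(records, arm = "treated") {
  if (inherits(records, "vegf_trial")) {
    recs <- derive_survival(records)
    recs <- merge(recs, records$params[, c("mouse_id", "k0", "k1")],
                  by = "mouse_id")
    records <- recs
  }
  need <- c("time_days", "status", "k0", "k1")
  if (!all(need %in% names(records)))
    .schema_error("records need columns: %s", paste(need, collapse = ", "))
  if (arm != "all" && "group" %in% names(records))
    records <- records[records$group == arm, , drop = FALSE]
  records
}

#' Valid threshold range(s) of a scan
#'
#' Collects the contiguous runs of significant candidates with a
#' consistent direction of benefit. Each run is reported as an interval
#' of threshold values; the maximal (widest) interval is flagged
#' primary. An empty result (no significant candidate) is a valid
#' output.
#'
#' @param scan a [threshold_scan()].
#' @return object of class `threshold_range`: data.frame `low`, `high`,
#'   `n_candidates`, `direction`, `primary`; zero rows when no
#'   candidate splits the population.
#' @export
valid_range <- function(scan) {
  ok <- !scan$skipped
  s <- scan[ok, , drop = FALSE]
  runs <- list()
  i <- 1
  while (i <= nrow(s)) {
    if (s$significant[i]) {
      j <- i
      while (j + 1 <= nrow(s) && s$significant[j + 1] &&
             s$direction[j + 1] == s$direction[i]) j <- j + 1
      runs[[length(runs) + 1]] <-
        data.frame(low = s$candidate[i], high = s$candidate[j],
                   n_candidates = j - i + 1, direction = s$direction[i],
                   stringsAsFactors = FALSE)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) {
    out <- data.frame(low = numeric(0), high = numeric(0),
                      n_candidates = integer(0), direction = character(0),
                      primary = logical(0))
  } else {
    out <- do.call(rbind, runs)
    span <- out$high - out$low
    out$primary <- seq_len(nrow(out)) == which.max(span)
  }
  structure(out, selector = attr(scan, "selector"),
            class = c("threshold_range", "data.frame"))
}

#' Intersection of per-case threshold ranges
#'
#' The common range across cases is the interval intersection of each
#' case's primary valid interval; its median is the midpoint of the
#' intersection endpoints. An empty intersection (or any empty input
#' range) is signalled via `empty = TRUE`.
#'
#' @param ranges list of `threshold_range` objects (or plain
#'   length-2 numeric `c(low, high)` intervals).
#' @return list `low`, `high`, `median`, `empty`.
#' @export
common_range <- function(ranges) {
  if (!length(ranges)) .domain_error("need at least one range")
  iv <- lapply(ranges, function(r) {
    if (is.numeric(r) && length(r) == 2) return(as.numeric(r))
    if (inherits(r, "data.frame")) {
      if (!nrow(r)) return(NULL)
      p <- if ("primary" %in% names(r)) which(r$primary)[1] else 1
      return(c(r$low[p], r$high[p]))
    }
    .domain_error("unrecognized range input")
  })
  if (any(vapply(iv, is.null, TRUE)))
    return(list(low = NA_real_, high = NA_real_, median = NA_real_,
                empty = TRUE))
  lo <- max(vapply(iv, `[`, 0, 1))
  hi <- min(vapply(iv, `[`, 0, 2))
  if (lo > hi)
    return(list(low = NA_real_, high = NA_real_, median = NA_real_,
                empty = TRUE))
  list(low = lo, high = hi, median = (lo + hi) / 2, empty = FALSE)
}

#' Six-group stratified survival comparison
#'
#' Splits a paired trial at a threshold of the selected parameter into
#' six groups -- control (all), treated (all), and control/treated with
#' the parameter below/above the threshold -- and returns their
#' Kaplan-Meier curves, median survivals, and the pairwise hazard-ratio
#' / log-rank comparison table. Comparisons involving an empty stratum
#' are marked unavailable.
#'
#' @param trial a `vegf_trial` (or records with parameters and both
#'   groups, columns as in [threshold_scan()]).
#' @param threshold split value.
#' @param selector `"ratio"`, `"k0"` or `"k1"`.
#' @param cutoff sacrifice volume for [derive_survival()].
#' @return list `groups` (named list of records), `curves` (named list
#'   of `km_curve`), `medians` (data.frame), `comparisons` (data.frame).
#' @export
stratify_and_compare <- function(trial, threshold,
                                 selector = c("ratio", "k0", "k1"),
                                 cutoff = 2) {
  selector <- match.arg(selector)
  recs <- .records_with_params(trial, arm = "all")
  param <- switch(selector, ratio = recs$k0 / recs$k1, k0 = recs$k0,
                  k1 = recs$k1)
  if (threshold < min(param) || threshold > max(param))
    warning("threshold outside the observed parameter span")
  groups <- list(
    control_all = recs[recs$group == "control", ],
    treated_all = recs[recs$group == "treated", ],
    control_below = recs[recs$group == "control" & param < threshold, ],
    control_above = recs[recs$group == "control" & param > threshold, ],
    treated_below = recs[recs$group == "treated" & param < threshold, ],
    treated_above = recs[recs$group == "treated" & param > threshold, ])
  curves <- lapply(groups, function(g) if (nrow(g)) km_estimate(g) else NULL)
  medians <- data.frame(
    group = names(groups),
    n = vapply(groups, nrow, 0L),
    median_days = vapply(curves, function(cv)
      if (is.null(cv)) NA_real_ else median_survival(cv), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- list(
    c("treated_above", "treated_below"),
    c("control_above", "control_below"),
    c("treated_above", "control_above"),
    c("treated_above", "treated_all"),
    c("treated_all", "control_all"),
    c("treated_below", "treated_all"))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    ga <- groups[[pr[1]]]; gb <- groups[[pr[2]]]
    lab <- paste(pr[1], "vs", pr[2])
    if (!nrow(ga) || !nrow(gb))
      return(data.frame(comparison = lab, hr = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p_value = NA_real_, n_a = nrow(ga), n_b = nrow(gb),
                        available = FALSE, stringsAsFactors = FALSE))
    cbind(survival_comparison(ga, gb, lab), available = TRUE)
  }))
  list(groups = groups, curves = curves, medians = medians,
       comparisons = comparisons, threshold = threshold,
       selector = selector)
}
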