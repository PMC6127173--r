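.step_records <- function(n = 120, r_star = 13, seed = 1) {
  # survival time is a deterministic step function of the k0/k1 ratio
  set.seed(seed)
  k0 <- runif(n, 5e-6, 1.5e-5)
  k1 <- runif(n, 3e-7, 7e-7)
  ratio <- k0 / k1
  time <- ifelse(ratio > r_star, 80, 20) + runif(n, 0, 0.5)
  cbind(surv_records(time, rep(TRUE, n), group = "treated"),
        k0 = k0, k1 = k1)
}

test_that("the sweep localizes a planted survival step", {
  rec <- .step_records(r_star = 13)
  scan <- threshold_scan(rec, "ratio")
  vr <- valid_range(scan)
  expect_gt(nrow(vr), 0)
  prim <- vr[which(vr$primary), ]
  expect_lte(prim$low, 13)
  expect_gte(prim$high, 13)
  expect_identical(prim$direction, "above")  # larger ratio survives longer
  # candidates immediately around the step are significant
  near <- scan[!scan$skipped & abs(scan$candidate - 13) < 1, ]
  expect_true(all(near$significant))
})

test_that("null populations yield no wide stable interval", {
  wide <- 0
  for (s in 1:25) {
    pop <- gen_planted_threshold_population(n = 300, hazard_low = 0.04,
                                            hazard_high = 0.04, seed = s)
    scan <- threshold_scan(pop, "ratio")
    vr <- valid_range(scan)
    w <- if (nrow(vr)) max(vr$n_candidates) / sum(!scan$skipped) else 0
    if (w > 0.2) wide <- wide + 1
  }
  expect_lte(wide, 2)  # individual alpha-level false positives are expected
})

test_that("valid_range collects islands and flags the maximal one", {
  scan <- structure(
    data.frame(candidate = 1:10,
               p_value = c(0.5, 0.01, 0.02, 0.5, 0.01, 0.01, 0.01, 0.04,
                           0.5, 0.5),
               n_above = 50, n_below = 50,
               direction = "above",
               significant = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                               TRUE, FALSE, FALSE),
               skipped = FALSE),
    selector = "ratio", alpha = 0.05,
    class = c("threshold_scan", "data.frame"))
  vr <- valid_range(scan)
  expect_equal(nrow(vr), 2)
  expect_equal(vr$low, c(2, 5))
  expect_equal(vr$high, c(3, 8))
  expect_equal(vr$primary, c(FALSE, TRUE))

  scan$significant <- FALSE
  expect_equal(nrow(valid_range(scan)), 0)

  # a direction flip breaks a run
  scan$significant <- TRUE
  scan$direction <- c(rep("above", 5), rep("below", 5))
  vr2 <- valid_range(scan)
  expect_equal(nrow(vr2), 2)
})

test_that("common range intersects cases and takes the midpoint median", {
  cr <- common_range(list(c(1.391e-6, 1.931e-6)))
  expect_identical(cr$median, (1.391e-6 + 1.931e-6) / 2)
  expect_equal(cr$median, 1.661e-6)

  cr2 <- common_range(list(c(5, 20), c(9.757, 25), c(8, 17.982)))
  expect_equal(c(cr2$low, cr2$high), c(9.757, 17.982))
  expect_equal(cr2$median, 13.8695)

  expect_true(common_range(list(c(1, 2), c(3, 4)))$empty)
  empty_rng <- structure(
    data.frame(low = numeric(0), high = numeric(0),
               n_candidates = integer(0), direction = character(0),
               primary = logical(0)),
    class = c("threshold_range", "data.frame"))
  expect_true(common_range(list(c(1, 5), empty_rng))$empty)
})

test_that("sweeping the reciprocal parameter mirrors the valid range", {
  rec <- .step_records(r_star = 13, seed = 4)
  scan_f <- threshold_scan(rec, "ratio")
  swapped <- rec
  swapped$k0 <- rec$k1; swapped$k1 <- rec$k0  # parameter becomes k1/k0
  scan_r <- threshold_scan(swapped, "ratio")
  vf <- valid_range(scan_f); vrv <- valid_range(scan_r)
  pf <- vf[which(vf$primary), ]; pr <- vrv[which(vrv$primary), ]
  expect_equal(pf$low, 1 / pr$high, tolerance = 1e-9)
  expect_equal(pf$high, 1 / pr$low, tolerance = 1e-9)
  expect_false(pf$direction == pr$direction)
})

test_that("k1 sweeps point at smaller-k1 benefit when large k1 kills early", {
  set.seed(9)
  n <- 120
  k0 <- runif(n, 5e-6, 1.5e-5)
  k1 <- runif(n, 3e-7, 7e-7)
  time <- ifelse(k1 < 5e-7, 80, 25) + runif(n)
  rec <- cbind(surv_records(time, rep(TRUE, n), group = "treated"),
               k0 = k0, k1 = k1)
  scan <- threshold_scan(rec, "k1")
  vr <- valid_range(scan)
  prim <- vr[which(vr$primary), ]
  expect_identical(prim$direction, "below")
  expect_lte(prim$low, 5e-7)
  expect_gte(prim$high, 5e-7)
})

test_that("six-group stratification mirrors the comparison table layout", {
  rec <- .step_records(n = 160, r_star = 13, seed = 6)
  ctrl <- rec
  ctrl$group <- "control"
  ctrl$time_days <- pmax(ctrl$time_days - 10, 1)
  both <- rbind(rec, ctrl)
  sac <- stratify_and_compare(both, 13, "ratio")
  expect_setequal(names(sac$groups),
                  c("control_all", "treated_all", "control_below",
                    "control_above", "treated_below", "treated_above"))
  expect_equal(nrow(sac$comparisons), 6)
  hr_ab <- sac$comparisons$hr[
    sac$comparisons$comparison == "treated_above vs treated_below"]
  expect_lt(hr_ab, 1)

  # threshold below every observed ratio: below strata empty, flagged
  expect_warning(sac2 <- stratify_and_compare(both, 1, "ratio"),
                 "outside")
  expect_equal(nrow(sac2$groups$treated_below), 0)
  expect_false(all(sac2$comparisons$available))
})

test_that("sweep guards inputs", {
  rec <- .step_records(n = 30)
  expect_error(threshold_scan(rec, "ratio", min_group_size = 20),
               class = "angiotrial_domain_error")
  expect_error(threshold_scan(rec[, -5], "ratio"),
               class = "angiotrial_schema_error")
})
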