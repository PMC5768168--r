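make_log <- function(times, tag = "A", receiver = "R1",
                     origin = as.POSIXct("2020-06-01", tz = "UTC")) {
  data.frame(timestamp = origin + times, receiver = receiver,
             transmitter = tag)
}

test_that("hourly counts bin, zero-fill and join distances", {
  origin <- as.POSIXct("2020-06-01", tz = "UTC")
  log <- make_log(c(10, 600, 3000, 7300))
  hc <- hourly_counts(log, c(A = 100))
  expect_equal(hc$detections, c(3L, 0L, 1L))
  expect_equal(hc$distance, rep(100, 3))
  expect_equal(hc$hour, origin + c(0, 3600, 7200))
  # a ten-day window yields 240 hourly rows per pair
  hc10 <- hourly_counts(log, c(A = 100),
                        window = c(origin, origin + 10 * 86400))
  expect_equal(nrow(hc10), 240L)
  expect_equal(sum(hc10$detections), 4L)
  expect_error(hourly_counts(make_log(1, tag = "B"), c(A = 100)),
               "B")
})

test_that("covariates join onto the hourly grid", {
  origin <- as.POSIXct("2020-06-01", tz = "UTC")
  log <- make_log(c(10, 4000))
  cov <- data.frame(hour = origin + c(0, 3600), wind = c(5, 9))
  hc <- hourly_counts(log, c(A = 50), covariates = cov)
  expect_equal(hc$wind, c(5, 9))
})

test_that("detection-function fitting recovers a known decay curve", {
  # Poisson counts straight from a monotone logistic decay
  set.seed(21)
  dists <- seq(0, 900, by = 100)
  rate <- 30 * plogis((600 - dists) / 80)
  counts <- data.frame(
    distance = rep(dists, each = 150),
    detections = rpois(150 * length(dists), rep(rate, each = 150)))
  fits <- fit_detection_function(counts)
  expect_s3_class(fits, "detection_fit_list")
  f <- fits[[1]]
  at <- match(dists, f$predictions$distance)
  mid <- rate > 1.5                     # compare away from the near-zero tail
  expect_true(all(abs(f$predictions$fit[at][mid] - rate[mid]) /
                    rate[mid] < 0.10))
  # monotone truth: no interior maximum, extent 0
  expect_equal(estimate_cpdi_extent(f), 0)
})

test_that("a suppressed near field produces an interior maximum", {
  set.seed(22)
  dists <- seq(0, 900, by = 75)
  rate <- 30 * plogis((600 - dists) / 80) *
    (1 - 0.9 * plogis((150 - dists) / 60))
  counts <- data.frame(
    distance = rep(dists, each = 120),
    detections = rpois(120 * length(dists), rep(rate, each = 120)))
  f <- fit_detection_function(counts)[[1]]
  imax <- which.max(f$predictions$fit)
  expect_gt(f$predictions$distance[imax], 100)
  expect_gt(estimate_cpdi_extent(f), 0)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_detection_function(
    data.frame(distance = rep(5, 10), detections = rpois(10, 3))),
    "distinct distances")
  expect_error(fit_detection_function(
    data.frame(distance = rep(c(0, 100), 5), detections = 0L)),
    "no detections")
  expect_error(fit_detection_function(
    data.frame(distance = c(0, 100), detections = c(-1L, 2L))),
    "non-negative")
})

test_that("the AMDR threshold rule and crossing logic hold", {
  expect_equal(amdr_threshold_rate(60), 3)
  expect_equal(amdr_threshold_rate(120), 1.5)
  expect_equal(amdr_threshold_rate(60, 0.10), 6)
  # constant prediction below threshold: AMDR at the first grid distance
  flat <- structure(list(list(
    id = "m1", covariates = character(0), aic = 0, delta_aic = 0,
    candidate = TRUE,
    predictions = data.frame(distance = 0:500, fit = 2.9, se = 0.1))),
    class = "detection_fit_list")
  est <- estimate_amdr(flat)
  expect_equal(est$point, 0)
  expect_equal(est$threshold, 3)
  # a decaying curve: higher threshold fraction gives smaller AMDR
  dec <- structure(list(list(
    id = "m1", covariates = character(0), aic = 0, delta_aic = 0,
    candidate = TRUE,
    predictions = data.frame(distance = 0:1000,
                             fit = 30 * plogis((600 - 0:1000) / 80),
                             se = 0.2))),
    class = "detection_fit_list")
  a05 <- estimate_amdr(dec, threshold_fraction = 0.05)$point
  a10 <- estimate_amdr(dec, threshold_fraction = 0.10)$point
  a02 <- estimate_amdr(dec, threshold_fraction = 0.02)$point
  expect_lte(a10, a05)
  expect_lte(a05, a02)
  expect_true(estimate_amdr(flat, threshold_fraction = 0.001)$censored)
  # the +/- 1 SE band brackets the point estimate
  e <- estimate_amdr(dec)
  expect_lte(e$low, e$point)
  expect_lte(e$point, e$high)
})

test_that("an interference trough is not mistaken for the AMDR", {
  # curve dips below threshold near the receiver, recovers, then decays
  d <- 0:1000
  fit <- 25 * plogis((600 - d) / 80) * (1 - 0.95 * plogis((200 - d) / 50))
  obj <- structure(list(list(
    id = "m1", covariates = character(0), aic = 0, delta_aic = 0,
    candidate = TRUE,
    predictions = data.frame(distance = d, fit = fit, se = 0.2))),
    class = "detection_fit_list")
  est <- estimate_amdr(obj)
  expect_gt(est$point, 500)
})

test_that("receiver metrics reproduce the meta-log arithmetic", {
  # perfect receiver: every sync becomes a detection, nothing rejected
  d0 <- data.frame(date = as.Date("2015-03-18"), detections = 1355,
                   syncs = 1355, pings = 10844, checksum_rejects = 0)
  m0 <- receiver_metrics(d0)
  expect_equal(m0$per_day$cde, 1)
  expect_equal(m0$per_day$rc, 0)
  # interference-affected receiver: many pings, few decoded trains
  d1 <- data.frame(date = as.Date("2015-03-18"), detections = 316.5,
                   syncs = 3658, pings = 11777.5, checksum_rejects = 50)
  m1 <- receiver_metrics(d1)
  expect_equal(m1$per_day$adjusted_cde, 316.5 / (11777.5 / 8),
               tolerance = 1e-12)
  expect_equal(round(m1$per_day$adjusted_cde, 3), 0.215)
  d2 <- data.frame(date = as.Date("2015-03-18"), detections = 100,
                   syncs = 400, pings = 800, checksum_rejects = 11)
  expect_equal(receiver_metrics(d2)$per_day$adjusted_rc, 0.110)
  # metrics are scale-free in the counts
  d3 <- d2
  d3[, -1] <- d3[, -1] * 7
  expect_equal(receiver_metrics(d3)$per_day[, c("cde", "rc",
                                                "adjusted_cde",
                                                "adjusted_rc")],
               receiver_metrics(d2)$per_day[, c("cde", "rc",
                                                "adjusted_cde",
                                                "adjusted_rc")])
})

test_that("zero-denominator days are excluded from medians", {
  d <- data.frame(date = as.Date("2015-03-18") + 0:2,
                  detections = c(0, 10, 20), syncs = c(0, 20, 40),
                  pings = c(0, 160, 320), checksum_rejects = c(0, 2, 4))
  m <- receiver_metrics(d)
  expect_true(is.na(m$per_day$cde[1]))
  expect_equal(unname(m$median["cde"]), 0.5)
  expect_error(receiver_metrics(
    data.frame(date = Sys.Date(), detections = -1, syncs = 5, pings = 50,
               checksum_rejects = 0)), "non-negative")
  expect_error(receiver_metrics(
    data.frame(date = Sys.Date(), detections = 10, syncs = 5, pings = 50,
               checksum_rejects = 0)), "invariant")
})
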