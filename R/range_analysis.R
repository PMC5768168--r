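# Detection-function estimation from range-test logs.
#
# Hourly detection counts per tag-receiver pair are modelled with a
# Poisson penalized-spline regression of counts on distance (basis
# dimension 6, chosen small enough that the sparse near-receiver region
# is not swamped by the far field). All subsets of the offered covariates
# are fitted; models within two AIC units of the best form the candidate
# set, and headline estimates are medians across candidates.

#' Aggregate a detection log into zero-filled hourly counts
#'
#' @param log A detection-log data frame with columns `timestamp`
#'   (POSIXct, UTC), `receiver`, `transmitter` (see [read_vue_csv()]).
#' @param tag_distances Data frame with columns `tag_id`, `distance_m`
#'   (or a named numeric vector, names = tag ids). Every transmitter in
#'   the log must have a distance.
#' @param covariates Optional data frame keyed by an `hour` POSIXct
#'   column, joined onto the counts.
#' @param window Optional POSIXct length-2 deployment window; hours are
#'   zero-filled over `[window[1], window[2])`. Defaults to the log's
#'   span, floored/ceiled to whole UTC hours.
#'
#' @return Data frame with one row per (receiver, tag, hour):
#'   `receiver`, `tag`, `distance`, `hour` (POSIXct UTC), `detections`,
#'   plus any covariate columns.
#' @export
hourly_counts <- function(log, tag_distances, covariates = NULL,
                          window = NULL) {
  stopifnot(is.data.frame(log),
            all(c("timestamp", "receiver", "transmitter") %in% names(log)))
  if (is.numeric(tag_distances) && !is.null(names(tag_distances)))
    tag_distances <- data.frame(tag_id = names(tag_distances),
                                distance_m = unname(tag_distances))
  stopifnot(all(c("tag_id", "distance_m") %in% names(tag_distances)))
  unknown <- setdiff(unique(log$transmitter), tag_distances$tag_id)
  if (length(unknown))
    stop("no distance given for tag(s): ", paste(unknown, collapse = ", "))
  if (is.null(window)) {
    span <- range(log$timestamp)
    window <- c(as.POSIXct(trunc(span[1], "hours")),
                as.POSIXct(trunc(span[2], "hours")) + 3600)
  }
  hours <- seq(from = as.POSIXct(window[1], tz = "UTC"),
               to = as.POSIXct(window[2], tz = "UTC") - 1,
               by = 3600)
  grid <- expand.grid(hour = hours,
                      tag = tag_distances$tag_id,
                      receiver = unique(log$receiver),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(rec, tag, hr) paste(rec, tag, format(hr, "%Y%m%d%H"))
  cnt <- table(key(log$receiver, log$transmitter,
                   trunc(log$timestamp, "hours")))
  k <- key(grid$receiver, grid$tag, grid$hour)
  grid$detections <- as.integer(ifelse(k %in% names(cnt), cnt[k], 0L))
  grid$distance <- tag_distances$distance_m[
    match(grid$tag, tag_distances$tag_id)]
  out <- grid[, c("receiver", "tag", "distance", "hour", "detections")]
  if (!is.null(covariates)) {
    stopifnot("hour" %in% names(covariates))
    out <- merge(out, covariates, by = "hour", all.x = TRUE, sort = FALSE)
    out <- out[, c("receiver", "tag", "distance", "hour", "detections",
                   setdiff(names(covariates), "hour"))]
  }
  out <- out[order(out$receiver, out$tag, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit candidate detection functions to hourly counts
#'
#' Fits `detections ~ s(distance, k = basis_dim)` Poisson GAMs for every
#' subset of the offered covariates (plus an optional ridge random
#' effect), computes AIC for each, and marks the candidate set: all
#' models within two AIC units of the best. Predictions with standard
#' errors are made on a 1 m distance grid, holding numeric covariates at
#' their median and factors at their most frequent level.
#'
#' @param counts Output of [hourly_counts()] (or [generate_range_test()]).
#' @param basis_dim Spline basis dimension for the distance smoother
#'   (default 6).
#' @param covariates Character vector of covariate column names to offer;
#'   default none.
#' @param group Optional column name (e.g. `"tag"`) entered as a ridge
#'   random effect in every model and excluded from predictions.
#' @param aic_window Candidate models lie within this many AIC units of
#'   the best fit (default 2).
#' @param grid_by Prediction grid spacing in metres (default 1).
#'
#' @return Object of class `detection_fit_list`: a list of fits, each
#'   with `id`, `covariates`, `aic`, `delta_aic`, `candidate` and a
#'   `predictions` data frame (`distance`, `fit`, `se`). Attributes
#'   record the threshold context.
#' @export
fit_detection_function <- function(counts, basis_dim = 6,
                                   covariates = character(0),
                                   group = NULL, aic_window = 2,
                                   grid_by = 1) {
  stopifnot(is.data.frame(counts),
            all(c("distance", "detections") %in% names(counts)))
  if (any(counts$detections < 0) ||
      any(counts$detections != round(counts$detections)))
    stop("`detections` must be non-negative integer counts")
  if (length(unique(counts$distance)) < 2L)
    stop("need counts at two or more distinct distances to fit a ",
         "detection function")
  if (all(counts$detections == 0L))
    stop("all counts are zero: no detections to model")
  stopifnot(all(covariates %in% names(counts)))
  if (!is.null(group)) {
    stopifnot(group %in% names(counts))
    counts[[group]] <- factor(counts[[group]])
  }

  dist_grid <- seq(0, max(counts$distance), by = grid_by)
  newdata <- data.frame(distance = dist_grid)
  for (cv in covariates) {
    v <- counts[[cv]]
    newdata[[cv]] <- if (is.numeric(v)) stats::median(v, na.rm = TRUE)
      else {
        f <- factor(v)
        factor(names(which.max(table(f))), levels = levels(f))
      }
  }
  if (!is.null(group))
    newdata[[group]] <- factor(levels(counts[[group]])[1],
                               levels = levels(counts[[group]]))

  subsets <- if (length(covariates) == 0L) list(character(0)) else {
    idx <- expand.grid(rep(list(c(FALSE, TRUE)), length(covariates)))
    lapply(seq_len(nrow(idx)),
           function(i) covariates[unlist(idx[i, ])])
  }

  fits <- lapply(seq_along(subsets), function(i) {
    cvs <- subsets[[i]]
    rhs <- sprintf("s(distance, k = %d)", basis_dim)
    if (length(cvs)) rhs <- paste(c(rhs, cvs), collapse = " + ")
    excl <- NULL
    if (!is.null(group)) {
      rhs <- paste0(rhs, " + s(", group, ", bs = \"re\")")
      excl <- sprintf("s(%s)", group)
    }
    fml <- stats::as.formula(paste("detections ~", rhs))
    fit <- mgcv::gam(fml, family = stats::poisson(), data = counts,
                     method = "REML")
    pr <- mgcv::predict.gam(fit, newdata = newdata, type = "response",
                            se.fit = TRUE, exclude = excl,
                            newdata.guaranteed = TRUE)
    list(id = paste0("m", i),
         covariates = cvs,
         aic = stats::AIC(fit),
         predictions = data.frame(distance = dist_grid,
                                  fit = as.numeric(pr$fit),
                                  se = as.numeric(pr$se.fit)))
  })
  best <- min(vapply(fits, `[[`, numeric(1), "aic"))
  for (i in seq_along(fits)) {
    fits[[i]]$delta_aic <- fits[[i]]$aic - best
    fits[[i]]$candidate <- fits[[i]]$delta_aic <= aic_window
  }
  structure(fits, class = "detection_fit_list",
            basis_dim = basis_dim, aic_window = aic_window)
}

#' @export
print.detection_fit_list <- function(x, ...) {
  cat("<detection_fit_list>", length(x), "fit(s),",
      sum(vapply(x, `[[`, logical(1), "candidate")),
      "candidate(s) within", attr(x, "aic_window"), "AIC units\n")
  for (f in x)
    cat(sprintf("  %s: AIC %.1f (d %.2f)%s [%s]\n", f$id, f$aic,
                f$delta_aic, if (f$candidate) " *" else "",
                if (length(f$covariates))
                  paste(f$covariates, collapse = ", ") else "distance only"))
  invisible(x)
}

# First grid distance, at or beyond the curve's maximum, where `y` drops
# below `threshold`. NA when the curve never crosses within the grid.
.crossing <- function(distance, y, threshold, from = which.max(y)) {
  i <- which(y < threshold & seq_along(y) >= from)
  if (length(i) == 0L) NA_real_ else distance[min(i)]
}

#' Estimate the AMDR from a fitted detection function
#'
#' The AMDR (average maximum detection radius) is the distance at which
#' the predicted number of detections falls below a threshold fraction
#' (default 5%) of the transmissions sent per hour -- for a 60 s nominal
#' transmission interval, 3 detections per hour. The crossing is searched
#' from the curve's maximum outwards so an interference trough near the
#' receiver is not mistaken for the detection limit. The uncertainty band
#' comes from the +/- 1 SE curves crossing the same threshold.
#'
#' @param fit A single fit from [fit_detection_function()], or the whole
#'   `detection_fit_list` (candidates are aggregated: median point,
#'   min/max band).
#' @param nominal_interval Nominal transmission interval, seconds
#'   (default 60).
#' @param threshold_fraction Detection-rate fraction defining "no longer
#'   detected" (default 0.05).
#'
#' @return List with `point`, `low`, `high` (m), `threshold`
#'   (detections/hour) and `censored` (`TRUE` when a curve never crosses
#'   within the prediction grid, i.e. the AMDR exceeds the tested range).
#' @export
estimate_amdr <- function(fit, nominal_interval = 60,
                          threshold_fraction = 0.05) {
  thr <- amdr_threshold_rate(nominal_interval, threshold_fraction)
  if (inherits(fit, "detection_fit_list")) {
    cand <- Filter(function(f) f$candidate, fit)
    ests <- lapply(cand, estimate_amdr, nominal_interval = nominal_interval,
                   threshold_fraction = threshold_fraction)
    return(list(
      point = stats::median(vapply(ests, `[[`, numeric(1), "point")),
      low = min(vapply(ests, `[[`, numeric(1), "low")),
      high = max(vapply(ests, `[[`, numeric(1), "high")),
      threshold = thr,
      censored = any(vapply(ests, `[[`, logical(1), "censored"))))
  }
  pr <- fit$predictions
  point <- .crossing(pr$distance, pr$fit, thr)
  low <- .crossing(pr$distance, pmax(pr$fit - pr$se, 0), thr)
  high <- .crossing(pr$distance, pr$fit + pr$se, thr)
  censored <- is.na(point) || is.na(high)
  if (censored) {
    mx <- max(pr$distance)
    point <- ifelse(is.na(point), mx, point)
    low <- ifelse(is.na(low), mx, low)
    high <- ifelse(is.na(high), mx, high)
  }
  list(point = point, low = low, high = high, threshold = thr,
       censored = censored)
}

#' Detection-rate threshold implied by the nominal transmission interval
#'
#' @param nominal_interval Nominal transmission interval, seconds.
#' @param threshold_fraction Fraction of transmissions (default 0.05).
#' @return Threshold in detections per hour
#'   (`threshold_fraction * 3600 / nominal_interval`).
#' @examples
#' amdr_threshold_rate(60)  # 3 detections/hour
#' @export
amdr_threshold_rate <- function(nominal_interval, threshold_fraction = 0.05) {
  stopifnot(nominal_interval > 0, threshold_fraction > 0)
  threshold_fraction * 3600 / nominal_interval
}

#' Estimate the CPDI extent from a fitted detection function
#'
#' Locates the global maximum of the predicted curve, then reports the
#' smallest distance whose +/- 1 SE interval intersects the maximum's
#' +/- 1 SE interval: the point from which predicted detections no longer
#' statistically differ from the peak. A curve whose maximum sits at the
#' smallest distance shows no interference and returns 0.
#'
#' @inheritParams estimate_amdr
#' @param se_width Half-width of the overlap bands in standard errors
#'   (default 1).
#' @return For a single fit, the extent in metres. For a
#'   `detection_fit_list`, a list with `point` (median across candidates),
#'   `low`, `high`.
#' @export
estimate_cpdi_extent <- function(fit, se_width = 1) {
  if (inherits(fit, "detection_fit_list")) {
    cand <- Filter(function(f) f$candidate, fit)
    ext <- vapply(cand, estimate_cpdi_extent, numeric(1),
                  se_width = se_width)
    return(list(point = stats::median(ext), low = min(ext),
                high = max(ext)))
  }
  pr <- fit$predictions
  imax <- which.max(pr$fit)
  if (imax == 1L) return(0)
  lo_max <- pr$fit[imax] - se_width * pr$se[imax]
  hi <- pr$fit + se_width * pr$se
  overlap <- hi >= lo_max        # band reaches up into the maximum's band
  pr$distance[which(overlap)[1]]
}

#' Receiver performance metrics from daily meta-logs
#'
#' Code detection efficiency (CDE) is the fraction of logged detections
#' to detected synchronization intervals; the rejection coefficient (RC)
#' is the fraction of checksum-rejected trains to syncs. Because
#' interference corrupts sync recognition itself, the adjusted variants
#' replace syncs with total detected pings divided by the pings per
#' train, a proxy for transmissions that does not rely on valid syncs.
#' Days with a zero denominator yield `NA` and are excluded from medians.
#'
#' @param days Data frame with columns `date`, `detections`, `syncs`,
#'   `pings`, `checksum_rejects` (see [read_meta_log_csv()]).
#' @param pings_per_train Pings per complete train (default 8).
#'
#' @return List with `per_day` (data frame adding `cde`, `rc`,
#'   `adjusted_cde`, `adjusted_rc`) and `median` (named vector of
#'   medians over defined days).
#' @examples
#' d <- data.frame(date = as.Date("2015-03-18") + 0:1,
#'                 detections = c(320, 310), syncs = c(3650, 3700),
#'                 pings = c(11800, 11700), checksum_rejects = c(160, 170))
#' receiver_metrics(d)$median
#' @export
receiver_metrics <- function(days, pings_per_train = 8) {
  stopifnot(is.data.frame(days),
            all(c("detections", "syncs", "pings", "checksum_rejects")
                %in% names(days)))
  cnt <- days[, c("detections", "syncs", "pings", "checksum_rejects")]
  if (any(cnt < 0)) stop("meta-log counts must be non-negative")
  if (any(days$detections > days$syncs) || any(days$syncs > days$pings))
    stop("meta-log invariant violated: need detections <= syncs <= pings")
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  trains <- days$pings / pings_per_train
  per_day <- cbind(days, data.frame(
    cde = ratio(days$detections, days$syncs),
    rc = ratio(days$checksum_rejects, days$syncs),
    adjusted_cde = ratio(days$detections, trains),
    adjusted_rc = ratio(days$checksum_rejects, trains)))
  med <- vapply(c("cde", "rc", "adjusted_cde", "adjusted_rc"),
                function(m) stats::median(per_day[[m]], na.rm = TRUE),
                numeric(1))
  list(per_day = per_day, median = med)
}

#' One-call ranging analysis: AMDR and CPDI extent with bands
#'
#' @inheritParams estimate_amdr
#' @param fits A `detection_fit_list`.
#' @param se_width Passed to [estimate_cpdi_extent()].
#' @return Object of class `ranging_estimate`: list with `amdr`,
#'   `cpdi_extent` (each `point`/`low`/`high`) and `candidate_count`.
#' @export
ranging_estimate <- function(fits, nominal_interval = 60,
                             threshold_fraction = 0.05, se_width = 1) {
  stopifnot(inherits(fits, "detection_fit_list"))
  amdr <- estimate_amdr(fits, nominal_interval, threshold_fraction)
  ext <- estimate_cpdi_extent(fits, se_width)
  structure(list(amdr = amdr, cpdi_extent = ext,
                 candidate_count = sum(vapply(fits, `[[`, logical(1),
                                              "candidate"))),
            class = "ranging_estimate")
}

#' @export
print.ranging_estimate <- function(x, ...) {
  cat(sprintf(
    "<ranging_estimate> AMDR %.1f m (%.0f-%.0f)%s; CPDI extent %.1f m (%.0f-%.0f); %d candidate fit(s)\n",
    x$amdr$point, x$amdr$low, x$amdr$high,
    if (x$amdr$censored) " [censored at grid edge]" else "",
    x$cpdi_extent$point, x$cpdi_extent$low, x$cpdi_extent$high,
    x$candidate_count))
  invisible(x)
}
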