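# Waveform-free receiver decoding simulator.
#
# A coded transmission is a train of pings whose inter-ping intervals
# carry the information (first interval = synchronization, last =
# checksum, middle = ID code). The receiver registers a ping, opens a
# blanking interval during which further arrivals are ignored, and
# accepts the train only if the registered inter-event intervals match
# the expected code. Multipath arrivals landing after a blanking interval
# are indistinguishable from pings and corrupt decoding -- the mechanism
# behind CPDI.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. No hidden global randomness.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Construct a coded ping train
#'
#' @param spec A [receiver_spec()]; fixes the number of pings.
#' @param code_intervals Inter-ping intervals in seconds, length
#'   `pings_per_train - 1`, each strictly greater than the blanking
#'   interval (a shorter interval would blank its own next ping).
#' @param start_time Emission time of the first ping, seconds.
#'
#' @return Object of class `ping_train`: list with `ping_times`,
#'   `intervals` and `roles` (`"sync"`, `"id"` ..., `"checksum"`).
#' @examples
#' make_ping_train(receiver_spec(amdr = 843), rep(0.5, 7))
#' @export
make_ping_train <- function(spec, code_intervals, start_time = 0) {
  stopifnot(inherits(spec, "receiver_spec"), is.numeric(code_intervals))
  n <- spec$pings_per_train
  if (length(code_intervals) != n - 1L)
    stop("need ", n - 1L, " code intervals for a ", n, "-ping train, got ",
         length(code_intervals))
  bad <- which(code_intervals <= spec$blanking_interval)
  if (length(bad))
    stop("code interval(s) ", paste(signif(code_intervals[bad], 4),
         collapse = ", "), " s not greater than the blanking interval (",
         spec$blanking_interval, " s): the train would blank itself")
  roles <- c("sync", rep("id", n - 3L), "checksum")
  structure(list(
    ping_times = start_time + c(0, cumsum(code_intervals)),
    intervals = as.numeric(code_intervals),
    roles = roles
  ), class = "ping_train")
}

#' Multipath impulse response for a tag--receiver geometry
#'
#' One spike per acoustic arrival: the direct path at delay 0 and each
#' reflected path at its relative delay. Amplitudes follow spherical
#' spreading, `1 / path_length` (equivalently `10^(-log10(L))`); no
#' additional reflection or scattering loss is applied, so reflected
#' arrivals are attenuated only by their extra travel distance.
#'
#' @param arrivals A `multipath_set` from [enumerate_multipaths()].
#' @param direct_length Direct path length in metres (> 0). Defaults to
#'   the length attached to `arrivals`.
#' @param unit_amplitude If `TRUE`, all spikes get amplitude 1 (useful for
#'   colocated geometries where the direct length is 0 and `1/L` is
#'   undefined).
#'
#' @return Data frame with columns `delay` (s) and `amplitude`, direct
#'   path first.
#' @export
impulse_response <- function(arrivals,
                             direct_length = attr(arrivals, "direct_length"),
                             unit_amplitude = FALSE) {
  stopifnot(is.data.frame(arrivals),
            all(c("relative_delay", "path_length") %in% names(arrivals)))
  if (!unit_amplitude && (is.null(direct_length) || direct_length <= 0))
    stop("direct path length is ", direct_length,
         ": spreading amplitudes 1/L are undefined; ",
         "call impulse_response(..., unit_amplitude = TRUE)")
  amp <- if (unit_amplitude) rep(1, nrow(arrivals) + 1L)
         else c(1 / direct_length, 1 / arrivals$path_length)
  data.frame(delay = c(0, arrivals$relative_delay), amplitude = amp)
}

#' Superpose a ping train with an impulse response
#'
#' The discrete-event analogue of convolving the source waveform with the
#' channel impulse response: every ping generates one arrival event per
#' impulse-response spike.
#'
#' @param train A [make_ping_train()] object.
#' @param ir An [impulse_response()] data frame.
#'
#' @return Data frame of arrival events sorted by time (stable tie-break
#'   by ping then spike index): `time` (s), `amplitude`, `source_ping`
#'   (1-based), `path` (`"direct"` or `"multipath"`), `path_index` (row of
#'   `ir`).
#' @export
superpose <- function(train, ir) {
  stopifnot(inherits(train, "ping_train"), is.data.frame(ir),
            nrow(ir) >= 1L)
  np <- length(train$ping_times)
  ni <- nrow(ir)
  ping <- rep(seq_len(np), each = ni)
  spike <- rep(seq_len(ni), times = np)
  ev <- data.frame(
    time = train$ping_times[ping] + ir$delay[spike],
    amplitude = ir$amplitude[spike],
    source_ping = ping,
    path = ifelse(spike == 1L & ir$delay[1] == 0, "direct", "multipath"),
    path_index = spike
  )
  ev[order(ev$time, ev$source_ping, ev$path_index), , drop = FALSE]
}

#' Decode an arrival-event stream through a blanking-interval receiver
#'
#' Sweeps the events in time order. An event is registered iff its
#' amplitude reaches `threshold` and it arrives at least one blanking
#' interval after the last registered event; blanked arrivals are simply
#' ignored and (by default) do not re-arm the blanking interval. The
#' train is detected iff exactly `pings_per_train` events are registered
#' and every registered inter-event interval matches the expected code
#' within `tolerance`.
#'
#' @param events Event data frame from [superpose()] (must be sorted by
#'   time; multiple trains' events may be concatenated).
#' @param spec A [receiver_spec()].
#' @param expected_intervals The transmitted code intervals, seconds
#'   (length `pings_per_train - 1`).
#' @param threshold Minimum registrable amplitude. Expressing it as
#'   `1 / amdr` (the amplitude of a path exactly AMDR long) keeps the
#'   simulator and the geometric criterion on the same footing.
#' @param tolerance Interval-match tolerance in seconds (default 5 ms).
#' @param rearm_on_blanked If `TRUE`, a blanked arrival restarts the
#'   blanking interval. Off by default: the modelled receiver ignores, but
#'   is not re-armed by, energy arriving while blanked.
#'
#' @return Object of class `decode_outcome`: list with `detected`,
#'   `registered_times`, and `failure_mode` (`"none"`, `"spurious_ping"`,
#'   `"interval_mismatch"`, `"missing_ping"` or `"collision"`).
#' @export
decode <- function(events, spec, expected_intervals,
                   threshold = 1 / spec$amdr, tolerance = 0.005,
                   rearm_on_blanked = FALSE) {
  stopifnot(inherits(spec, "receiver_spec"), is.data.frame(events),
            threshold >= 0)
  if (is.unsorted(events$time))
    stop("`events` must be sorted by arrival time")
  if (length(expected_intervals) != spec$pings_per_train - 1L)
    stop("`expected_intervals` must have length pings_per_train - 1")
  bi <- spec$blanking_interval
  reg <- logical(nrow(events))
  gate <- -Inf                                    # next registrable time
  for (k in seq_len(nrow(events))) {
    if (events$time[k] < gate) {
      if (rearm_on_blanked && events$amplitude[k] >= threshold)
        gate <- events$time[k] + bi
      next
    }
    if (events$amplitude[k] >= threshold) {
      reg[k] <- TRUE
      gate <- events$time[k] + bi
    }
  }
  times <- events$time[reg]
  n <- spec$pings_per_train
  failure <- "none"
  detected <- FALSE
  if (length(times) < n) {
    failure <- "missing_ping"
  } else if (any(events$path[reg] != "direct")) {
    failure <- "spurious_ping"
  } else if (length(times) > n) {
    failure <- "spurious_ping"
  } else if (any(abs(diff(times) - expected_intervals) > tolerance)) {
    failure <- "interval_mismatch"
  } else {
    detected <- TRUE
  }
  structure(list(detected = detected, registered_times = times,
                 failure_mode = failure), class = "decode_outcome")
}

#' @export
print.decode_outcome <- function(x, ...) {
  cat("<decode_outcome>", if (x$detected) "DETECTED" else
      paste0("rejected (", x$failure_mode, ")"),
      "-", length(x$registered_times), "events registered\n")
  invisible(x)
}

#' Monte-Carlo simulation of multi-tag transmission collisions
#'
#' Independent tags transmit trains of fixed duration separated by
#' uniformly distributed random delays. When two trains from different
#' tags overlap in time the receiver rejects both. Returns the realised
#' detection rate; with a single tag nothing ever collides.
#'
#' For two tags the stationary overlap probability is
#' `2 * train_duration / mean(interval_window)`, the analytic benchmark
#' the simulation converges to.
#'
#' @param n_tags Number of tags within range of the receiver (>= 1).
#' @param interval_window Length-2 numeric, `c(min, max)` seconds of the
#'   uniform inter-transmission delay. Default `c(30, 90)` (60 s nominal).
#' @param train_duration Duration of one transmission train, seconds
#'   (default 3.5).
#' @param hours Simulated listening time, hours.
#' @param seed Integer seed (required; the generator has no hidden
#'   randomness).
#'
#' @return List with `mean_detections_per_hour` (total across tags),
#'   `detection_fraction` (per-tag named vector), `overall_fraction`, and
#'   `n_transmissions`.
#' @examples
#' simulate_collisions(2, hours = 10, seed = 1)
#' @export
simulate_collisions <- function(n_tags, interval_window = c(30, 90),
                                train_duration = 3.5, hours = 24,
                                seed) {
  stopifnot(n_tags >= 1, length(interval_window) == 2L,
            interval_window[1] > 0,
            interval_window[2] >= interval_window[1],
            train_duration > 0, hours > 0)
  if (missing(seed)) stop("`seed` is required")
  horizon <- hours * 3600
  .with_seed(seed, {
    n_max <- ceiling(horizon / interval_window[1]) + 1L
    starts <- vector("list", n_tags)
    for (tg in seq_len(n_tags)) {
      s <- cumsum(stats::runif(n_max, interval_window[1],
                               interval_window[2]))
      starts[[tg]] <- s[s + train_duration <= horizon]
    }
    tag_id <- rep(seq_len(n_tags), lengths(starts))
    s <- unlist(starts)
    o <- order(s)
    s <- s[o]; tag_id <- tag_id[o]
    m <- length(s)
    lost <- logical(m)
    if (m > 1L) {
      # Same-tag gaps exceed interval_window[1] >> train_duration, so any
      # overlapping neighbour is from another tag; adjacent pairs suffice
      # when the minimum delay exceeds the train duration.
      gap <- diff(s)
      i <- which(gap < train_duration & tag_id[-m] != tag_id[-1L])
      lost[i] <- TRUE
      lost[i + 1L] <- TRUE
    }
    frac <- vapply(seq_len(n_tags), function(tg) {
      sel <- tag_id == tg
      if (!any(sel)) return(NA_real_)
      mean(!lost[sel])
    }, numeric(1))
    names(frac) <- paste0("tag", seq_len(n_tags))
    list(mean_detections_per_hour = sum(!lost) / hours,
         detection_fraction = frac,
         overall_fraction = mean(!lost),
         n_transmissions = m)
  })
}

# Analytic per-transmission survival under independent-thinning collisions:
# probability that none of the other tags starts a train within +/- the
# train duration of this one's start.
.collision_survival <- function(n_tags, interval_window, train_duration) {
  p_pair <- 2 * train_duration / mean(interval_window)
  (1 - min(1, p_pair))^(n_tags - 1)
}
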