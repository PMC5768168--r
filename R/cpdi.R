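# CPDI prediction: classify multipath arrivals against the receiver's
# blanking interval and AMDR, and map the interference region.
#
# Category 1: delay <= BI and length <= AMDR -- absorbed by the blanking
#             interval, harmless.
# Category 2: delay >  BI and length <= AMDR -- detectable energy arriving
#             after the blanking interval; mistaken for the next ping and
#             predicted to invalidate the train (CPDI).
# Category 3: length > AMDR -- too attenuated to be detected, harmless.
# Both boundary comparisons are inclusive.

#' Classify multipath arrivals into interference categories
#'
#' @param arrivals A `multipath_set` from [enumerate_multipaths()] (or any
#'   data frame with `path_length` and `relative_delay` columns).
#' @param spec A [receiver_spec()].
#'
#' @return The input with its `category` column set: 1 = within blanking
#'   interval (harmless), 2 = CPDI-producing, 3 = beyond AMDR (harmless).
#' @export
classify_multipath <- function(arrivals, spec) {
  stopifnot(inherits(spec, "receiver_spec"),
            all(c("path_length", "relative_delay") %in% names(arrivals)))
  L <- arrivals$path_length
  d <- arrivals$relative_delay
  arrivals$category <- ifelse(L > spec$amdr, 3L,
                              ifelse(d > spec$blanking_interval, 2L, 1L))
  arrivals
}

# Fast internal point predictor avoiding data-frame construction.
# Returns the number of category-2 arrivals.
.n_cat2 <- function(D, c_w, zt, zr, r, bi, amdr, max_arrivals = NULL,
                    first_surface_only = FALSE) {
  if (first_surface_only) {
    v <- zt + zr
    L <- sqrt(r^2 + v^2)
    if (L > amdr) return(0L)
    delay <- (L - .direct_length(zt, zr, r)) / c_w
    return(as.integer(delay > bi))
  }
  s <- .image_set(D, zt, zr, r, amdr)
  L <- s$length
  if (!is.null(max_arrivals) && length(L) > max_arrivals)
    L <- L[seq_len(max_arrivals)]
  delay <- (L - .direct_length(zt, zr, r)) / c_w
  sum(delay > bi)
}

#' Predict CPDI at a single tag position
#'
#' Enumerates all reflected paths no longer than the AMDR (optionally
#' truncated to the shortest `max_arrivals`), classifies them, and flags
#' the position if at least one arrival is CPDI-producing (category 2).
#'
#' @param env An [acoustic_env()].
#' @param spec A [receiver_spec()].
#' @param receiver_depth,tag_depth Depths below the surface, metres.
#' @param range Horizontal tag--receiver range, metres.
#' @param max_arrivals Optional truncation of the enumeration to the
#'   shortest reflected paths (default `NULL`: complete enumeration).
#' @param first_surface_only If `TRUE`, only the first surface reflection
#'   is considered (the textbook single-bounce regime).
#'
#' @return List with `cpdi` (logical flag) and `n_category2` (count of
#'   interfering arrivals).
#' @examples
#' env <- acoustic_env(215)
#' spec <- receiver_spec(amdr = 843)
#' predict_cpdi_point(env, spec, receiver_depth = 214, tag_depth = 214,
#'                    range = 0)
#' @export
predict_cpdi_point <- function(env, spec, receiver_depth, tag_depth, range,
                               max_arrivals = NULL,
                               first_surface_only = FALSE) {
  stopifnot(inherits(env, "acoustic_env"), inherits(spec, "receiver_spec"))
  geom <- pair_geometry(env, tag_depth, receiver_depth, range)  # validates
  n2 <- .n_cat2(env$water_depth, env$sound_speed, geom$tag_depth,
                geom$receiver_depth, geom$horizontal_range,
                spec$blanking_interval, spec$amdr, max_arrivals,
                first_surface_only)
  list(cpdi = n2 > 0L, n_category2 = as.integer(n2))
}

#' Map predicted CPDI over a range-by-depth grid
#'
#' Grids the study area by horizontal range and tag depth, with the
#' receiver fixed at range 0, and evaluates the CPDI criterion at every
#' node. Nodes sit at `0, resolution, 2 * resolution, ...` up to
#' `max_range` inclusive.
#'
#' @inheritParams predict_cpdi_point
#' @param max_range Largest tag range to evaluate, metres
#'   (`>= resolution`).
#' @param depth_axis Increasing vector of tag depths (m) to evaluate;
#'   default: the single depth equal to `receiver_depth`.
#' @param resolution Grid spacing along the range axis, metres (> 0).
#'
#' @return An object of class `cpdi_grid`: list with `range_axis`,
#'   `depth_axis`, logical matrix `cpdi_flag` (depth x range), integer
#'   matrix `n_category2`, `receiver_depth`, and the `env`/`spec`/
#'   `enumeration` provenance. Convert with [as.data.frame.cpdi_grid()].
#' @examples
#' env <- acoustic_env(300)
#' spec <- receiver_spec(amdr = 843)
#' g <- predict_cpdi_map(env, spec, receiver_depth = 299, max_range = 400,
#'                       depth_axis = 299, resolution = 1)
#' cpdi_extent(g, tag_depth = 299)
#' @export
predict_cpdi_map <- function(env, spec, receiver_depth, max_range,
                             depth_axis = receiver_depth, resolution = 1,
                             max_arrivals = NULL,
                             first_surface_only = FALSE) {
  stopifnot(inherits(env, "acoustic_env"), inherits(spec, "receiver_spec"))
  if (!is.numeric(resolution) || resolution <= 0)
    stop("`resolution` must be a positive grid spacing in metres")
  if (max_range < resolution)
    stop("`max_range` must be at least one `resolution` step")
  depth_axis <- sort(unique(as.numeric(depth_axis)))
  if (length(depth_axis) == 0L) stop("`depth_axis` is empty")
  if (any(depth_axis < 0 | depth_axis > env$water_depth))
    stop("`depth_axis` must lie within the water column")
  if (receiver_depth < 0 || receiver_depth > env$water_depth)
    stop("`receiver_depth` must lie within the water column")
  range_axis <- seq(0, max_range, by = resolution)

  n2 <- matrix(0L, nrow = length(depth_axis), ncol = length(range_axis),
               dimnames = list(depth = NULL, range = NULL))
  for (i in seq_along(depth_axis)) {
    for (j in seq_along(range_axis)) {
      n2[i, j] <- .n_cat2(env$water_depth, env$sound_speed,
                          depth_axis[i], receiver_depth, range_axis[j],
                          spec$blanking_interval, spec$amdr,
                          max_arrivals, first_surface_only)
    }
  }
  structure(list(
    range_axis = range_axis,
    depth_axis = depth_axis,
    cpdi_flag = n2 > 0L,
    n_category2 = n2,
    receiver_depth = as.numeric(receiver_depth),
    env = env,
    spec = spec,
    enumeration = list(
      complete = is.null(max_arrivals) && !first_surface_only,
      max_arrivals = max_arrivals,
      first_surface_only = first_surface_only,
      resolution = as.numeric(resolution))
  ), class = "cpdi_grid")
}

#' @export
print.cpdi_grid <- function(x, ...) {
  cat("<cpdi_grid> ", length(x$depth_axis), " tag depth(s) x ",
      length(x$range_axis), " ranges (0-",
      max(x$range_axis), " m, res ", x$enumeration$resolution, " m)\n",
      sep = "")
  cat("  receiver at", x$receiver_depth, "m depth; AMDR", x$spec$amdr,
      "m; BI", x$spec$blanking_interval * 1000, "ms;",
      if (x$enumeration$complete) "complete enumeration"
      else if (x$enumeration$first_surface_only) "first surface bounce only"
      else paste("first", x$enumeration$max_arrivals, "arrivals"), "\n")
  for (i in seq_along(x$depth_axis))
    cat("  tag depth ", x$depth_axis[i], " m: CPDI extent ",
        cpdi_extent(x, x$depth_axis[i]), " m\n", sep = "")
  invisible(x)
}

#' Flatten a CPDI grid to a data frame
#'
#' @param x A `cpdi_grid`.
#' @param ... Unused.
#' @return Data frame with columns `range_m`, `tag_depth_m`, `cpdi` (0/1)
#'   and `n_cat2`, ordered by depth then range.
#' @export
as.data.frame.cpdi_grid <- function(x, ...) {
  data.frame(
    range_m = rep(x$range_axis, times = length(x$depth_axis)),
    tag_depth_m = rep(x$depth_axis, each = length(x$range_axis)),
    cpdi = as.integer(t(x$cpdi_flag)),
    n_cat2 = as.integer(t(x$n_category2))
  )
}

#' CPDI extent at a given tag depth
#'
#' The maximum flagged range for that depth row of the grid (0 if no node
#' is flagged). Contiguity from the receiver outward is not required, so
#' the extent stays well defined for fragmented interference zones.
#'
#' @param grid A `cpdi_grid` from [predict_cpdi_map()].
#' @param tag_depth A depth on the grid's depth axis (m).
#' @return The extent in metres.
#' @export
cpdi_extent <- function(grid, tag_depth) {
  stopifnot(inherits(grid, "cpdi_grid"))
  i <- which(abs(grid$depth_axis - tag_depth) < 1e-9)
  if (length(i) != 1L)
    stop("tag_depth ", tag_depth, " m is not on the grid's depth axis")
  flags <- grid$cpdi_flag[i, ]
  if (!any(flags)) 0 else max(grid$range_axis[flags])
}

#' Critical depth for first-surface-bounce CPDI
#'
#' For a tag and receiver colocated at equal depth z, the first surface
#' reflection travels 2z farther than the direct path, so its delay 2z/c
#' exceeds the blanking interval exactly when z > c * bi / 2. Below that
#' depth the surface bounce is absorbed by the blanking interval and can
#' never produce CPDI on its own.
#'
#' @param sound_speed Sound speed, m/s.
#' @param blanking_interval Blanking interval, s.
#' @return The threshold depth c * bi / 2 in metres.
#' @examples
#' critical_depth(1530, 0.260)  # 198.9 m
#' @export
critical_depth <- function(sound_speed, blanking_interval) {
  stopifnot(is.numeric(sound_speed), sound_speed > 0,
            is.numeric(blanking_interval), blanking_interval >= 0)
  sound_speed * blanking_interval / 2
}

#' Closed-form CPDI extent from the first surface reflection alone
#'
#' Continuous (not gridded) solution of
#' `sqrt(r^2 + v^2) - sqrt(r^2 + dz^2) = c * bi` with `v = zt + zr` and
#' `dz = zt - zr`, capped by the AMDR detectability constraint
#' `sqrt(r^2 + v^2) <= amdr`. Returns 0 when the surface bounce is
#' absorbed by the blanking interval even at range 0.
#'
#' @param env An [acoustic_env()].
#' @param spec A [receiver_spec()].
#' @param tag_depth,receiver_depth Depths below the surface, metres.
#' @return Extent in metres (not rounded to any grid).
#' @examples
#' surface_bounce_extent(acoustic_env(300), receiver_spec(amdr = 843),
#'                       tag_depth = 299, receiver_depth = 299)  # 250.58 m
#' @export
surface_bounce_extent <- function(env, spec, tag_depth, receiver_depth) {
  stopifnot(inherits(env, "acoustic_env"), inherits(spec, "receiver_spec"))
  X <- env$sound_speed * spec$blanking_interval
  v <- tag_depth + receiver_depth
  dz <- tag_depth - receiver_depth
  if (v - abs(dz) <= X) return(0)                 # absorbed even at r = 0
  q <- (v^2 - X^2 - dz^2) / (2 * X)               # = sqrt(r^2 + dz^2)
  if (q < abs(dz)) return(0)
  r_delay <- sqrt(q^2 - dz^2)                     # delay == BI here
  if (v > spec$amdr) return(0)                    # undetectable at r = 0
  r_amdr <- sqrt(spec$amdr^2 - v^2)               # length == AMDR here
  min(r_delay, r_amdr)
}
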