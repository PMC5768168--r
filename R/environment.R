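#' Acoustic environment: a flat waveguide
#'
#' Describes the idealised study environment all geometry runs in: a
#' constant-depth water column bounded by a flat free surface and a flat
#' seafloor, with a single depth- and range-independent sound speed
#' (straight-line propagation). Refraction, sloping bathymetry and
#' reflection losses are deliberately outside the model.
#'
#' @param water_depth Water column depth in metres (> 0).
#' @param sound_speed Sound speed in metres per second (> 0). The default,
#'   1530 m/s, is typical of warm subtropical coastal water.
#'
#' @return An object of class `acoustic_env`.
#' @examples
#' acoustic_env(water_depth = 300)
#' @export
acoustic_env <- function(water_depth, sound_speed = 1530) {
  stopifnot(is.numeric(water_depth), length(water_depth) == 1L,
            is.numeric(sound_speed), length(sound_speed) == 1L)
  if (!is.finite(water_depth) || water_depth <= 0)
    stop("`water_depth` must be a positive number of metres, got ",
         water_depth)
  if (!is.finite(sound_speed) || sound_speed <= 0)
    stop("`sound_speed` must be a positive number of m/s, got ", sound_speed)
  structure(list(water_depth = as.numeric(water_depth),
                 sound_speed = as.numeric(sound_speed)),
            class = "acoustic_env")
}

#' @export
print.acoustic_env <- function(x, ...) {
  cat("<acoustic_env> flat waveguide:",
      x$water_depth, "m deep, c =", x$sound_speed, "m/s\n")
  invisible(x)
}

#' Tag--receiver pair geometry
#'
#' Relative position of one transmitter tag and one receiver inside an
#' [acoustic_env()]. Depths are metres below the free surface (positive
#' down); use [heights_to_depths()] to convert mooring heights above the
#' seafloor.
#'
#' @param tag_depth,receiver_depth Depths below the surface in metres; must
#'   lie within the water column `[0, water_depth]`.
#' @param horizontal_range Horizontal separation in metres (>= 0).
#' @param env The [acoustic_env()] the pair sits in (used for validation).
#'
#' @return An object of class `pair_geometry`.
#' @export
pair_geometry <- function(env, tag_depth, receiver_depth, horizontal_range) {
  stopifnot(inherits(env, "acoustic_env"))
  for (nm in c("tag_depth", "receiver_depth", "horizontal_range")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number")
  }
  D <- env$water_depth
  if (tag_depth < 0 || tag_depth > D)
    stop("tag_depth ", tag_depth, " m is outside the water column [0, ",
         D, "] m")
  if (receiver_depth < 0 || receiver_depth > D)
    stop("receiver_depth ", receiver_depth,
         " m is outside the water column [0, ", D, "] m")
  if (horizontal_range < 0)
    stop("horizontal_range must be >= 0, got ", horizontal_range)
  structure(list(tag_depth = as.numeric(tag_depth),
                 receiver_depth = as.numeric(receiver_depth),
                 horizontal_range = as.numeric(horizontal_range)),
            class = "pair_geometry")
}

#' Receiver detection contract
#'
#' The two numbers that decide whether a multipath arrival can corrupt
#' decoding: the post-ping blanking interval during which further arrivals
#' are ignored, and the AMDR (average maximum detection radius) standing in
#' for the receiver's detection-threshold distance. Also carries the number
#' of pings composing a complete coded transmission train.
#'
#' @param amdr Average maximum detection radius in metres (> 0): the
#'   farthest distance at which transmissions are still detectable; path
#'   lengths beyond it are assumed below the detection threshold.
#' @param blanking_interval Blanking interval in seconds (> 0). Default
#'   0.260 s, the longest selectable on the modelled receiver.
#' @param pings_per_train Pings per complete transmission train (>= 7);
#'   default 8.
#'
#' @return An object of class `receiver_spec`.
#' @examples
#' receiver_spec(amdr = 843)
#' @export
receiver_spec <- function(amdr, blanking_interval = 0.260,
                          pings_per_train = 8L) {
  if (!is.numeric(amdr) || length(amdr) != 1L || !is.finite(amdr) ||
      amdr <= 0)
    stop("`amdr` must be a positive length in metres, got ", amdr)
  if (!is.numeric(blanking_interval) || length(blanking_interval) != 1L ||
      !is.finite(blanking_interval) || blanking_interval <= 0)
    stop("`blanking_interval` must be a positive time in seconds, got ",
         blanking_interval)
  if (!is.numeric(pings_per_train) || length(pings_per_train) != 1L ||
      pings_per_train < 7 || pings_per_train != round(pings_per_train))
    stop("`pings_per_train` must be an integer >= 7, got ", pings_per_train)
  structure(list(blanking_interval = as.numeric(blanking_interval),
                 amdr = as.numeric(amdr),
                 pings_per_train = as.integer(pings_per_train)),
            class = "receiver_spec")
}

#' @export
print.receiver_spec <- function(x, ...) {
  cat("<receiver_spec> BI =", x$blanking_interval * 1000, "ms, AMDR =",
      x$amdr, "m,", x$pings_per_train, "pings/train\n")
  invisible(x)
}

#' Convert mooring heights above the seafloor to depths
#'
#' Field deployments are usually described by the height of each unit above
#' the seafloor; the image-source algebra wants depths below the surface.
#'
#' @param env An [acoustic_env()].
#' @param tag_height,receiver_height Heights above the seafloor in metres,
#'   each within `[0, water_depth]`.
#'
#' @return Named list with `tag_depth` and `receiver_depth` in metres below
#'   the surface.
#' @examples
#' heights_to_depths(acoustic_env(300), tag_height = 1, receiver_height = 1)
#' @export
heights_to_depths <- function(env, tag_height, receiver_height) {
  stopifnot(inherits(env, "acoustic_env"))
  D <- env$water_depth
  for (nm in c("tag_height", "receiver_height")) {
    h <- get(nm)
    if (!is.numeric(h) || length(h) != 1L || !is.finite(h) ||
        h < 0 || h > D)
      stop("`", nm, "` = ", h, " m is outside the water column [0, ",
           D, "] m")
  }
  list(tag_depth = D - tag_height, receiver_depth = D - receiver_height)
}
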