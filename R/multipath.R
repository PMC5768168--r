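# Image-source enumeration of reflected propagation paths.
#
# In a flat waveguide every reflected path from tag to receiver is a
# straight line to one of the tag's mirror images. The images sit at the
# signed depths z = 2mD + zt and z = 2mD - zt over the integers m; the
# direct path is the (m = 0, +) member. The vertical image distance is
# v = |z - zr| and the path length L = sqrt(r^2 + v^2).

# Vectorised internal core: image distances, bounce counts, lengths.
# Returns a list of parallel vectors, sorted by (L, surface, bottom),
# restricted to reflected paths with L <= max_path_length.
.image_set <- function(D, zt, zr, r, max_path_length) {
  # For |m| >= M every image is farther than max_path_length:
  # v >= 2|m|D - 2D, so 2D(M - 1) > max_path_length suffices.
  M <- floor(max_path_length / (2 * D)) + 2L
  m_all <- seq.int(-M, M)
  m_plus <- m_all[m_all != 0L]                   # + family, m = 0 is direct
  z <- c(2 * m_plus * D + zt, 2 * m_all * D - zt)
  fam <- rep(c("+", "-"), c(length(m_plus), length(m_all)))
  m <- c(m_plus, m_all)
  v <- abs(z - zr)

  surface <- integer(length(m))
  bottom <- integer(length(m))
  p <- fam == "+"
  surface[p] <- abs(m[p]); bottom[p] <- abs(m[p])
  n0 <- !p & m == 0L
  surface[n0] <- 1L; bottom[n0] <- 0L
  npos <- !p & m > 0L
  surface[npos] <- m[npos] - 1L; bottom[npos] <- m[npos]
  nneg <- !p & m < 0L
  surface[nneg] <- abs(m[nneg]) + 1L; bottom[nneg] <- abs(m[nneg])

  L <- sqrt(r^2 + v^2)
  keep <- L <= max_path_length
  o <- order(L[keep], surface[keep], bottom[keep])
  idx <- which(keep)[o]
  list(v = v[idx], length = L[idx],
       surface = surface[idx], bottom = bottom[idx])
}

.direct_length <- function(zt, zr, r) sqrt(r^2 + (zt - zr)^2)

#' Enumerate reflected multipath arrivals between a tag and a receiver
#'
#' Uses the image-source method to list every surface/seafloor-reflected
#' propagation path with length up to `max_path_length`, sorted by
#' increasing path length (ties broken by ascending surface then bottom
#' bounce counts). Enumeration is provably complete: image orders are
#' expanded until the smallest achievable image distance exceeds
#' `max_path_length`. The direct path is excluded from the returned set but
#' its length is attached as an attribute and drives the relative delays.
#'
#' @param env An [acoustic_env()].
#' @param geom A [pair_geometry()] valid in `env`.
#' @param max_path_length Only paths with length `<=` this bound (metres)
#'   are returned. Typically the receiver's AMDR.
#' @param max_arrivals Optional truncation: keep only this many shortest
#'   reflected paths. `NULL` (default) keeps all. Truncation mirrors
#'   implementations that only consider the first few acoustic arrivals.
#'
#' @return A data frame of class `multipath_set` with one row per reflected
#'   arrival and columns `path_length` (m), `vertical_image_distance` (m),
#'   `surface_bounces`, `bottom_bounces`, `relative_delay` (s, relative to
#'   the direct arrival), `amplitude_scalar` (1/path_length, spherical
#'   spreading), and `category` (NA until classified, see
#'   [classify_multipath()]). The direct path length is in
#'   `attr(, "direct_length")`.
#' @examples
#' env <- acoustic_env(300)
#' geom <- pair_geometry(env, tag_depth = 299, receiver_depth = 299,
#'                       horizontal_range = 100)
#' enumerate_multipaths(env, geom, max_path_length = 843)
#' @export
enumerate_multipaths <- function(env, geom, max_path_length,
                                 max_arrivals = NULL) {
  stopifnot(inherits(env, "acoustic_env"), inherits(geom, "pair_geometry"))
  if (!is.numeric(max_path_length) || length(max_path_length) != 1L ||
      !is.finite(max_path_length) || max_path_length <= 0)
    stop("`max_path_length` must be a positive length in metres")
  if (!is.null(max_arrivals)) {
    stopifnot(is.numeric(max_arrivals), length(max_arrivals) == 1L,
              max_arrivals >= 0)
    max_arrivals <- as.integer(max_arrivals)
  }
  D <- env$water_depth
  zt <- geom$tag_depth; zr <- geom$receiver_depth
  r <- geom$horizontal_range
  s <- .image_set(D, zt, zr, r, max_path_length)
  if (!is.null(max_arrivals) && length(s$length) > max_arrivals) {
    i <- seq_len(max_arrivals)
    s <- lapply(s, `[`, i)
  }
  direct <- .direct_length(zt, zr, r)
  out <- data.frame(
    path_length = s$length,
    vertical_image_distance = s$v,
    surface_bounces = s$surface,
    bottom_bounces = s$bottom,
    relative_delay = (s$length - direct) / env$sound_speed,
    amplitude_scalar = ifelse(s$length > 0, 1 / s$length, Inf),
    category = rep(NA_integer_, length(s$length))
  )
  attr(out, "direct_length") <- direct
  class(out) <- c("multipath_set", "data.frame")
  out
}

#' Direct path length for a pair geometry
#'
#' @param geom A [pair_geometry()].
#' @return Length of the straight tag-to-receiver path in metres.
#' @export
direct_path_length <- function(geom) {
  stopifnot(inherits(geom, "pair_geometry"))
  .direct_length(geom$tag_depth, geom$receiver_depth,
                 geom$horizontal_range)
}

# Vertical image distances achievable for one bounce signature.
# Bounce counts constrain the image family and order; a signature with
# s == b matches two images (surface-first and bottom-first unfoldings),
# in which case the shorter path is used.
.signature_image_distances <- function(D, zt, zr, surface, bottom) {
  v <- numeric(0)
  if (surface == bottom && surface >= 1) {
    m <- surface
    v <- c(abs(2 * m * D + zt - zr), abs(-2 * m * D + zt - zr))
  } else if (surface == 1 && bottom == 0) {
    v <- zt + zr
  } else if (bottom == surface + 1) {
    m <- bottom                                  # (m, -), m > 0
    v <- abs(2 * m * D - zt - zr)
  } else if (surface == bottom + 1 && bottom >= 1) {
    m <- -bottom                                 # (m, -), m < 0
    v <- abs(2 * m * D - zt - zr)
  }
  v
}

#' Relative arrival delay of one multipath across a set of ranges
#'
#' For a fixed tag and receiver depth, computes the delay of the reflected
#' arrival with the given bounce signature relative to the direct arrival,
#' at each horizontal range. For any fixed signature the delay decreases
#' strictly with range: direct and reflected arrival times converge, which
#' is why interference is a close-proximity phenomenon.
#'
#' @param env An [acoustic_env()].
#' @param tag_depth,receiver_depth Depths below the surface, metres.
#' @param ranges Numeric vector of horizontal ranges (m, >= 0).
#' @param surface_bounces,bottom_bounces Bounce signature selecting the
#'   arrival; the default `(1, 0)` is the first surface reflection. When
#'   the signature is ambiguous (equal bounce counts) the shorter path is
#'   used.
#'
#' @return Numeric vector of delays in seconds, one per range.
#' @examples
#' relative_delay_curve(acoustic_env(300), 299, 299, ranges = c(0, 100, 250))
#' @export
relative_delay_curve <- function(env, tag_depth, receiver_depth, ranges,
                                 surface_bounces = 1L, bottom_bounces = 0L) {
  stopifnot(inherits(env, "acoustic_env"), is.numeric(ranges))
  if (any(!is.finite(ranges)) || any(ranges < 0))
    stop("`ranges` must be non-negative and finite")
  D <- env$water_depth
  if (tag_depth < 0 || tag_depth > D || receiver_depth < 0 ||
      receiver_depth > D)
    stop("tag and receiver depths must lie within the water column")
  v <- .signature_image_distances(D, tag_depth, receiver_depth,
                                  surface_bounces, bottom_bounces)
  v <- v[v > 0]
  if (length(v) == 0L)
    stop("no reflected arrival has signature (", surface_bounces,
         " surface, ", bottom_bounces, " bottom)")
  v <- min(v)
  direct <- .direct_length(tag_depth, receiver_depth, ranges)
  (sqrt(ranges^2 + v^2) - direct) / env$sound_speed
}

#' @export
print.multipath_set <- function(x, ...) {
  cat("<multipath_set>", nrow(x), "reflected arrivals, direct path",
      format(attr(x, "direct_length"), digits = 6), "m\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
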