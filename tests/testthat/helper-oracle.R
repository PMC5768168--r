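# Independent brute-force multipath oracle: unfolds reflections
# recursively by mirroring the source image across the surface and the
# seafloor alternately, never using the closed-form image-depth formula.
# Returns the multiset of reflected paths with length <= max_len as a
# data frame (path_length, surface_bounces, bottom_bounces), sorted.
oracle_multipaths <- function(D, zt, zr, r, max_len) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  depth_cap <- 2L * ceiling(max_len / (2 * D)) + 6L
  expand <- function(z, s, b, last, k) {
    if (k > depth_cap) return(invisible())
    for (side in c("surface", "bottom")) {
      if (identical(side, last)) next
      z2 <- if (side == "surface") -z else 2 * D - z
      s2 <- s + (side == "surface")
      b2 <- b + (side == "bottom")
      v <- abs(z2 - zr)
      L <- sqrt(r^2 + v^2)
      if (L <= max_len)
        acc$rows[[length(acc$rows) + 1L]] <- c(L, s2, b2)
      # images only ever move away from the water column; stop expanding
      # once even the vertical distance alone exceeds the bound by a
      # whole round trip
      if (v <= max_len + 2 * D)
        expand(z2, s2, b2, side, k + 1L)
    }
  }
  expand(zt, 0L, 0L, NULL, 1L)
  if (length(acc$rows) == 0L)
    return(data.frame(path_length = numeric(0),
                      surface_bounces = integer(0),
                      bottom_bounces = integer(0)))
  m <- do.call(rbind, acc$rows)
  out <- data.frame(path_length = m[, 1],
                    surface_bounces = as.integer(m[, 2]),
                    bottom_bounces = as.integer(m[, 3]))
  out[order(out$path_length, out$surface_bounces, out$bottom_bounces), ,
      drop = FALSE]
}

# Random interior geometry in one of the reference water depths.
random_geometry <- function(D = sample(c(25, 215, 300), 1)) {
  list(D = D,
       zt = runif(1, 0.5, D - 0.5),
       zr = runif(1, 0.5, D - 0.5),
       r = runif(1, 0, 1000))
}
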