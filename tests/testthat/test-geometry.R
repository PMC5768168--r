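test_that("heights above the seafloor convert to depths below the surface", {
  env <- acoustic_env(300)
  expect_equal(heights_to_depths(env, 1, 1),
               list(tag_depth = 299, receiver_depth = 299))
  expect_equal(heights_to_depths(env, 0, 0),
               list(tag_depth = 300, receiver_depth = 300))
  sh <- heights_to_depths(acoustic_env(25), tag_height = 7.5,
                          receiver_height = 15)
  expect_equal(sh$tag_depth, 17.5)
  expect_equal(sh$receiver_depth, 10)
  expect_error(heights_to_depths(env, -1, 5), "-1")
  expect_error(heights_to_depths(env, 5, 301), "301")
})

test_that("constructors reject physically impossible inputs", {
  expect_error(acoustic_env(-10), "water_depth")
  expect_error(acoustic_env(100, 0), "sound_speed")
  env <- acoustic_env(100)
  expect_error(pair_geometry(env, 150, 50, 10), "water column")
  expect_error(pair_geometry(env, 50, 50, -1), "horizontal_range")
  expect_error(receiver_spec(amdr = -5), "amdr")
  expect_error(receiver_spec(843, blanking_interval = 0), "blanking")
  expect_error(receiver_spec(843, pings_per_train = 5), "pings_per_train")
})

test_that("forced geometries yield the expected single arrivals", {
  env <- acoustic_env(300)
  geom <- pair_geometry(env, 299, 299, 0)
  # both units 1 m off the bottom, colocated: only the seafloor bounce
  # (vertical image distance 2 m) fits under 10 m
  mp <- enumerate_multipaths(env, geom, max_path_length = 10)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$surface_bounces, 0L)
  expect_equal(mp$bottom_bounces, 1L)
  expect_equal(mp$vertical_image_distance, 2)
  expect_equal(mp$path_length, 2)
  expect_equal(mp$relative_delay, 2 / 1530)
  # widen the bound: the surface bounce shows up at v = zt + zr = 598
  mp2 <- enumerate_multipaths(env, geom, max_path_length = 843)
  surf <- mp2[mp2$surface_bounces == 1L & mp2$bottom_bounces == 0L, ]
  expect_equal(surf$vertical_image_distance, 598)
  expect_equal(surf$path_length, 598)
  # shallow off-axis case: surface bounce length by Pythagoras
  env25 <- acoustic_env(25)
  mp3 <- enumerate_multipaths(env25, pair_geometry(env25, 17.5, 24, 100),
                              max_path_length = 300)
  surf3 <- mp3[mp3$surface_bounces == 1L & mp3$bottom_bounces == 0L, ]
  expect_equal(surf3$vertical_image_distance, 41.5)
  expect_equal(surf3$path_length, sqrt(100^2 + 41.5^2), tolerance = 1e-12)
})

test_that("enumeration equals the reflection-unfolding oracle", {
  set.seed(101)
  for (i in 1:120) {
    g <- random_geometry()
    ml <- runif(1, 50, 2000)
    o <- oracle_multipaths(g$D, g$zt, g$zr, g$r, ml)
    env <- acoustic_env(g$D)
    e <- enumerate_multipaths(env, pair_geometry(env, g$zt, g$zr, g$r), ml)
    expect_equal(nrow(e), nrow(o))
    expect_equal(e$path_length, o$path_length, tolerance = 1e-9)
    expect_equal(e$surface_bounces, o$surface_bounces)
    expect_equal(e$bottom_bounces, o$bottom_bounces)
  }
})

test_that("the direct path is shortest and delays behave", {
  set.seed(7)
  for (i in 1:40) {
    g <- random_geometry()
    env <- acoustic_env(g$D)
    geom <- pair_geometry(env, g$zt, g$zr, g$r)
    mp <- enumerate_multipaths(env, geom, 1500)
    expect_true(all(mp$path_length >= attr(mp, "direct_length")))
    expect_true(all(mp$relative_delay >= 0))
    expect_true(all(diff(mp$path_length) >= -1e-12))
    expect_true(all(mp$surface_bounces + mp$bottom_bounces >= 1L))
    expect_equal(mp$amplitude_scalar, 1 / mp$path_length)
    # colocated in range: delay is exactly v / c
    geom0 <- pair_geometry(env, g$zt, g$zr, 0)
    mp0 <- enumerate_multipaths(env, geom0, 1500)
    v0 <- mp0$vertical_image_distance
    expect_equal(mp0$relative_delay,
                 (sqrt(v0^2) - abs(g$zt - g$zr)) / 1530, tolerance = 1e-12)
  }
})

test_that("enumeration is complete: a larger order bound adds nothing", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_geometry()
    env <- acoustic_env(g$D)
    geom <- pair_geometry(env, g$zt, g$zr, g$r)
    ml <- runif(1, 100, 2000)
    full <- enumerate_multipaths(env, geom, ml)
    # enumerate far beyond the bound, then filter back down
    wider <- enumerate_multipaths(env, geom, ml + 6 * g$D)
    refiltered <- wider[wider$path_length <= ml, ]
    expect_equal(nrow(full), nrow(refiltered))
    expect_equal(full$path_length, refiltered$path_length,
                 tolerance = 1e-9)
  }
})

test_that("max_arrivals keeps only the shortest reflected paths", {
  env <- acoustic_env(50)
  geom <- pair_geometry(env, 49, 49, 0)
  all_paths <- enumerate_multipaths(env, geom, 843)
  top4 <- enumerate_multipaths(env, geom, 843, max_arrivals = 4)
  expect_equal(nrow(top4), 4L)
  expect_equal(top4$path_length, all_paths$path_length[1:4])
})

test_that("relative delay decreases with range and hits known values", {
  env <- acoustic_env(1000)
  # equal depths, colocated: first surface bounce delay = 2z / c
  expect_equal(relative_delay_curve(env, 50, 50, 0), 100 / 1530)
  env300 <- acoustic_env(300)
  d <- relative_delay_curve(env300, 299, 299, ranges = c(0, 250))
  expect_lt(d[2], d[1])
  dd <- relative_delay_curve(env300, 299, 299, ranges = seq(0, 900, 50))
  expect_true(all(diff(dd) < 0))
  # the range where the surface-bounce delay equals a 260 ms blanking
  # interval solves sqrt(r^2 + 598^2) - r = 397.8
  r_star <- (598^2 - 397.8^2) / (2 * 397.8)
  expect_equal(relative_delay_curve(env300, 299, 299, r_star), 0.260,
               tolerance = 1e-9)
  expect_error(relative_delay_curve(env300, 299, 299, 100,
                                    surface_bounces = 0,
                                    bottom_bounces = 0),
               "no reflected arrival")
})
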