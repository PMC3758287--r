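test_that("wound frames have orthonormal axes pointing at the wound", {
  f <- build_wound_frame(c(90, 100, 10, 90), c(100, 100), "right")
  expect_equal(f$c_axis, c(1, 0)); expect_equal(f$r_axis, c(0, 1))
  f2 <- build_wound_frame(c(10, 90, 1, 10), c(100, 100), "top")
  expect_equal(f2$c_axis, c(0, -1)); expect_equal(f2$r_axis, c(1, 0))
  f3 <- build_wound_frame(c(40, 60, 40, 60), c(100, 100), 30)
  expect_equal(f3$c_axis, c(cos(pi / 6), -sin(pi / 6)))
  expect_equal(sum(f3$c_axis * f3$r_axis), 0)
  expect_equal(sqrt(sum(f3$r_axis^2)), 1)
  expect_error(build_wound_frame(c(50, 50, 10, 20), c(100, 100), "right"),
               "degenerate")
})

test_that("displacements decompose into oriented and lateral components", {
  f <- build_wound_frame(c(90, 100, 10, 90), c(100, 100), "right")
  d1 <- displacement_components(c(10, 20), c(12, 20), f)
  expect_equal(d1$oriented_distance, 2)
  expect_equal(d1$lateral_distance, 0)
  expect_equal(d1$effective_velocity, 1)
  d2 <- displacement_components(c(10, 20), c(10, 23), f)
  expect_equal(d2$oriented_distance, 0)
  expect_equal(d2$lateral_distance, 3)
  expect_equal(d2$effective_velocity, 0)
  d3 <- displacement_components(c(10, 20), c(9, 21), f)
  expect_equal(d3$effective_velocity, -1 / sqrt(2))
  # zero displacement scores 0, not NaN
  expect_equal(displacement_components(c(5, 5), c(5, 5),
                                       f)$effective_velocity, 0)
})

test_that("oriented^2 + lateral^2 + z^2 = absolute^2 on random steps", {
  set.seed(23)
  f <- build_wound_frame(c(40, 60, 40, 60), c(100, 100),
                         runif(1, 0, 360))
  for (i in 1:50) {
    p0 <- runif(3, 0, 100); p1 <- p0 + rnorm(3, 0, 4)
    dc <- displacement_components(p0, p1, f)
    expect_equal(dc$oriented_distance^2 + dc$lateral_distance^2 +
                   dc$z_distance^2, dc$absolute_distance^2)
  }
})

test_that("effective velocity is invariant under joint rotation", {
  set.seed(8)
  p0 <- c(30, 40); p1 <- c(34, 37)
  for (a in c(0, 20, 110, 250)) {
    f <- build_wound_frame(c(40, 60, 40, 60), c(100, 100), a)
    a2 <- a * pi / 180
    # the map taking the frame's axes onto the angle-0 axes
    rot <- matrix(c(cos(a2), sin(a2), -sin(a2), cos(a2)), 2)
    q0 <- as.vector(rot %*% p0); q1 <- as.vector(rot %*% p1)
    f0 <- build_wound_frame(c(40, 60, 40, 60), c(100, 100), 0)
    expect_equal(displacement_components(q0, q1, f0)$effective_velocity,
                 displacement_components(p0, p1, f)$effective_velocity)
  }
})

mk_track_set <- function(paths, volume = 100) {
  link_sequence(nodes_from_paths(paths, volume),
                keyhole_params(first_link_radius = 30, min_keyhole = 15))
}

test_that("meandering index hits its anchor values", {
  f <- build_wound_frame(c(90, 100, 10, 90), c(100, 100), "right")
  # straight track: index 1
  tm1 <- track_metrics(mk_track_set(straight_paths(1, 10)), f)
  expect_equal(tm1$meandering_index, 1)
  # out-and-back: index 0
  paths2 <- data.frame(cell = 1, t = 1:9,
                       x = c(10, 12, 14, 16, 18, 16, 14, 12, 10),
                       y = 50, z = 5)
  expect_equal(track_metrics(mk_track_set(paths2), f)$meandering_index, 0)
  # L-shaped track, legs 3 and 4: index 5/7
  paths3 <- data.frame(cell = 1, t = 1:8,
                       x = c(10, 11, 12, 13, 13, 13, 13, 13),
                       y = c(50, 50, 50, 50, 51, 52, 53, 54), z = 5)
  expect_equal(track_metrics(mk_track_set(paths3), f)$meandering_index,
               5 / 7)
})

test_that("track velocities convert to physical units when metadata given", {
  f <- build_wound_frame(c(90, 100, 10, 90), c(100, 100), "right")
  ts <- mk_track_set(straight_paths(1, 5, step = 2))
  tm_px <- track_metrics(ts, f)
  expect_equal(tm_px$velocity, 2)            # px/frame
  tm_um <- track_metrics(ts, f, voxel_size = c(0.5, 0.5, 2),
                         frame_interval = 0.5)
  expect_equal(tm_um$velocity, 2)            # 1 um per 0.5 min
})

test_that("population metrics count wound behaviour on a hand-built fixture", {
  f <- build_wound_frame(c(80, 100, 1, 100), c(100, 100), "right")
  # three cells: enters and stays, enters and leaves, never enters
  paths <- rbind(
    data.frame(cell = 1, t = 1:6, x = c(70, 75, 81, 85, 88, 90), y = 20,
               z = 0),
    data.frame(cell = 2, t = 1:6, x = c(70, 76, 82, 88, 76, 70), y = 50,
               z = 0),
    data.frame(cell = 3, t = 1:6, x = c(10, 12, 14, 16, 18, 20), y = 80,
               z = 0))
  ts <- mk_track_set(paths)
  pm <- population_metrics(ts, f, min_track_length = 2)
  expect_equal(pm$in_wound_neutrophils, 2)
  expect_equal(pm$transiting_wound_neutrophils, 1)
  expect_equal(pm$n_displacements, 15)
  # hand count: cells 1 and 3 always head for the wound (5 + 5 steps),
  # cell 2 approaches for 3 steps then retreats for 2
  expect_equal(pm$forward_ratio, 13 / 15)
  expect_equal(pm$backward_ratio, 2 / 15)
  # displacements ending inside x >= 80: 4 (cell 1) + 2 (cell 2)
  expect_equal(pm$in_wound_ratio, 6 / 15)
  # 8 post-arrival displacements across cells 1 and 2
  expect_equal(pm$in_wound_ratio_2, 6 / 8)
  # idle population inside the wound
  idle <- data.frame(cell = 1, t = 1:5, x = 90, y = 50, z = 0)
  ts_idle <- link_sequence(nodes_from_paths(idle),
                           keyhole_params(first_link_radius = 5,
                                          min_keyhole = 2))
  pm_idle <- population_metrics(ts_idle, f, min_track_length = 2)
  expect_equal(pm_idle$idle_wound_ratio, 1)
  expect_equal(pm_idle$in_wound_neutrophils, 1)
  expect_equal(pm_idle$in_wound_ratio, 1)
})

test_that("all-forward motion gives forward_ratio 1 and backward_ratio 0", {
  f <- build_wound_frame(c(90, 100, 1, 100), c(100, 100), "right")
  ts <- mk_track_set(straight_paths(3, 8, step = 3))
  pm <- population_metrics(ts, f)
  expect_equal(pm$forward_ratio, 1)
  expect_equal(pm$backward_ratio, 0)
  # the literal reading duplicates the forward-type criterion
  pm_lit <- population_metrics(ts, f, literal_ratios = TRUE)
  expect_equal(pm_lit$backward_ratio, 1)
  # mirrored definitions can never sum above 1
  expect_lte(pm$forward_ratio + pm$backward_ratio, 1)
})

test_that("empty denominators give NA ratios, not zero", {
  f <- build_wound_frame(c(90, 100, 1, 100), c(100, 100), "right")
  ts <- mk_track_set(straight_paths(1, 5))  # never reaches the wound
  pm <- population_metrics(ts, f)
  expect_true(is.na(pm$in_wound_ratio_2))
  expect_true(is.na(pm$idle_wound_ratio))
  expect_equal(pm$in_wound_neutrophils, 0)
})

test_that("a 500-column field with 20-column bands yields 25 bands", {
  bp <- band_partition(500, 20)
  expect_equal(nrow(bp), 25)
  expect_equal(bp$col_min[1], 1)
  expect_equal(bp$col_max[25], 500)
  expect_true(all(diff(bp$col_min) == 20))
})

test_that("volume profile normalisation and the flat-volume null", {
  set.seed(2)
  paths <- do.call(rbind, lapply(1:4, function(i)
    data.frame(cell = i, t = 1:40, x = 5 + 12 * (1:40) + rnorm(40, 0, .2),
               y = 30 * i, z = 5)))
  nodes <- nodes_from_paths(paths, volume = 120)
  nodes$volume <- nodes$volume + rnorm(nrow(nodes), 0, 2)
  ts <- link_sequence(nodes, keyhole_params(first_link_radius = 20,
                                            min_keyhole = 13))
  vp <- volume_position_profile(ts, n_bands = 24, band_width = 20,
                                min_duration = 30, min_velocity = 2)
  expect_equal(vp$n_tracks, 4)
  # grand mean of normalised node volumes is 1 by construction
  expect_equal(sum(vp$bands$mean_volume * vp$bands$n_nodes) /
                 sum(vp$bands$n_nodes), 1, tolerance = 1e-10)
  expect_lt(abs(vp$fit$slope), 0.005)
  expect_gt(vp$fit$p_value, 0.05)
})

test_that("the profile filters name their thresholds when nothing survives", {
  ts <- mk_track_set(straight_paths(1, 5))
  expect_error(volume_position_profile(ts), "duration")
})
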