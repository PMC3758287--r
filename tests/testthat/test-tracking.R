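kp0 <- keyhole_params(first_link_radius = 3, min_keyhole = 0)

test_that("keyhole membership follows the wedge/sphere geometry", {
  # straight continuation: dead centre of the wedge
  k <- keyhole_contains(kp0, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(k$inside); expect_equal(k$distance, 0)
  # lateral step: inside via the truncated sphere
  expect_true(keyhole_contains(kp0, c(0, 0, 0), c(1, 0, 0),
                               c(1, 0.5, 0))$inside)
  # beyond the wedge reach (3x the previous displacement)
  expect_false(keyhole_contains(kp0, c(0, 0, 0), c(1, 0, 0),
                                c(10, 0, 0))$inside)
  # lateral step beyond the sphere radius (1x displacement)
  expect_false(keyhole_contains(kp0, c(0, 0, 0), c(1, 0, 0),
                                c(1, 1.5, 0))$inside)
  # no history: plain sphere of first_link_radius
  expect_true(keyhole_contains(kp0, NULL, c(5, 5, 5), c(7, 5, 5))$inside)
  expect_false(keyhole_contains(kp0, NULL, c(5, 5, 5), c(9, 5, 5))$inside)
})

test_that("wedge and truncated sphere partition the angular range", {
  expect_error(keyhole_params(wedge_angle = 60, circle_angle = 290),
               "360")
  # a candidate at fixed radius flips region exactly at the half-angle
  gp <- c(0, 0, 0); p <- c(2, 0, 0); d <- 2
  for (ang_deg in c(0, 15, 29.9, 30.1, 60, 120, 179)) {
    a <- ang_deg * pi / 180
    r <- 0.9 * d  # inside sphere radius; inside wedge reach too
    cand <- p + r * c(cos(a), sin(a), 0)
    k <- keyhole_contains(kp0, gp, p, cand)
    expect_true(k$inside, info = paste("angle", ang_deg))
  }
  # between sphere radius and wedge reach, only the wedge sector remains
  for (ang_deg in c(0, 20, 29)) {
    cand <- p + 1.5 * d * c(cos(ang_deg * pi / 180),
                            sin(ang_deg * pi / 180), 0)
    expect_true(keyhole_contains(kp0, gp, p, cand)$inside)
  }
  for (ang_deg in c(31, 90, 170)) {
    cand <- p + 1.5 * d * c(cos(ang_deg * pi / 180),
                            sin(ang_deg * pi / 180), 0)
    expect_false(keyhole_contains(kp0, gp, p, cand)$inside)
  }
})

test_that("keyhole test agrees with the analytic-geometry oracle", {
  set.seed(31)
  n_bad <- 0
  for (i in 1:2000) {
    gp <- runif(3, 0, 20); p <- gp + rnorm(3, 0, 2)
    cand <- p + rnorm(3, 0, 3)
    k <- keyhole_contains(kp0, gp, p, cand)
    expect_identical(k$inside, keyhole_oracle(kp0, gp, p, cand))
  }
})

test_that("an isolated object is linked into a single track", {
  nodes <- nodes_from_paths(straight_paths(1, 10))
  ts <- link_sequence(nodes, keyhole_params())
  expect_length(ts$tracks, 1)
  expect_length(ts$tracks[[1]], 10)
  n <- ts$nodes
  expect_true(all(diff(n$t[match(ts$tracks[[1]], n$node_id)]) == 1))
})

test_that("parallel tracks do not switch and match exhaustive assignment", {
  set.seed(17)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    paths <- straight_paths(k, 8, spacing = 50)
    paths$x <- paths$x + rnorm(nrow(paths), 0, 0.2)
    paths$y <- paths$y + rnorm(nrow(paths), 0, 0.2)
    nodes0 <- nodes_from_paths(paths)
    kp <- keyhole_params(first_link_radius = 6, gap_roi_radius = 4,
                         min_keyhole = 3)
    ts <- link_sequence(nodes0, kp)
    nodes <- ts$nodes
    expect_length(ts$tracks, k)
    # every track follows one cell
    for (tr in ts$tracks) {
      cells <- nodes$frame_label[match(tr, nodes$node_id)]
      expect_length(unique(cells), 1)
    }
    # frame-by-frame links equal the exhaustive minimum-cost matching
    pos <- as.matrix(nodes[, c("x", "y", "z")])
    for (t in 1:7) {
      pr <- which(nodes$t == t); ch <- which(nodes$t == t + 1)
      feas <- matrix(FALSE, length(pr), length(ch))
      cost <- matrix(Inf, length(pr), length(ch))
      for (a in seq_along(pr)) for (b in seq_along(ch)) {
        gp <- if (!is.na(nodes$parent_id[pr[a]]))
          pos[match(nodes$parent_id[pr[a]], nodes$node_id), ] else NULL
        kc <- keyhole_contains(kp, gp, pos[pr[a], ],
                               matrix(pos[ch[b], ], 1))
        feas[a, b] <- kc$inside; cost[a, b] <- kc$distance
      }
      opt <- exhaustive_match(feas, cost, length(pr), length(ch))
      links <- which(!is.na(nodes$child_id[pr]))
      got <- cbind(links,
                   match(match(nodes$child_id[pr[links]], nodes$node_id),
                         ch))
      expect_equal(unname(got[order(got[, 1]), , drop = FALSE]),
                   unname(opt[order(opt[, 1]), , drop = FALSE]))
    }
  }
})

test_that("tracking is deterministic given the node table", {
  set.seed(5)
  paths <- straight_paths(3, 12)
  paths$x <- paths$x + rnorm(nrow(paths), 0, 0.5)
  nodes <- nodes_from_paths(paths)
  ts1 <- link_sequence(nodes, keyhole_params())
  ts2 <- link_sequence(nodes, keyhole_params())
  expect_identical(ts1$tracks, ts2$tracks)
  expect_identical(ts1$nodes, ts2$nodes)
})

test_that("backward validation removes an implausible first node", {
  # a clean 1 px/frame track whose claimed first node is 20 px off the
  # backward prediction
  paths <- data.frame(cell = 1, t = 1:8,
                      x = c(30, 10, 11, 12, 13, 14, 15, 16),
                      y = 5, z = 5)
  nodes <- nodes_from_paths(paths)
  kp <- keyhole_params(first_link_radius = 25, min_keyhole = 1)
  ts <- link_sequence(nodes, kp)
  expect_length(ts$tracks, 1)           # the generous first link takes it
  ts2 <- backward_validate(ts)
  len <- sort(lengths(ts2$tracks))
  expect_equal(len, c(1, 7))            # first node cut loose
  # a straight constant-velocity track is untouched
  ts3 <- backward_validate(link_sequence(
    nodes_from_paths(straight_paths(1, 10)), keyhole_params()))
  expect_length(ts3$tracks, 1)
  expect_length(ts3$tracks[[1]], 10)
})

test_that("backward validation leaves sub-3-node tracks alone", {
  nodes <- nodes_from_paths(straight_paths(1, 2))
  ts <- backward_validate(link_sequence(nodes, keyhole_params()))
  expect_length(ts$tracks, 1)
  expect_length(ts$tracks[[1]], 2)
})

test_that("single-frame gaps are bridged with interpolated nodes", {
  paths <- straight_paths(1, 10)
  paths <- paths[paths$t != 6, ]
  nodes <- nodes_from_paths(paths)
  ts <- bridge_gaps(link_sequence(nodes, keyhole_params()))
  expect_length(ts$tracks, 1)
  expect_length(ts$tracks[[1]], 10)
  n <- ts$nodes
  mid <- n[n$interpolated, ]
  expect_equal(nrow(mid), 1)
  expect_equal(mid$t, 6)
  expect_equal(mid$x, mean(paths$x[paths$t %in% c(5, 7)]))
  expect_equal(mid$volume, 100)
  # far-apart endpoints stay separate
  paths2 <- straight_paths(1, 10)
  paths2$y[paths2$t >= 7] <- paths2$y[paths2$t >= 7] + 100
  paths2 <- paths2[paths2$t != 6, ]
  ts2 <- bridge_gaps(link_sequence(nodes_from_paths(paths2),
                                   keyhole_params(gap_roi_radius = 10)))
  expect_length(ts2$tracks, 2)
})

test_that("a blinking cell is reassembled across repeated gaps", {
  paths <- straight_paths(1, 11, step = 1.5)
  paths <- paths[paths$t %% 2 == 1, ]   # visible on odd frames only
  nodes <- nodes_from_paths(paths)
  ts <- bridge_gaps(link_sequence(nodes,
                                  keyhole_params(first_link_radius = 5,
                                                 gap_roi_radius = 5)))
  expect_length(ts$tracks, 1)
  expect_length(ts$tracks[[1]], 11)     # full duration restored
  expect_equal(sum(ts$nodes$interpolated), 5)
})

collision_sequence <- function() {
  t_all <- 1:11
  x1 <- c(10, 13, 16, 19, 22, 22, 22, 19, 16, 13, 10)
  x2 <- c(40, 37, 34, 31, 28, 28, 28, 31, 34, 37, 40)
  stacks <- lapply(t_all, function(t) {
    st <- sphere_stack(rbind(c(x1[t], 20, 6), c(x2[t], 20, 6)), r = 4.5)
    st$time_index <- t
    st
  })
  volume_sequence(stacks)
}

test_that("collisions are split by watershed into two continuous tracks", {
  sq <- collision_sequence()
  labeled <- segment_sequence(sq, thresholds = c(50, 150))
  vols_before <- vapply(labeled, function(l) sum(l$records$volume),
                        numeric(1))
  ts <- link_sequence(node_table(labeled), keyhole_params())
  rc <- resolve_collisions(ts, labeled)
  expect_true(any(rc$events$type == "merge" & rc$events$resolved))
  expect_length(rc$track_set$tracks, 2)
  expect_equal(sort(lengths(rc$track_set$tracks)), c(11, 11))
  n <- rc$track_set$nodes
  # per-frame split volumes sum to the merged volume: exact conservation
  expect_equal(as.numeric(tapply(n$volume, n$t, sum)),
               unname(vols_before))
  # the merged pair separating again is seen as a division event
  expect_true(any(rc$events$type == "division") ||
                length(rc$track_set$tracks) == 2)
})

test_that("a modest volume step without a terminating neighbour is no event", {
  paths <- straight_paths(2, 8, spacing = 60)
  nodes <- nodes_from_paths(paths)
  nodes$volume <- 100
  nodes$volume[nodes$t >= 5 & nodes$frame_label == 1] <- 110  # 1.1x step
  ts <- link_sequence(nodes, keyhole_params())
  rc <- resolve_collisions(ts, list())
  expect_equal(nrow(rc$events), 0)
  expect_length(rc$track_set$tracks, 2)
})

test_that("track editing: break and merge are inverse, delete excludes nodes", {
  nodes <- nodes_from_paths(straight_paths(1, 10))
  ts <- link_sequence(nodes, keyhole_params())
  b <- edit_tracks(ts, "break", track = 1, at = 6)
  expect_length(b$tracks, 2)
  expect_equal(sort(lengths(b$tracks)), c(5, 5))
  expect_error(edit_tracks(ts, "break", track = 1, at = 1), "endpoint")
  m <- edit_tracks(b, "merge", track = 1, track2 = 2)
  expect_length(m$tracks, 1)
  expect_equal(m$tracks[[1]], ts$tracks[[1]])
  expect_length(attr(m, "audit"), 2)
  # merging temporally overlapping tracks is refused
  paths2 <- straight_paths(2, 6, spacing = 40)
  ts2 <- link_sequence(nodes_from_paths(paths2), keyhole_params())
  expect_error(edit_tracks(ts2, "merge", track = 1, track2 = 2),
               "disjoint")
  # deletion removes the track's nodes from subsequent metrics
  d <- edit_tracks(ts2, "delete", track = 2)
  expect_length(d$tracks, 1)
  frame <- build_wound_frame(c(50, 60, 10, 80), c(100, 100), "right")
  pm_all <- population_metrics(ts2, frame)
  pm_del <- population_metrics(d, frame)
  expect_equal(pm_del$n_displacements, pm_all$n_displacements / 2)
})

test_that("a merge across a one-frame gap interpolates the missing node", {
  paths <- straight_paths(1, 9)
  paths <- paths[paths$t != 5, ]
  nodes <- nodes_from_paths(paths)
  kp <- keyhole_params(gap_roi_radius = 0.1)  # too tight to auto-bridge
  ts <- bridge_gaps(link_sequence(nodes, kp))
  expect_length(ts$tracks, 2)
  m <- edit_tracks(ts, "merge", track = 1, track2 = 2)
  expect_length(m$tracks, 1)
  expect_equal(sum(m$nodes$interpolated), 1)
})
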