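# Fixture builders and independent oracles shared across the suite.

# --- geometry fixtures ------------------------------------------------------

# Solid sphere(s) rendered into a 3D array of given background/amplitude.
sphere_stack <- function(centres, r = 4.5, dims = c(40, 60, 12),
                         amplitude = 200, background = 10,
                         time_index = 1L) {
  arr <- array(background, dims)
  if (is.null(dim(centres))) centres <- matrix(centres, nrow = 1)
  for (i in seq_len(nrow(centres))) {
    cc <- centres[i, ]
    xs <- max(1, floor(cc[1] - r)):min(dims[2], ceiling(cc[1] + r))
    zs <- max(1, floor(cc[3] - r)):min(dims[3], ceiling(cc[3] + r))
    ys <- seq_len(dims[1])
    for (z in zs) for (x in xs) {
      d2 <- (x - cc[1])^2 + (ys - cc[2])^2 + (z - cc[3])^2
      arr[ys[d2 <= r^2], x, z] <- background + amplitude
    }
  }
  volume_stack(arr, time_index, bit_depth = 8L)
}

# Node table built directly from per-cell path matrices (perfect centroids).
nodes_from_paths <- function(paths, volume = 100) {
  # paths: data.frame(cell, t, x, y, z)
  nodes <- data.frame(t = paths$t, x = paths$x, y = paths$y, z = paths$z,
                      volume = volume, mean_intensity = NA_real_,
                      frame_label = paths$cell)
  nodes <- nodes[order(nodes$t, nodes$frame_label), ]
  nodes$node_id <- seq_len(nrow(nodes))
  nodes$parent_id <- NA_integer_
  nodes$child_id <- NA_integer_
  nodes$track_id <- NA_integer_
  nodes$interpolated <- FALSE
  rownames(nodes) <- NULL
  class(nodes) <- c("node_table", "data.frame")
  nodes
}

straight_paths <- function(n_cells, n_t, spacing = 50, step = 2) {
  do.call(rbind, lapply(seq_len(n_cells), function(i)
    data.frame(cell = i, t = seq_len(n_t),
               x = 10 + step * (seq_len(n_t) - 1),
               y = i * spacing, z = 5)))
}

# --- independent oracles ----------------------------------------------------

# Flood fill oracle for hysteresis: iterative in-mask dilation from seeds
# using array shifts (no shared code with the package's C++ routine).
flood_oracle <- function(arr, low, high, connectivity = 26) {
  d <- dim(arr)
  mask <- arr >= low
  cur <- arr >= high & mask
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$di) + abs(offs$dj) + abs(offs$dk) == 1, ]
  shift <- function(m, di, dj, dk) {
    out <- array(FALSE, d)
    si <- seq_len(d[1]); sj <- seq_len(d[2]); sk <- seq_len(d[3])
    out[si[si + di >= 1 & si + di <= d[1]] + di,
        sj[sj + dj >= 1 & sj + dj <= d[2]] + dj,
        sk[sk + dk >= 1 & sk + dk <= d[3]] + dk] <-
      m[si[si + di >= 1 & si + di <= d[1]],
        sj[sj + dj >= 1 & sj + dj <= d[2]],
        sk[sk + dk >= 1 & sk + dk <= d[3]]]
    out
  }
  repeat {
    grown <- cur
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift(cur, offs$di[r], offs$dj[r], offs$dk[r])
    grown <- grown & mask
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

# Analytic-geometry oracle for the keyhole: rotates into a canonical frame
# where the previous displacement lies on +x, then applies the definitions
# in spherical terms.
keyhole_oracle <- function(params, gp, p, cand) {
  if (is.null(gp))
    return(sqrt(sum((cand - p)^2)) <= params$first_link_radius)
  v <- p - gp
  d <- sqrt(sum(v^2))
  if (d < params$idle_tol)
    return(sqrt(sum((cand - p)^2)) <= params$first_link_radius)
  # orthonormal basis with e1 along v
  e1 <- v / d
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- helper - sum(helper * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rel <- cand - p
  u <- c(sum(rel * e1), sum(rel * e2), sum(rel * e3))
  r <- sqrt(sum(u^2))
  if (r == 0) return(TRUE)
  ang <- acos(min(1, max(-1, u[1] / r))) * 180 / pi
  floorr <- if (is.na(params$min_keyhole)) 0 else params$min_keyhole
  if (r <= floorr) return(TRUE)
  if (ang <= params$wedge_angle / 2)
    r <= params$wedge_reach * d
  else
    r <= params$circle_radius * d
}

# Exhaustive minimum-cost one-to-one matching between two frames, over
# keyhole-feasible pairs only. Enumerates all injective assignments.
exhaustive_match <- function(feas, cost, np, nc) {
  # feas/cost: np x nc logical / numeric
  best <- NULL; best_cost <- Inf; best_size <- -1L
  rec <- function(p, used, pairs, tot) {
    if (p > np) {
      size <- nrow(pairs)
      if (size > best_size || (size == best_size && tot < best_cost)) {
        best <<- pairs; best_cost <<- tot; best_size <<- size
      }
      return(invisible())
    }
    rec(p + 1L, used, pairs, tot)  # parent p unmatched
    for (c in seq_len(nc))
      if (feas[p, c] && !used[c])
        rec(p + 1L, `[<-`(used, c, TRUE),
            rbind(pairs, c(p, c)), tot + cost[p, c])
  }
  rec(1L, logical(nc), matrix(integer(), 0, 2), 0)
  best
}

# --- cached synthetic benchmark for the acceptance tests --------------------

.fixture_cache <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.fixture_cache$bench)) {
    spec <- synthetic_spec()
    gd <- generate_dataset(spec, seed = 1L)
    prof <- clean_class_profiles(gd$sequence, spec)
    sigma <- calibrate_noise_levels(prof, c(1.61, 1.25, 1, 0.66, 0.45))
    gold_red <- gd$gold
    gold_red$x <- to_reduced_coords(gold_red$x)
    gold_red$y <- to_reduced_coords(gold_red$y)
    .fixture_cache$bench <- list(spec = spec, clean = gd$sequence,
                                 gold = gd$gold, gold_red = gold_red,
                                 profiles = prof, sigma = sigma)
  }
  .fixture_cache$bench
}

# mean in-plane half-maximum radius of the default blob, on the reduced grid
default_cell_radius_reduced <- function(spec = synthetic_spec()) {
  sqrt(2 * log(2)) * mean(spec$width_xy) / 2
}
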