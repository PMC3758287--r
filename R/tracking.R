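#' Build a node table from labelled stacks
#'
#' Every segmented object becomes a node carrying its centroid, volume and
#' frame label, with empty parent/child/track fields ready for linking.
#'
#' @param labeled list of `labeled_stack` objects.
#' @return Data frame of class `node_table` with columns `node_id, t, x, y,
#'   z, volume, mean_intensity, frame_label, parent_id, child_id, track_id,
#'   interpolated`.
#' @export
node_table <- function(labeled) {
  rows <- lapply(labeled, function(l) {
    r <- l$records
    if (!nrow(r)) return(NULL)
    data.frame(t = l$time_index, x = r$x, y = r$y, z = r$z,
               volume = as.numeric(r$volume),
               mean_intensity = if ("mean_intensity" %in% names(r))
                 r$mean_intensity else NA_real_,
               frame_label = r$label)
  })
  nodes <- do.call(rbind, rows)
  if (is.null(nodes))
    nodes <- data.frame(t = integer(), x = numeric(), y = numeric(),
                        z = numeric(), volume = numeric(),
                        mean_intensity = numeric(), frame_label = integer())
  nodes <- nodes[order(nodes$t, nodes$frame_label), , drop = FALSE]
  nodes$node_id <- seq_len(nrow(nodes))
  nodes$parent_id <- rep(NA_integer_, nrow(nodes))
  nodes$child_id <- rep(NA_integer_, nrow(nodes))
  nodes$track_id <- rep(NA_integer_, nrow(nodes))
  nodes$interpolated <- rep(FALSE, nrow(nodes))
  rownames(nodes) <- NULL
  class(nodes) <- c("node_table", "data.frame")
  nodes[, c("node_id", "t", "x", "y", "z", "volume", "mean_intensity",
            "frame_label", "parent_id", "child_id", "track_id",
            "interpolated")]
}

#' Keyhole model parameters
#'
#' The keyhole is the union of a narrow wedge (default 60 degrees wide)
#' oriented towards the constant-velocity prediction, for straight-moving
#' cells, and a complementary truncated sphere (default 300 degrees) around
#' the current position, for random-moving cells. Its size scales with the
#' displacement between the two previous time points.
#'
#' @param wedge_angle full wedge opening angle, degrees.
#' @param circle_angle angular extent of the truncated sphere, degrees;
#'   `wedge_angle + circle_angle` must equal 360.
#' @param wedge_reach wedge range as a multiple of the previous
#'   displacement.
#' @param circle_radius truncated-sphere radius as a multiple of the
#'   previous displacement.
#' @param first_link_radius search radius (pixels) when a cell has no
#'   history; `NA` means 3x the median object diameter of the node table.
#' @param collision_volume_ratio volume jump factor that flags a collision.
#' @param gap_roi_radius region-of-interest radius (pixels) for bridging
#'   single-frame gaps; `NA` means 2x the median object diameter.
#' @param idle_tol displacements below this (pixels) count as no history
#'   and fall back to the first-link sphere.
#' @param min_keyhole minimum search radius (pixels): candidates within
#'   this distance of the parent are always inside the keyhole, whatever
#'   the previous displacement. Because the keyhole scales with the
#'   previous displacement it would otherwise collapse below the
#'   centroid-jitter scale for slowly moving cells; a cell can always be
#'   re-found within its own footprint, so the default (`NA`) resolves to
#'   the median object diameter. Use 0 for the literal
#'   displacement-scaled geometry.
#' @param mode `"3d"` (full displacement vectors) or `"2d"` (in-plane
#'   projection, for strongly anisotropic z).
#' @return A list of class `keyhole_params`.
#' @export
keyhole_params <- function(wedge_angle = 60, circle_angle = 300,
                           wedge_reach = 3, circle_radius = 1,
                           first_link_radius = NA,
                           collision_volume_ratio = 1.5,
                           gap_roi_radius = NA, idle_tol = 0.5,
                           min_keyhole = NA, mode = c("3d", "2d")) {
  if (abs(wedge_angle + circle_angle - 360) > 1e-9)
    stop("wedge_angle + circle_angle must equal 360 degrees")
  if (wedge_reach <= 0 || circle_radius <= 0)
    stop("keyhole multipliers must be positive")
  structure(list(wedge_angle = wedge_angle, circle_angle = circle_angle,
                 wedge_reach = wedge_reach, circle_radius = circle_radius,
                 first_link_radius = first_link_radius,
                 collision_volume_ratio = collision_volume_ratio,
                 gap_roi_radius = gap_roi_radius, idle_tol = idle_tol,
                 min_keyhole = min_keyhole, mode = match.arg(mode)),
            class = "keyhole_params")
}

.median_diameter <- function(volumes) {
  v <- volumes[is.finite(volumes) & volumes > 0]
  if (!length(v)) return(6)
  2 * (3 * median(v) / (4 * pi))^(1 / 3)
}

.resolve_radii <- function(params, nodes) {
  dia <- .median_diameter(nodes$volume)
  if (is.na(params$first_link_radius))
    params$first_link_radius <- 3 * dia
  if (is.na(params$gap_roi_radius))
    params$gap_roi_radius <- 2 * dia
  if (is.na(params$min_keyhole))
    params$min_keyhole <- dia
  params
}

.proj <- function(p, mode) if (mode == "2d") c(p[1], p[2], 0) else p

#' Keyhole membership test
#'
#' Predicts the landing position of a cell at the next time point as
#' `parent + (parent - grandparent)` and tests whether a candidate lies in
#' the keyhole: within the wedge (half-angle `wedge_angle/2` about the
#' predicted direction, range `wedge_reach * d` from the parent) or within
#' the complementary truncated sphere (radius `circle_radius * d`), where
#' `d` is the previous displacement. Without history (no grandparent, or
#' previous displacement below `idle_tol`) a plain sphere of radius
#' `first_link_radius` is used and the prediction is the parent position.
#'
#' @param params a [keyhole_params()] (with `first_link_radius` resolved to
#'   a number).
#' @param grandparent position at `t - 1` (length-3 numeric) or `NULL`.
#' @param parent position at `t`.
#' @param candidate position at `t + 1`, or a matrix with one row per
#'   candidate.
#' @return List with logical `inside` and numeric `distance` (to the
#'   predicted landing position), vectorised over candidates.
#' @export
keyhole_contains <- function(params, grandparent, parent, candidate) {
  if (is.null(dim(candidate)))
    candidate <- matrix(candidate, nrow = 1)
  stopifnot(ncol(candidate) == 3)
  parent <- .proj(as.numeric(parent), params$mode)
  cand <- candidate
  if (params$mode == "2d") cand[, 3] <- 0
  v <- NULL
  if (!is.null(grandparent)) {
    v <- parent - .proj(as.numeric(grandparent), params$mode)
    if (sqrt(sum(v^2)) < params$idle_tol) v <- NULL
  }
  rel <- sweep(cand, 2, parent)
  rr <- sqrt(rowSums(rel^2))
  if (is.null(v)) {
    r0 <- params$first_link_radius
    if (is.na(r0)) stop("first_link_radius is unresolved; supply a value")
    return(list(inside = rr <= r0, distance = rr))
  }
  d <- sqrt(sum(v^2))
  predicted <- parent + v
  dist <- sqrt(rowSums(sweep(cand, 2, predicted)^2))
  cosang <- as.vector(rel %*% v) / (rr * d)
  cosang[rr == 0] <- 1                     # zero displacement: on-axis
  half <- cos(params$wedge_angle / 2 * pi / 180)
  in_wedge <- cosang >= half & rr <= params$wedge_reach * d & rr > 0
  in_circle <- cosang < half & rr <= params$circle_radius * d
  in_circle[rr == 0] <- TRUE               # staying put is always reachable
  floorr <- if (is.na(params$min_keyhole)) 0 else params$min_keyhole
  list(inside = in_wedge | in_circle | rr <= floorr, distance = dist)
}

#' Link segmented objects over time with the keyhole model
#'
#' A frame-by-frame forward pass: every object at `t` projects a keyhole at
#' `t + 1` from its own history; all (parent, child) pairs whose child lies
#' inside the parent's keyhole are candidate links, assigned greedily in
#' ascending distance to the predicted landing position, each node used at
#' most once (ties broken by node id). Unassigned children open new tracks.
#'
#' @param nodes a [node_table()].
#' @param params a [keyhole_params()].
#' @return A `track_set`: list with `tracks` (list of node-id vectors,
#'   singletons included), `nodes` (the table with parent/child/track
#'   fields filled) and `params`.
#' @export
link_sequence <- function(nodes, params = keyhole_params()) {
  params <- .resolve_radii(params, nodes)
  nodes <- nodes[order(nodes$t, nodes$node_id), , drop = FALSE]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  if (params$mode == "2d") pos[, 3] <- 0
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  rows_by_t <- split(seq_len(nrow(nodes)), nodes$t)
  times <- as.integer(names(rows_by_t))
  half <- cos(params$wedge_angle / 2 * pi / 180)
  for (ti in seq_len(length(times) - 1L)) {
    if (times[ti + 1L] != times[ti] + 1L) next
    pr <- rows_by_t[[ti]]
    ch <- rows_by_t[[ti + 1L]]
    np <- length(pr); nc <- length(ch)
    # previous displacement per parent (NA rows: no history)
    gp_id <- nodes$parent_id[pr]
    v <- matrix(NA_real_, np, 3)
    has_gp <- !is.na(gp_id)
    if (any(has_gp))
      v[has_gp, ] <- pos[pr[has_gp], , drop = FALSE] -
        pos[id2row[gp_id[has_gp]], , drop = FALSE]
    d <- sqrt(rowSums(v^2))
    hist <- has_gp & !is.na(d) & d >= params$idle_tol
    # squared pairwise distances (np x nc), then a per-parent reach cut
    rr2 <- outer(rowSums(pos[pr, , drop = FALSE]^2),
                 rowSums(pos[ch, , drop = FALSE]^2), `+`) -
      2 * pos[pr, , drop = FALSE] %*% t(pos[ch, , drop = FALSE])
    reach <- ifelse(hist,
                    pmax(params$wedge_reach * d, params$circle_radius * d,
                         params$min_keyhole),
                    params$first_link_radius)
    hits <- which(rr2 <= reach^2)      # reach recycles down columns
    if (!length(hits)) next
    hp <- (hits - 1L) %% np + 1L       # parent index within pr
    hc <- (hits - 1L) %/% np + 1L      # child index within ch
    dx <- pos[ch[hc], 1] - pos[pr[hp], 1]
    dy <- pos[ch[hc], 2] - pos[pr[hp], 2]
    dz <- pos[ch[hc], 3] - pos[pr[hp], 3]
    rr <- sqrt(pmax(rr2[hits], 0))
    h <- hist[hp]
    inside <- logical(length(hits))
    dist <- rr
    inside[!h] <- rr[!h] <= params$first_link_radius
    if (any(h)) {
      vh <- v[hp[h], , drop = FALSE]
      dh <- d[hp[h]]
      rh <- rr[h]
      cosang <- (dx[h] * vh[, 1] + dy[h] * vh[, 2] + dz[h] * vh[, 3]) /
        (rh * dh)
      cosang[rh == 0] <- 1
      in_wedge <- cosang >= half & rh <= params$wedge_reach * dh & rh > 0
      in_circle <- cosang < half & rh <= params$circle_radius * dh
      in_circle[rh == 0] <- TRUE
      inside[h] <- in_wedge | in_circle | rh <= params$min_keyhole
      dist[h] <- sqrt((dx[h] - vh[, 1])^2 + (dy[h] - vh[, 2])^2 +
                        (dz[h] - vh[, 3])^2)
    }
    keep <- which(inside)
    if (!length(keep)) next
    hp <- hp[keep]; hc <- hc[keep]; dist <- dist[keep]
    o <- order(dist, nodes$node_id[pr[hp]], nodes$node_id[ch[hc]])
    take <- .cpp_greedy_assign(hp[o], hc[o], np, nc)
    sel <- o[take]
    nodes$child_id[pr[hp[sel]]] <- nodes$node_id[ch[hc[sel]]]
    nodes$parent_id[ch[hc[sel]]] <- nodes$node_id[pr[hp[sel]]]
  }
  .finish_track_set(nodes, params)
}

# Rebuild the track list from parent/child pointers and assign track ids in
# order of (start time, start node id).
.finish_track_set <- function(nodes, params) {
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  starts <- which(is.na(nodes$parent_id))
  starts <- starts[order(nodes$t[starts], nodes$node_id[starts])]
  tracks <- vector("list", length(starts))
  nodes$track_id <- NA_integer_
  for (k in seq_along(starts)) {
    chain <- integer(0)
    i <- starts[k]
    repeat {
      chain <- c(chain, nodes$node_id[i])
      nodes$track_id[i] <- k
      nx <- nodes$child_id[i]
      if (is.na(nx)) break
      i <- id2row[nx]
    }
    tracks[[k]] <- chain
  }
  structure(list(tracks = tracks, nodes = nodes, params = params),
            class = "track_set")
}

#' Rebuild a track set from a node table's parent/child pointers
#'
#' Reconstructs track membership from an existing node table (for
#' example one re-read from `nodes.csv`) without re-running the linker.
#'
#' @param nodes a [node_table()] with `parent_id`/`child_id` filled.
#' @param params a [keyhole_params()] (carried for later operations).
#' @return A `track_set`.
#' @export
track_set_from_nodes <- function(nodes, params = keyhole_params()) {
  .finish_track_set(nodes, .resolve_radii(params, nodes))
}

#' @export
print.track_set <- function(x, ...) {
  len <- lengths(x$tracks)
  cat(sprintf("<track_set> %d tracks (%d of length >= 2), %d nodes\n",
              length(x$tracks), sum(len >= 2), nrow(x$nodes)))
  invisible(x)
}

#' Track start/end summary
#' @param ts a `track_set`.
#' @return Data frame with track id, start/end time and length.
#' @export
track_summary <- function(ts) {
  n <- ts$nodes
  id2row <- integer(max(n$node_id, 0L)); id2row[n$node_id] <- seq_len(nrow(n))
  data.frame(track_id = seq_along(ts$tracks),
             start_t = vapply(ts$tracks, function(tr) n$t[id2row[tr[1]]],
                              numeric(1)),
             end_t = vapply(ts$tracks,
                            function(tr) n$t[id2row[tr[length(tr)]]],
                            numeric(1)),
             length = lengths(ts$tracks))
}

#' Validate links by running the keyhole model backwards
#'
#' Each link is re-tested with a keyhole built from the two later nodes
#' pointing backward in time: for the link `t -> t+1`, the node at `t + 2`
#' acts as grandparent and the node at `t + 1` as parent; if the node at
#' `t` falls outside that backward keyhole the link is cut. This is
#' especially important for the first link of a track, which was formed
#' without motion history. Tracks shorter than 3 nodes are untouched.
#'
#' @param ts a `track_set`.
#' @param mode `"all"` validates every link, `"first"` only each track's
#'   first link.
#' @return The updated `track_set` (cut-off leading nodes become
#'   singletons).
#' @export
backward_validate <- function(ts, mode = c("all", "first")) {
  mode <- match.arg(mode)
  nodes <- ts$nodes
  params <- ts$params
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  for (tr in ts$tracks) {
    if (length(tr) < 3) next
    links <- if (mode == "first") 1L else seq_len(length(tr) - 2L)
    for (i in links) {
      a <- id2row[tr[i]]; b <- id2row[tr[i + 1]]; c <- id2row[tr[i + 2]]
      kc <- keyhole_contains(params, pos[c, ], pos[b, ],
                             matrix(pos[a, ], nrow = 1))
      if (!kc$inside) {
        nodes$child_id[a] <- NA_integer_
        nodes$parent_id[b] <- NA_integer_
      }
    }
  }
  .finish_track_set(nodes, params)
}

#' Bridge single-frame gaps with interpolated nodes
#'
#' A cell present at `t - 1`, absent at `t` and present again at `t + 1`
#' within a small region of interest is taken to be a faint cell that
#' dipped below threshold. An artificial node is created at `t` (midpoint
#' centroid, mean volume of its neighbours, `interpolated = TRUE`) and the
#' two tracks are merged. When several candidates compete, the nearest pair
#' of endpoints wins, ties broken by lower track id. Applied repeatedly
#' until no gap remains; gaps of exactly one frame are bridged.
#'
#' @param ts a `track_set`.
#' @return The updated `track_set`.
#' @export
bridge_gaps <- function(ts) {
  params <- .resolve_radii(ts$params, ts$nodes)
  nodes <- ts$nodes
  repeat {
    tset <- .finish_track_set(nodes, params)
    nodes <- tset$nodes
    sm <- track_summary(tset)
    id2row <- integer(max(nodes$node_id, 0L))
    id2row[nodes$node_id] <- seq_len(nrow(nodes))
    ends <- vapply(tset$tracks, function(tr) tr[length(tr)], integer(1))
    firsts <- vapply(tset$tracks, function(tr) tr[1], integer(1))
    cand <- vector("list", 0L)
    starts_by_t <- split(seq_along(tset$tracks), sm$start_t)
    for (et in unique(sm$end_t)) {
      bs <- starts_by_t[[as.character(et + 2L)]]
      as_ <- which(sm$end_t == et)
      if (is.null(bs) || !length(as_)) next
      pa <- as.matrix(nodes[id2row[ends[as_]], c("x", "y", "z"),
                            drop = FALSE])
      pb <- as.matrix(nodes[id2row[firsts[bs]], c("x", "y", "z"),
                            drop = FALSE])
      dd <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) -
                   2 * pa %*% t(pb))
      hit <- which(dd <= params$gap_roi_radius)
      if (!length(hit)) next
      ia <- (hit - 1L) %% nrow(dd) + 1L
      ib <- (hit - 1L) %/% nrow(dd) + 1L
      cand[[length(cand) + 1L]] <-
        data.frame(a = as_[ia], b = bs[ib], d = dd[hit])
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || !nrow(cand)) break
    cand <- cand[order(cand$d, cand$a, cand$b), , drop = FALSE]
    used <- logical(length(tset$tracks))
    new_rows <- vector("list", 0L)
    next_id <- max(nodes$node_id)
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (used[a] || used[b]) next
      used[a] <- TRUE; used[b] <- TRUE
      na <- id2row[ends[a]]; nb <- id2row[firsts[b]]
      next_id <- next_id + 1L
      mid <- (nodes[na, c("x", "y", "z")] + nodes[nb, c("x", "y", "z")]) / 2
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        node_id = next_id, t = nodes$t[na] + 1L,
        x = mid$x, y = mid$y, z = mid$z,
        volume = (nodes$volume[na] + nodes$volume[nb]) / 2,
        mean_intensity = NA_real_, frame_label = NA_integer_,
        parent_id = nodes$node_id[na], child_id = nodes$node_id[nb],
        track_id = NA_integer_, interpolated = TRUE)
      nodes$child_id[na] <- next_id
      nodes$parent_id[nb] <- next_id
    }
    if (!length(new_rows)) break
    nodes <- rbind(nodes, do.call(rbind, new_rows))
  }
  .finish_track_set(nodes, params)
}

#' Drop tracks shorter than a minimum length
#'
#' Objects that appear in too few frames (by default, single-frame
#' detections) are usually noise; their nodes are released from track
#' membership and the remaining tracks renumbered.
#'
#' @param ts a `track_set`.
#' @param min_length minimum number of nodes for a track to be kept.
#' @return The filtered `track_set`.
#' @export
filter_tracks <- function(ts, min_length = 2L) {
  keep <- lengths(ts$tracks) >= min_length
  nodes <- ts$nodes
  drop_ids <- unlist(ts$tracks[!keep])
  if (length(drop_ids)) {
    sel <- nodes$node_id %in% drop_ids
    nodes$track_id[sel] <- NA_integer_
  }
  tracks <- ts$tracks[keep]
  # renumber surviving tracks
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  for (k in seq_along(tracks))
    nodes$track_id[id2row[tracks[[k]]]] <- k
  structure(list(tracks = tracks, nodes = nodes, params = ts$params),
            class = "track_set")
}

#' Detect and resolve collisions and divisions
#'
#' A merge is flagged when a node's volume is at least
#' `collision_volume_ratio` times its track's volume at the previous frame
#' and a neighbouring track terminates at that previous frame within
#' `gap_roi_radius`. The merged object is re-split frame by frame with a
#' seeded watershed on the distance transform of its binary mask, seeded
#' from the colliding tracks' previous centroids; the neighbouring track is
#' extended through its half and links are re-attached by nearest distance.
#' Division events (the inverse rules: volume drop plus a new neighbouring
#' track) are detected and logged; when they close a merged interval the
#' split chains are joined to the diverging tracks.
#'
#' @param ts a `track_set`.
#' @param labeled list of `labeled_stack` objects the nodes came from.
#' @param max_events cap on processed merge events (spurious volume jumps
#'   in very noisy segmentations would otherwise dominate the run time;
#'   unprocessed candidates simply stay merged).
#' @return List with `track_set`, `labeled` (labels updated where objects
#'   were split) and `events` (data frame log).
#' @export
resolve_collisions <- function(ts, labeled, max_events = 20L) {
  params <- .resolve_radii(ts$params, ts$nodes)
  events <- data.frame(type = character(), t = integer(),
                       track = integer(), other = integer(),
                       resolved = logical())
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > max_events) break
    found <- .find_merge_event(ts, params, events)
    if (is.null(found)) break
    res <- .process_merge(ts, labeled, params, found)
    events <- rbind(events, res$event)
    ts <- res$ts
    labeled <- res$labeled
  }
  events <- rbind(events, .find_divisions(ts, params))
  list(track_set = ts, labeled = labeled, events = events)
}

.find_merge_event <- function(ts, params, seen) {
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  sm <- track_summary(ts)
  ends_by_t <- split(seq_along(ts$tracks), sm$end_t)
  end_rows <- id2row[vapply(ts$tracks, function(tr) tr[length(tr)],
                            integer(1))]
  ex <- nodes$x[end_rows]; ey <- nodes$y[end_rows]; ez <- nodes$z[end_rows]
  px <- nodes$x; py <- nodes$y; pz <- nodes$z
  for (k in seq_along(ts$tracks)) {
    tr <- ts$tracks[[k]]
    if (length(tr) < 2) next
    rows <- id2row[tr]
    vols <- nodes$volume[rows]
    jump <- which(vols[-1] >= params$collision_volume_ratio *
                    vols[-length(vols)] &
                    !nodes$interpolated[rows[-1]]) + 1L
    for (j in jump) {
      tt <- nodes$t[rows[j]]
      if (nrow(seen) && any(seen$type == "merge" & seen$t == tt &
                            seen$track == k)) next
      # a neighbouring track must terminate at t - 1 nearby
      others <- setdiff(ends_by_t[[as.character(tt - 1L)]], k)
      if (!length(others)) next
      r <- rows[j]
      dd <- sqrt((ex[others] - px[r])^2 + (ey[others] - py[r])^2 +
                   (ez[others] - pz[r])^2)
      hit <- which(dd <= params$gap_roi_radius)
      if (length(hit))
        return(list(track = k, j = j, other = others[hit[which.min(dd[hit])]],
                    t = tt))
    }
  }
  NULL
}

# Split the merged frames of one event and re-attach the links.
.process_merge <- function(ts, labeled, params, ev) {
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  tr <- ts$tracks[[ev$track]]
  rows <- id2row[tr]
  vol_pre <- nodes$volume[rows[ev$j - 1]]
  jj <- ev$j
  while (jj < length(tr) &&
         nodes$volume[rows[jj + 1]] >=
         params$collision_volume_ratio * vol_pre &&
         !nodes$interpolated[rows[jj + 1]])
    jj <- jj + 1L
  merged_rows <- rows[ev$j:jj]
  t_frames <- nodes$t[merged_rows]
  other_end_row <- id2row[ts$tracks[[ev$other]][length(ts$tracks[[ev$other]])]]
  seeds_pos <- rbind(as.numeric(nodes[other_end_row, c("x", "y", "z")]),
                     as.numeric(nodes[rows[ev$j - 1], c("x", "y", "z")]))
  new_nodes <- list()
  ok <- TRUE
  for (m in seq_along(merged_rows)) {
    r <- merged_rows[m]
    tf <- nodes$t[r]
    li <- which(vapply(labeled, `[[`, integer(1), "time_index") == tf)
    if (!length(li) || is.na(nodes$frame_label[r])) { ok <- FALSE; break }
    sp <- .watershed_split(labeled[[li]], nodes$frame_label[r], seeds_pos)
    if (is.null(sp)) { ok <- FALSE; break }
    labeled[[li]] <- sp$labeled
    new_nodes[[m]] <- data.frame(
      t = tf, x = sp$records$x, y = sp$records$y, z = sp$records$z,
      volume = as.numeric(sp$records$volume),
      mean_intensity = NA_real_, frame_label = sp$records$label,
      seed = sp$records$seed)
    seeds_pos <- as.matrix(sp$records[order(sp$records$seed),
                                      c("x", "y", "z")])
  }
  event <- data.frame(type = "merge", t = ev$t, track = ev$track,
                      other = ev$other, resolved = ok)
  if (!ok) return(list(ts = ts, labeled = labeled, event = event))

  # remove merged nodes, insert the split nodes, re-attach links
  next_id <- max(nodes$node_id)
  add <- do.call(rbind, new_nodes)
  add$node_id <- next_id + seq_len(nrow(add))
  add$parent_id <- NA_integer_; add$child_id <- NA_integer_
  add$track_id <- NA_integer_; add$interpolated <- FALSE
  chain1 <- add$node_id[add$seed == 1]   # the neighbouring track's side
  chain2 <- add$node_id[add$seed == 2]   # the original track's side
  seed_of <- add$seed
  after_row <- if (jj < length(tr)) rows[jj + 1L] else NA_integer_
  add$seed <- NULL
  keep <- setdiff(seq_len(nrow(nodes)), merged_rows)
  removed_ids <- nodes$node_id[merged_rows]
  nodes <- nodes[keep, , drop = FALSE]
  nodes$child_id[nodes$child_id %in% removed_ids] <- NA_integer_
  nodes$parent_id[nodes$parent_id %in% removed_ids] <- NA_integer_
  nodes <- rbind(nodes, add[, names(nodes)])
  id2 <- integer(max(nodes$node_id)); id2[nodes$node_id] <- seq_len(nrow(nodes))
  link <- function(aid, bid) {
    nodes$child_id[id2[aid]] <<- bid
    nodes$parent_id[id2[bid]] <<- aid
  }
  # chains through the merged interval
  for (m in seq_len(length(chain1) - 1)) link(chain1[m], chain1[m + 1])
  for (m in seq_len(length(chain2) - 1)) link(chain2[m], chain2[m + 1])
  link(ts$nodes$node_id[other_end_row], chain1[1])
  link(ts$nodes$node_id[rows[ev$j - 1]], chain2[1])
  # reconnect whatever followed the merged interval
  if (!is.na(after_row)) {
    after_id <- ts$nodes$node_id[after_row]
    tails <- c(tail(chain1, 1), tail(chain2, 1))
    tp <- nodes[id2[tails], c("x", "y", "z")]
    ap <- as.numeric(ts$nodes[after_row, c("x", "y", "z")])
    # a division partner: a track starting right after the interval nearby
    sm <- track_summary(ts)
    div <- which(sm$start_t == nodes$t[id2[tails[1]]] + 1L &
                 seq_along(ts$tracks) != ev$track &
                 seq_along(ts$tracks) != ev$other)
    div_id <- NA_integer_
    if (length(div)) {
      for (o in div) {
        os <- ts$tracks[[o]][1]
        op <- as.numeric(ts$nodes[ts$nodes$node_id == os, c("x", "y", "z")])
        if (sqrt(sum((op - ap)^2)) <= 2 * params$gap_roi_radius) {
          div_id <- os; break
        }
      }
    }
    if (!is.na(div_id)) {
      dp <- as.numeric(nodes[id2[div_id], c("x", "y", "z")])
      # assign the two chain tails to the two diverging heads by total
      # distance (identity vs swap)
      d_ident <- sqrt(sum((as.numeric(tp[1, ]) - dp)^2)) +
        sqrt(sum((as.numeric(tp[2, ]) - ap)^2))
      d_swap <- sqrt(sum((as.numeric(tp[1, ]) - ap)^2)) +
        sqrt(sum((as.numeric(tp[2, ]) - dp)^2))
      if (d_ident <= d_swap) {
        link(tails[1], div_id); link(tails[2], after_id)
      } else {
        link(tails[1], after_id); link(tails[2], div_id)
      }
    } else {
      # no division partner: continue the original track through the
      # nearer tail
      d1 <- sqrt(sum((as.numeric(tp[1, ]) - ap)^2))
      d2 <- sqrt(sum((as.numeric(tp[2, ]) - ap)^2))
      link(if (d1 < d2) tails[1] else tails[2], after_id)
    }
  }
  list(ts = .finish_track_set(nodes, params), labeled = labeled,
       event = event)
}

# Watershed split of one labelled object from seed positions. Returns NULL
# when the watershed yields fewer regions than seeds.
.watershed_split <- function(lstack, frame_label, seeds_pos) {
  lab <- lstack$labels
  d <- dim(lab)
  mask <- lab == frame_label
  if (!any(mask)) return(NULL)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  seeds <- array(0L, d)
  taken <- integer(0)
  for (s in seq_len(nrow(seeds_pos))) {
    dd <- (co[, 2] - seeds_pos[s, 1])^2 + (co[, 1] - seeds_pos[s, 2])^2 +
      (co[, 3] - seeds_pos[s, 3])^2
    ord <- order(dd)
    pick <- ord[!(idx[ord] %in% taken)][1]
    if (is.na(pick)) return(NULL)
    seeds[idx[pick]] <- s
    taken <- c(taken, idx[pick])
  }
  dist <- .cpp_chamfer3d(as.logical(mask), d)
  part <- .cpp_watershed_seeded(dist, as.logical(mask), seeds, d)
  dim(part) <- d
  ns <- nrow(seeds_pos)
  if (any(tabulate(part[idx], ns) == 0)) return(NULL)
  new_lab <- max(lab) + seq_len(ns - 1L)
  lab[part > 1L] <- new_lab[part[part > 1L] - 1L]
  # measure the parts
  recs <- NULL
  for (s in seq_len(ns)) {
    lb <- if (s == 1L) frame_label else new_lab[s - 1L]
    sel <- which(lab == lb)
    cs <- arrayInd(sel, d)
    recs <- rbind(recs, data.frame(label = lb, x = mean(cs[, 2]),
                                   y = mean(cs[, 1]), z = mean(cs[, 3]),
                                   volume = length(sel), seed = s))
  }
  lstack$labels <- lab
  lstack$records <- NULL  # frame records are superseded by the node table
  list(labeled = lstack, records = recs)
}

.find_divisions <- function(ts, params) {
  nodes <- ts$nodes
  if (!nrow(nodes)) return(NULL)
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  sm <- track_summary(ts)
  starts_by_t <- split(seq_along(ts$tracks), sm$start_t)
  start_rows <- id2row[vapply(ts$tracks, `[`, integer(1), 1L)]
  sx <- nodes$x[start_rows]; sy <- nodes$y[start_rows]
  sz <- nodes$z[start_rows]
  out <- NULL
  for (k in seq_along(ts$tracks)) {
    tr <- ts$tracks[[k]]
    if (length(tr) < 2) next
    rows <- id2row[tr]
    vols <- nodes$volume[rows]
    drop_j <- which(vols[-1] <= vols[-length(vols)] /
                      params$collision_volume_ratio) + 1L
    for (j in drop_j) {
      tt <- nodes$t[rows[j]]
      others <- setdiff(starts_by_t[[as.character(tt)]], k)
      if (!length(others)) next
      r <- rows[j]
      dd <- sqrt((sx[others] - nodes$x[r])^2 + (sy[others] - nodes$y[r])^2 +
                   (sz[others] - nodes$z[r])^2)
      hit <- which.min(dd)
      if (dd[hit] <= params$gap_roi_radius)
        out <- rbind(out, data.frame(type = "division", t = tt,
                                     track = k, other = others[hit],
                                     resolved = TRUE))
    }
  }
  out
}

#' Edit tracks: delete, break or merge
#'
#' The three editing operations of the proofreading workflow, exposed
#' programmatically. `delete` removes a track (its nodes become
#' unassigned); `break` splits a track in two at a given time; `merge`
#' concatenates two temporally disjoint tracks, bridging a one-frame gap
#' with an interpolated node if needed. Every edit is appended to the audit
#' log carried by the track set.
#'
#' @param ts a `track_set`.
#' @param action `"delete"`, `"break"` or `"merge"`.
#' @param track track id the action applies to.
#' @param at for `break`: the time point at which to cut; the node at this
#'   time starts the second track. Must not be the track's first or last
#'   time point.
#' @param track2 for `merge`: the id of the later track.
#' @return The edited `track_set` with an updated `audit` attribute.
#' @export
edit_tracks <- function(ts, action = c("delete", "break", "merge"),
                        track, at = NULL, track2 = NULL) {
  action <- match.arg(action)
  nodes <- ts$nodes
  params <- ts$params
  audit <- attr(ts, "audit") %||% list()
  if (track < 1 || track > length(ts$tracks)) stop("no such track: ", track)
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  tr <- ts$tracks[[track]]
  if (action == "delete") {
    rows <- id2row[tr]
    nodes$track_id[rows] <- NA_integer_
    nodes$child_id[rows] <- NA_integer_
    nodes$parent_id[rows] <- NA_integer_
    # deleted nodes are removed from consideration entirely
    nodes <- nodes[-rows, , drop = FALSE]
  } else if (action == "break") {
    tt <- nodes$t[id2row[tr]]
    if (is.null(at) || at <= min(tt) || at > max(tt))
      stop("cannot break at a track endpoint")
    cut <- which(tt == at)
    if (!length(cut)) stop("track ", track, " has no node at t=", at)
    a <- id2row[tr[cut - 1L]]; b <- id2row[tr[cut]]
    nodes$child_id[a] <- NA_integer_
    nodes$parent_id[b] <- NA_integer_
  } else {
    if (is.null(track2) || track2 < 1 || track2 > length(ts$tracks))
      stop("no such track: ", track2)
    tr2 <- ts$tracks[[track2]]
    e1 <- id2row[tr[length(tr)]]; s2 <- id2row[tr2[1]]
    if (nodes$t[s2] <= nodes$t[e1])
      stop("merge requires temporally disjoint tracks (end before start)")
    gap <- nodes$t[s2] - nodes$t[e1]
    if (gap == 1L) {
      nodes$child_id[e1] <- nodes$node_id[s2]
      nodes$parent_id[s2] <- nodes$node_id[e1]
    } else if (gap == 2L) {
      new_id <- max(nodes$node_id) + 1L
      mid <- (nodes[e1, c("x", "y", "z")] + nodes[s2, c("x", "y", "z")]) / 2
      nodes <- rbind(nodes, data.frame(
        node_id = new_id, t = nodes$t[e1] + 1L, x = mid$x, y = mid$y,
        z = mid$z, volume = (nodes$volume[e1] + nodes$volume[s2]) / 2,
        mean_intensity = NA_real_, frame_label = NA_integer_,
        parent_id = nodes$node_id[e1], child_id = nodes$node_id[s2],
        track_id = NA_integer_, interpolated = TRUE))
      nodes$child_id[e1] <- new_id
      nodes$parent_id[s2] <- new_id
    } else {
      stop("merge can bridge at most a one-frame gap (gap is ", gap - 1L,
           " frames)")
    }
  }
  audit[[length(audit) + 1L]] <- list(action = action, track = track,
                                      at = at, track2 = track2,
                                      time = as.character(Sys.time()))
  out <- .finish_track_set(nodes, params)
  attr(out, "audit") <- audit
  out
}
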