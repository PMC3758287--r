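#' Build the wound-oriented coordinate frame
#'
#' The user-drawn rectangular wound region defines a rotated axis system:
#' unit vector `c` points from the field towards the wound and unit vector
#' `r` is the in-plane lateral axis perpendicular to it. Displacement
#' components along `c` and `r` are the oriented and lateral distances.
#'
#' @param rectangle numeric `c(x_min, x_max, y_min, y_max)` in image
#'   pixels.
#' @param image_dims `c(rows, cols)` of the image the rectangle lives in.
#' @param wound_side `"left"`, `"right"`, `"top"`, `"bottom"`, or a numeric
#'   angle in degrees (0 = towards +x, measured counter-clockwise with y
#'   pointing up, i.e. `c = (cos a, -sin a)` in image coordinates).
#' @return An object of class `wound_frame` with fields `rectangle`,
#'   `c_axis`, `r_axis`.
#' @export
build_wound_frame <- function(rectangle, image_dims,
                              wound_side = "right") {
  if (length(rectangle) != 4) stop("rectangle must be (x_min, x_max, y_min, y_max)")
  if (rectangle[2] <= rectangle[1] || rectangle[4] <= rectangle[3])
    stop("degenerate wound rectangle")
  if (rectangle[1] < 1 || rectangle[3] < 1 ||
      rectangle[2] > image_dims[2] || rectangle[4] > image_dims[1])
    stop("wound rectangle must lie inside the image")
  if (is.numeric(wound_side)) {
    a <- wound_side * pi / 180
    cax <- c(cos(a), -sin(a))
  } else {
    cax <- switch(match.arg(wound_side,
                            c("right", "left", "top", "bottom")),
                  right = c(1, 0), left = c(-1, 0),
                  top = c(0, -1), bottom = c(0, 1))
  }
  rax <- c(-cax[2], cax[1])
  structure(list(rectangle = as.numeric(rectangle), c_axis = cax,
                 r_axis = rax),
            class = "wound_frame")
}

.in_wound <- function(x, y, frame) {
  r <- frame$rectangle
  x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]
}

#' Decompose a displacement in the wound frame
#'
#' Projects the in-plane displacement onto the wound axes. The effective
#' velocity scores how directly the step heads for the wound: +1 parallel
#' to the wound axis, 0 perpendicular, -1 straight away, and the cosine of
#' the angle in between; 0 for a zero displacement.
#'
#' @param p0,p1 positions `(x, y, z)` (z optional, assumed 0).
#' @param frame a [wound_frame()].
#' @param dt frame interval.
#' @return List with `absolute_distance`, `oriented_distance`,
#'   `lateral_distance`, `z_distance`, `effective_velocity`, `in_wound`
#'   (endpoint inside the rectangle) and `dt`.
#' @export
displacement_components <- function(p0, p1, frame, dt = 1) {
  if (dt <= 0) stop("'dt' must be positive")
  p0 <- c(as.numeric(p0), 0, 0)[1:3]
  p1 <- c(as.numeric(p1), 0, 0)[1:3]
  d <- p1 - p0
  oriented <- sum(d[1:2] * frame$c_axis)
  lateral <- sum(d[1:2] * frame$r_axis)
  absolute <- sqrt(sum(d^2))
  eff <- if (absolute > 0) oriented / absolute else 0
  list(absolute_distance = absolute, oriented_distance = oriented,
       lateral_distance = lateral, z_distance = d[3],
       effective_velocity = eff,
       in_wound = .in_wound(p1[1], p1[2], frame), dt = dt)
}

# Per-displacement table for a set of tracks: one row per step.
.displacement_table <- function(ts, frame, dt = 1, min_length = 2L) {
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  out <- NULL
  for (k in seq_along(ts$tracks)) {
    tr <- ts$tracks[[k]]
    if (length(tr) < min_length || length(tr) < 2) next
    rows <- id2row[tr]
    p <- as.matrix(nodes[rows, c("x", "y", "z")])
    d <- diff(p)
    oriented <- d[, 1] * frame$c_axis[1] + d[, 2] * frame$c_axis[2]
    lateral <- d[, 1] * frame$r_axis[1] + d[, 2] * frame$r_axis[2]
    absolute <- sqrt(rowSums(d^2))
    eff <- ifelse(absolute > 0, oriented / absolute, 0)
    inw <- .in_wound(p[-1, 1], p[-1, 2], frame)
    arrived <- cumsum(.in_wound(p[, 1], p[, 2], frame)) > 0
    out <- rbind(out, data.frame(
      track_id = k, t = nodes$t[rows[-1]],
      absolute = absolute / dt, oriented = oriented / dt,
      lateral = lateral / dt, effective = eff, in_wound = inw,
      post_arrival = arrived[-length(arrived)] | inw))
  }
  out
}

#' Per-track kinematic metrics
#'
#' Mean absolute, oriented and lateral velocities, the meandering index
#' (straight-line distance between the track endpoints divided by the path
#' length; 1 = perfectly direct, 0 = returned to start), duration, and
#' wound arrival. Velocities are in pixels per frame unless `voxel_size`
#' and `frame_interval` are supplied, in which case they are micrometres
#' per minute.
#'
#' @param ts a `track_set`.
#' @param frame a [wound_frame()].
#' @param voxel_size optional `(dy, dx, dz)` in microns.
#' @param frame_interval optional frame interval in minutes.
#' @return Data frame with one row per track (length >= 2).
#' @export
track_metrics <- function(ts, frame, voxel_size = NULL,
                          frame_interval = NULL) {
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  dt <- frame_interval %||% 1
  vs <- voxel_size %||% c(1, 1, 1)
  out <- NULL
  for (k in seq_along(ts$tracks)) {
    tr <- ts$tracks[[k]]
    if (length(tr) < 2) next
    rows <- id2row[tr]
    p <- as.matrix(nodes[rows, c("x", "y", "z")])
    ps <- sweep(p, 2, c(vs[2], vs[1], vs[3]), `*`)
    d <- diff(ps)
    oriented <- d[, 1] * frame$c_axis[1] + d[, 2] * frame$c_axis[2]
    lateral <- d[, 1] * frame$r_axis[1] + d[, 2] * frame$r_axis[2]
    absolute <- sqrt(rowSums(d^2))
    path_len <- sum(absolute)
    net <- sqrt(sum((ps[nrow(ps), ] - ps[1, ])^2))
    inw <- .in_wound(p[, 1], p[, 2], frame)
    arrive <- if (any(inw)) nodes$t[rows[which(inw)[1]]] else NA_integer_
    out <- rbind(out, data.frame(
      track_id = k,
      velocity = mean(absolute) / dt,
      oriented_velocity = mean(oriented) / dt,
      lateral_velocity = mean(lateral) / dt,
      meandering_index = if (path_len > 0) net / path_len else NA_real_,
      duration = length(tr),
      reached_wound = any(inw),
      time_to_wound = if (!is.na(arrive)) arrive - nodes$t[rows[1]]
                      else NA_real_))
  }
  out
}

#' Population-level migration measurements
#'
#' The panel of computationally derived measurements used to assess
#' phagocyte migration towards a wound: per-track mean velocities and
#' meandering index (averaged over tracks), plus the population counts and
#' ratios built from individual displacements. The forward ratio is the
#' fraction of displacements with effective velocity above `forward_cut`;
#' the backward and leave-wound ratios use the mirrored criterion
#' (effective velocity below `-forward_cut`) by default. Two sign
#' conventions circulate for these ratios; `literal_ratios` applies the
#' forward-type sign (larger than `-forward_cut`) instead. Ratios with
#' empty denominators are `NA`, not 0.
#'
#' @param ts a `track_set`.
#' @param frame a [wound_frame()].
#' @param forward_cut effective-velocity cutoff for forward movement.
#' @param idle_cut absolute-velocity level (pixels/frame) below which a
#'   displacement counts as idle.
#' @param literal_ratios use the forward-type sign for the backward and
#'   leave-wound ratios instead of the mirrored reading.
#' @param min_track_length tracks shorter than this are excluded.
#' @param dt frame interval used to scale velocities.
#' @return List of class `population_metrics`.
#' @export
population_metrics <- function(ts, frame, forward_cut = 0.6,
                               idle_cut = 0.5, literal_ratios = FALSE,
                               min_track_length = 2L, dt = 1) {
  disp <- .displacement_table(ts, frame, dt, min_track_length)
  tm <- track_metrics(ts, frame)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  if (is.null(disp) || !nrow(disp)) {
    counts <- list(n_displacements = 0L)
    return(structure(c(list(
      mean_velocity = NA_real_, mean_oriented_velocity = NA_real_,
      mean_lateral_velocity = NA_real_, mean_meandering_index = NA_real_,
      in_wound_neutrophils = 0L, forward_ratio = NA_real_,
      in_wound_ratio = NA_real_, in_wound_ratio_2 = NA_real_,
      idle_wound_ratio = NA_real_, backward_ratio = NA_real_,
      leave_wound_ratio = NA_real_, transiting_wound_neutrophils = 0L),
      counts), class = "population_metrics"))
  }
  n_disp <- nrow(disp)
  n_post <- sum(disp$post_arrival)
  n_inw <- sum(disp$in_wound)
  backward_sel <- if (literal_ratios) disp$effective > -forward_cut
                  else disp$effective < -forward_cut
  # wound membership per node, for counts of arriving/transiting tracks
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  reach <- transit <- logical(length(ts$tracks))
  for (k in seq_along(ts$tracks)) {
    if (length(ts$tracks[[k]]) < min_track_length) next
    rows <- id2row[ts$tracks[[k]]]
    inw <- .in_wound(nodes$x[rows], nodes$y[rows], frame)
    reach[k] <- any(inw)
    transit[k] <- any(inw) && any(!inw[seq_along(inw) > which(inw)[1]])
  }
  structure(list(
    mean_velocity = mean(tm$velocity),
    mean_oriented_velocity = mean(tm$oriented_velocity),
    mean_lateral_velocity = mean(tm$lateral_velocity),
    mean_meandering_index = mean(tm$meandering_index, na.rm = TRUE),
    in_wound_neutrophils = sum(reach),
    forward_ratio = ratio(sum(disp$effective > forward_cut), n_disp),
    in_wound_ratio = ratio(n_inw, n_disp),
    in_wound_ratio_2 = ratio(n_inw, n_post),
    idle_wound_ratio = ratio(sum(disp$in_wound &
                                 disp$absolute < idle_cut), n_inw),
    backward_ratio = ratio(sum(backward_sel), n_disp),
    leave_wound_ratio = ratio(sum(backward_sel & disp$post_arrival),
                              n_post),
    transiting_wound_neutrophils = sum(transit),
    n_displacements = n_disp), class = "population_metrics")
}

#' @export
print.population_metrics <- function(x, ...) {
  cat("<population_metrics>\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm,
                format(x[[nm]], digits = 4)))
  invisible(x)
}

#' Partition a field of view into adjacent column bands
#'
#' @param n_columns number of columns of the processed grid.
#' @param band_width columns per band.
#' @return Data frame with `band`, `col_min`, `col_max`; one row per band
#'   (`floor(n_columns / band_width)` bands).
#' @export
band_partition <- function(n_columns, band_width) {
  n_bands <- n_columns %/% band_width
  if (n_bands < 1) stop("field narrower than one band")
  data.frame(band = seq_len(n_bands),
             col_min = (seq_len(n_bands) - 1L) * band_width + 1L,
             col_max = seq_len(n_bands) * band_width)
}

#' Volume against position towards the wound
#'
#' Reproduces the volume/position analysis: migratory tracks (duration
#' above `min_duration` frames and mean absolute velocity at least
#' `min_velocity` pixels/frame) contribute every node to a column band; the
#' field of view is split into `n_bands` adjacent bands of `band_width`
#' columns, higher band numbers closer to the wound (`wound_side "right"`;
#' use `"left"` to flip). Volumes are normalised to the dataset mean (so
#' the grand mean of normalised volumes is 1) and averaged per band, and an
#' ordinary least squares line of mean normalised volume against band index
#' is fitted, with a two-sided t-test on the slope.
#'
#' @param ts a `track_set`.
#' @param n_bands number of bands.
#' @param band_width band width in columns of the processed grid.
#' @param min_duration minimum number of time points spanned (strictly
#'   more).
#' @param min_velocity minimum mean absolute velocity, pixels/frame.
#' @param wound_side `"right"` or `"left"`.
#' @param dt frame interval for the velocity filter.
#' @return Object of class `volume_band_profile`: data frame `bands` (band
#'   index, mean normalised volume, node count), `normalisation` (dataset
#'   mean volume), `fit` (slope, intercept, r_squared, p_value), `n_tracks`.
#' @export
volume_position_profile <- function(ts, n_bands = 25, band_width = 20,
                                    min_duration = 30, min_velocity = 2,
                                    wound_side = "right", dt = 1) {
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  keep_nodes <- NULL
  n_tracks <- 0L
  for (k in seq_along(ts$tracks)) {
    tr <- ts$tracks[[k]]
    if (length(tr) <= min_duration) next
    rows <- id2row[tr]
    p <- as.matrix(nodes[rows, c("x", "y", "z")])
    vel <- mean(sqrt(rowSums(diff(p)^2))) / dt
    if (vel < min_velocity) next
    n_tracks <- n_tracks + 1L
    keep_nodes <- c(keep_nodes, rows)
  }
  if (!n_tracks)
    stop("no tracks survive the filters (duration > ", min_duration,
         " frames and mean absolute velocity >= ", min_velocity,
         " px/frame)")
  x <- nodes$x[keep_nodes]
  vol <- nodes$volume[keep_nodes]
  band <- ceiling(x / band_width)
  if (wound_side == "left") band <- n_bands + 1L - band
  sel <- band >= 1 & band <= n_bands & !is.na(vol)
  band <- band[sel]; vol <- vol[sel]
  norm_const <- mean(vol)
  nv <- vol / norm_const
  bt <- data.frame(band = sort(unique(band)))
  bt$mean_volume <- as.numeric(tapply(nv, band, mean))
  bt$n_nodes <- as.integer(tapply(nv, band, length))
  fit <- lm(mean_volume ~ band, data = bt)
  sfit <- summary(fit)
  structure(list(
    bands = bt, normalisation = norm_const,
    fit = list(slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = sfit$r.squared,
               p_value = sfit$coefficients[2, 4]),
    n_tracks = n_tracks, n_bands = n_bands, band_width = band_width),
    class = "volume_band_profile")
}

#' @export
print.volume_band_profile <- function(x, ...) {
  cat(sprintf(
    "<volume_band_profile> %d bands x %d columns, %d tracks\n  slope %.4f (p = %.3g, r^2 = %.3f)\n",
    x$n_bands, x$band_width, x$n_tracks, x$fit$slope, x$fit$p_value,
    x$fit$r_squared))
  invisible(x)
}
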