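#' Distance between automatic tracks and a gold standard
#'
#' Two complementary node-wise accuracy measures: `d_ag`, the mean distance
#' from every automatically tracked node to the nearest gold-standard node
#' at the same time point, and `d_ga`, the reverse. The pair exposes both
#' failure modes: spurious automatic tracks inflate `d_ag` while missed
#' (e.g. faint) cells inflate `d_ga`. Nodes with no counterpart at their
#' time point are excluded from the mean and counted as unmatched. Medians
#' and per-track breakdowns are also reported.
#'
#' @param ts a `track_set` (only nodes assigned to tracks are scored) or a
#'   data frame with columns `t, x, y, z` (and optionally `track_id`).
#' @param gold data frame with columns `cell, t, x, y, z` (the gold
#'   standard; coordinates must be on the same grid as the automatic
#'   nodes).
#' @return Object of class `track_distance_report`.
#' @export
track_set_distance <- function(ts, gold) {
  if (inherits(ts, "track_set")) {
    auto <- ts$nodes[!is.na(ts$nodes$track_id),
                     c("t", "x", "y", "z", "track_id")]
  } else auto <- ts
  if (!nrow(auto)) stop("automatic track set is empty")
  if (is.null(gold) || !nrow(gold)) stop("gold standard set is empty")
  one_way <- function(from, to, group) {
    d <- rep(NA_real_, nrow(from))
    for (tt in unique(from$t)) {
      fi <- which(from$t == tt)
      gi <- which(to$t == tt)
      if (!length(gi)) next
      fx <- as.matrix(from[fi, c("x", "y", "z")])
      gx <- as.matrix(to[gi, c("x", "y", "z")])
      dd <- outer(rowSums(fx^2), rowSums(gx^2), `+`) -
        2 * fx %*% t(gx)
      d[fi] <- sqrt(pmax(apply(dd, 1, min), 0))
    }
    list(dist = d, unmatched = sum(is.na(d)))
  }
  gold2 <- data.frame(t = gold$t, x = gold$x, y = gold$y, z = gold$z)
  ag <- one_way(auto, gold2, auto$track_id)
  ga <- one_way(gold2, auto, gold$cell)
  per_track <- if (!is.null(auto$track_id))
    tapply(ag$dist, auto$track_id, mean, na.rm = TRUE) else NULL
  per_cell <- if (!is.null(gold$cell))
    tapply(ga$dist, gold$cell, mean, na.rm = TRUE) else NULL
  structure(list(
    d_ag = mean(ag$dist, na.rm = TRUE),
    d_ga = mean(ga$dist, na.rm = TRUE),
    d_ag_median = median(ag$dist, na.rm = TRUE),
    d_ga_median = median(ga$dist, na.rm = TRUE),
    unmatched_auto = ag$unmatched, unmatched_gold = ga$unmatched,
    per_track = per_track, per_cell = per_cell,
    n_auto = nrow(auto), n_gold = nrow(gold2)),
    class = "track_distance_report")
}

#' @export
print.track_distance_report <- function(x, ...) {
  cat(sprintf(
    "<track_distance_report> d_ag = %.3f (median %.3f), d_ga = %.3f (median %.3f)\n  %d auto nodes (%d unmatched), %d gold nodes (%d unmatched)\n",
    x$d_ag, x$d_ag_median, x$d_ga, x$d_ga_median, x$n_auto,
    x$unmatched_auto, x$n_gold, x$unmatched_gold))
  invisible(x)
}

#' Threshold robustness sweep
#'
#' Re-runs the full segmentation-and-tracking pipeline with the
#' automatically detected hysteresis thresholds scaled by each fraction
#' (the classical robustness experiment varies them from 40% to 140%) and
#' scores every run against the gold standard. A failure at one fraction is
#' recorded and the sweep continues.
#'
#' @param x the (already reduced, if desired) [volume_sequence()].
#' @param gold gold-standard data frame on the same grid as `x`.
#' @param fractions increasing threshold multipliers.
#' @param seg_params a [segmentation_params()] (its `threshold_fraction` is
#'   overridden per run).
#' @param key_params a [keyhole_params()].
#' @param min_track_length tracks shorter than this are dropped before
#'   scoring.
#' @return Data frame of class `sweep_result`: one row per fraction with
#'   `d_ag`, `d_ga`, `n_tracks`, `error`.
#' @export
threshold_sweep <- function(x, gold, fractions = seq(0.4, 1.4, by = 0.1),
                            seg_params = segmentation_params(),
                            key_params = keyhole_params(),
                            min_track_length = 3L) {
  if (is.unsorted(fractions, strictly = TRUE))
    stop("'fractions' must be strictly increasing")
  base <- auto_thresholds(x, seg_params)
  out <- data.frame(fraction = fractions, d_ag = NA_real_,
                    d_ga = NA_real_, n_tracks = NA_integer_,
                    error = NA_character_)
  for (i in seq_along(fractions)) {
    res <- tryCatch({
      th <- base * fractions[i]
      labeled <- segment_sequence(x, seg_params, thresholds = th)
      labeled <- split_volume_outliers(labeled, seg_params)
      ts <- link_sequence(node_table(labeled), key_params)
      ts <- backward_validate(ts)
      ts <- bridge_gaps(ts)
      ts <- resolve_collisions(ts, labeled)$track_set
      ts <- filter_tracks(ts, min_track_length)
      rep <- track_set_distance(ts, gold)
      list(d_ag = rep$d_ag, d_ga = rep$d_ga,
           n_tracks = length(ts$tracks))
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) out$error[i] <- res$error
    else {
      out$d_ag[i] <- res$d_ag; out$d_ga[i] <- res$d_ga
      out$n_tracks[i] <- res$n_tracks
    }
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}
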