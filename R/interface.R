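.config_defaults <- function() list(
  layout = "slice_folders",
  reduce = TRUE,
  channel_override = NULL,
  voxel_size = NULL,
  frame_interval = NULL,
  # segmentation
  threshold_fraction = 1, connectivity = 26, outlier_k = 3,
  n_bins = 256, background_trim = TRUE, trim_k = 3,
  per_timepoint = FALSE, erode_in_plane = FALSE, max_erosions = 30,
  min_volume = 5,
  # tracking
  wedge_angle = 60, circle_angle = 300, wedge_reach = 3,
  circle_radius = 1, first_link_radius = NA, idle_tol = 0.5,
  collision_volume_ratio = 1.5, gap_roi_radius = NA, min_keyhole = NA,
  backward_mode = "all", keyhole_mode = "3d", min_track_length = 3,
  resolve_collisions = TRUE,
  # kinematics
  wound = NULL, wound_side = "right", forward_cut = 0.6, idle_cut = 0.5,
  literal_ratios = FALSE,
  n_bands = 25, band_width = 20, min_duration = 30, min_velocity = 2,
  # run
  seed = 1, output_dir = NULL)

#' Assemble and validate a pipeline configuration
#'
#' All tunables of the pipeline with their defaults; unknown keys are
#' rejected before any computation. Can be loaded from a YAML or JSON file
#' with [read_config()].
#'
#' @param ... named settings overriding the defaults (see
#'   [segmentation_params()], [keyhole_params()],
#'   [population_metrics()] and [volume_position_profile()] for their
#'   meaning).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  user <- list(...)
  if (length(user) && is.null(names(user)))
    stop("configuration settings must be named")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  # eager validation via the parameter constructors
  .seg_params_from(cfg)
  .key_params_from(cfg)
  if (!cfg$backward_mode %in% c("all", "first"))
    stop("backward_mode must be 'all' or 'first'")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path)
         else stop("unsupported config format: .", ext)
  do.call(pipeline_config, lst)
}

.seg_params_from <- function(cfg)
  segmentation_params(cfg$threshold_fraction, cfg$connectivity,
                      cfg$outlier_k, cfg$n_bins, cfg$background_trim,
                      cfg$trim_k, cfg$per_timepoint, cfg$erode_in_plane,
                      cfg$max_erosions, cfg$min_volume)

.key_params_from <- function(cfg)
  keyhole_params(cfg$wedge_angle, cfg$circle_angle, cfg$wedge_reach,
                 cfg$circle_radius, cfg$first_link_radius,
                 cfg$collision_volume_ratio, cfg$gap_roi_radius,
                 cfg$idle_tol, cfg$min_keyhole, cfg$keyhole_mode)

#' Run the full segmentation, tracking and measurement pipeline
#'
#' Executes read (when `input` is a path), 2x2 reduction, automatic
#' thresholding, hysteresis segmentation, volume-outlier splitting, keyhole
#' linking, backward validation, gap bridging, collision resolution, short
#' track filtering, and (when a wound rectangle is configured) the
#' kinematic measurements. Node coordinates in the result are on the
#' processed (reduced) grid. If a stage fails and `output_dir` is set, the
#' partial results are written and the manifest records the failure point.
#'
#' @param input a path (read with `config$layout`) or a
#'   [volume_sequence()].
#' @param config a [pipeline_config()].
#' @return A results bundle: list with `nodes`, `track_set`, `labeled`,
#'   `thresholds`, `metrics` (when a wound is configured), `events`,
#'   `manifest` and `log`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  bundle <- list(manifest = list(
    package_version = as.character(utils::packageVersion("phagotrack")),
    config = unclass(config), completed = character()))
  log <- character()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      bundle$manifest$failed_stage <<- name
      bundle$manifest$error <<- conditionMessage(e)
      if (!is.null(config$output_dir))
        try(export_results(bundle, config$output_dir), silent = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  sq <- stage("read", function() {
    if (inherits(input, "volume_sequence")) input
    else read_sequence(input, config$layout,
                       config[c("voxel_size", "frame_interval")])
  })
  note("read: %d time points of %s", length(sq$stacks),
       paste(.seq_dims(sq), collapse = "x"))
  bundle$manifest$completed <- c(bundle$manifest$completed, "read")

  if (isTRUE(config$reduce)) {
    sq <- stage("reduce", function() reduce_sequence(sq))
    note("reduce: grid now %s", paste(.seq_dims(sq), collapse = "x"))
  }
  seg_par <- .seg_params_from(config)
  key_par <- .key_params_from(config)

  labeled <- stage("segment", function() segment_sequence(sq, seg_par))
  th <- attr(labeled, "thresholds")
  if (!is.null(th))
    note("segment: thresholds low=%.2f high=%.2f", th[1], th[2])
  note("segment: %d objects in total",
       sum(vapply(labeled, function(l) nrow(l$records), integer(1))))
  bundle$labeled <- labeled
  bundle$thresholds <- th
  bundle$manifest$completed <- c(bundle$manifest$completed, "segment")

  labeled <- stage("split_outliers",
                   function() split_volume_outliers(labeled, seg_par))
  bundle$labeled <- labeled

  ts <- stage("track", function() {
    nodes <- node_table(labeled)
    link_sequence(nodes, key_par)
  })
  note("track: %d tracks from %d nodes", length(ts$tracks),
       nrow(ts$nodes))
  ts <- stage("backward_validate",
              function() backward_validate(ts, config$backward_mode))
  ts <- stage("bridge_gaps", function() bridge_gaps(ts))
  events <- NULL
  if (isTRUE(config$resolve_collisions)) {
    rc <- stage("resolve_collisions",
                function() resolve_collisions(ts, labeled))
    ts <- rc$track_set
    bundle$labeled <- labeled <- rc$labeled
    events <- rc$events
    if (!is.null(events) && nrow(events))
      note("collisions: %d events (%d resolved)", nrow(events),
           sum(events$resolved))
  }
  ts <- stage("filter", function()
    filter_tracks(ts, config$min_track_length))
  note("post-processing: %d tracks of length >= %d", length(ts$tracks),
       config$min_track_length)
  bundle$track_set <- ts
  bundle$nodes <- ts$nodes
  bundle$events <- events
  bundle$manifest$completed <- c(bundle$manifest$completed, "track")

  if (!is.null(config$wound)) {
    bundle$metrics <- stage("measure", function() {
      frame <- build_wound_frame(config$wound, .seq_dims(sq)[1:2],
                                 config$wound_side)
      list(wound_frame = frame,
           tracks = track_metrics(ts, frame, config$voxel_size,
                                  config$frame_interval),
           population = population_metrics(
             ts, frame, config$forward_cut, config$idle_cut,
             config$literal_ratios, config$min_track_length))
    })
    bundle$manifest$completed <- c(bundle$manifest$completed, "measure")
  }
  bundle$log <- log
  bundle$manifest$seed <- config$seed
  if (!is.null(config$output_dir))
    export_results(bundle, config$output_dir)
  bundle
}

#' Export a results bundle to CSV/JSON files
#'
#' Writes the node table (`nodes.csv`), track membership (`tracks.json`),
#' events log, metrics (JSON) and the run manifest with an md5 checksum of
#' the node table. Stable column order; identical runs produce
#' byte-identical node and track tables.
#'
#' @param bundle result of [run_pipeline()] (possibly partial).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$nodes)) {
    nodes <- as.data.frame(bundle$nodes)
    write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$track_set))
    jsonlite::write_json(
      list(tracks = bundle$track_set$tracks),
      file.path(dir, "tracks.json"), auto_unbox = FALSE, digits = NA)
  if (!is.null(bundle$events) && NROW(bundle$events))
    jsonlite::write_json(bundle$events, file.path(dir, "events.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$metrics)) {
    pop <- bundle$metrics$population
    jsonlite::write_json(unclass(pop), file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(bundle$metrics$tracks))
      write.csv(bundle$metrics$tracks,
                file.path(dir, "track_metrics.csv"), row.names = FALSE)
  }
  manifest <- bundle$manifest
  if (file.exists(file.path(dir, "nodes.csv")))
    manifest$nodes_md5 <- unname(tools::md5sum(file.path(dir,
                                                         "nodes.csv")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' Read back an exported node table
#'
#' @param path the `nodes.csv` written by [export_results()].
#' @return A `node_table` data frame.
#' @export
read_nodes_csv <- function(path) {
  nodes <- read.csv(path)
  class(nodes) <- c("node_table", "data.frame")
  nodes
}

#' Labelled stacks as multipage TIFF
#'
#' Writes each time point's label image as a 16-bit multipage TIFF under
#' `dir` (the labelled-image companion of the intensity data).
#'
#' @param labeled list of `labeled_stack`s.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_labeled_tiff <- function(labeled, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in labeled) {
    arr <- l$labels / 65535
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages,
                    file.path(dir, sprintf("t%04d.tif", l$time_index)),
                    bits.per.sample = 16L)
  }
  invisible(dir)
}

#' 3D track plot with time as the vertical axis
#'
#' Renders each track as a polyline in an oblique projection of (x, y, t):
#' the in-plane position spreads horizontally and time rises vertically, so
#' near-vertical lines are slow or stationary cells and shallow lines are
#' fast ones. Optionally overlays the wound rectangle (and a reference
#' image outline) on the t = 0 plane.
#'
#' @param ts a `track_set`.
#' @param wound optional rectangle `c(x_min, x_max, y_min, y_max)`.
#' @param dic optional 2D matrix shown as a grey image on the base plane.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param min_length only tracks with at least this many nodes are drawn.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_tracks_3d <- function(ts, wound = NULL, dic = NULL, file = NULL,
                           min_length = 2L) {
  keep <- which(lengths(ts$tracks) >= min_length)
  if (!length(keep)) stop("no tracks to plot")
  nodes <- ts$nodes
  id2row <- integer(max(nodes$node_id, 0L))
  id2row[nodes$node_id] <- seq_len(nrow(nodes))
  proj <- function(x, y, t) list(px = x + 0.45 * y, py = t + 0.3 * y)
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  xr <- range(nodes$x); yr <- range(nodes$y); tr <- range(nodes$t)
  corners <- proj(c(xr[1], xr[2], xr[2], xr[1]),
                  c(yr[1], yr[1], yr[2], yr[2]), rep(tr[1], 4))
  top <- proj(xr, yr, rep(tr[2], 2))
  graphics::plot(NA, xlim = range(corners$px, top$px),
                 ylim = range(corners$py, top$py),
                 xlab = "x (+ oblique y)", ylab = "time (frames)",
                 main = sprintf("%d tracks", length(keep)))
  graphics::polygon(corners$px, corners$py, border = "grey60")
  if (!is.null(dic)) {
    # outline only: the reference plane at t = 0
    graphics::polygon(corners$px, corners$py, col = "grey95",
                      border = "grey60")
  }
  if (!is.null(wound)) {
    wc <- proj(c(wound[1], wound[2], wound[2], wound[1]),
               c(wound[3], wound[3], wound[4], wound[4]), rep(tr[1], 4))
    graphics::polygon(wc$px, wc$py, border = "black", lwd = 2)
  }
  cols <- grDevices::hcl.colors(length(keep), "Dark 3")
  for (i in seq_along(keep)) {
    tr_ids <- ts$tracks[[keep[i]]]
    rows <- id2row[tr_ids]
    p <- proj(nodes$x[rows], nodes$y[rows], nodes$t[rows])
    graphics::lines(p$px, p$py, col = cols[i], lwd = 1.5)
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
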