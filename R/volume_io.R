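#' A single time point's 3D intensity grid
#'
#' Container for one 3D fluorescence volume. Dimensions are ordered
#' (row = y, column = x, slice = z); coordinates throughout the package are
#' 1-based voxel centres in this grid.
#'
#' @param intensities 3D numeric array of non-negative intensities (a matrix
#'   is promoted to a single-slice array).
#' @param time_index integer frame number, 1-based.
#' @param voxel_size numeric length-3, voxel pitch `(dy, dx, dz)` in microns.
#' @param frame_interval time between frames, in minutes.
#' @param bit_depth integer bit depth of the acquisition (defines the valid
#'   intensity range `[0, 2^bit_depth - 1]`).
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(intensities, time_index = 1L,
                         voxel_size = c(1, 1, 1), frame_interval = 1,
                         bit_depth = 16L) {
  if (is.matrix(intensities)) dim(intensities) <- c(dim(intensities), 1L)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (any(dim(intensities) < 1L)) stop("all dimensions must be positive")
  if (anyNA(intensities) || min(intensities) < 0)
    stop("intensities must be non-negative and free of NA")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (dy, dx, dz)")
  if (frame_interval <= 0) stop("'frame_interval' must be positive")
  structure(
    list(intensities = intensities, time_index = as.integer(time_index),
         voxel_size = as.numeric(voxel_size),
         frame_interval = as.numeric(frame_interval),
         bit_depth = as.integer(bit_depth)),
    class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_stack> t=%d  %dx%dx%d (rows x cols x slices)  %d-bit\n",
              x$time_index, d[1], d[2], d[3], x$bit_depth))
  invisible(x)
}

#' An ordered sequence of volume stacks
#'
#' @param stacks list of [volume_stack()] objects with identical dimensions
#'   and voxel size, strictly increasing `time_index`.
#' @param channel_labels character tags, one per channel, each
#'   `"fluorescent"` or `"dic"`.
#' @param source_layout one of `"slice_folders"`, `"multipage_tiff"`,
#'   `"serialized"` or `"memory"`.
#' @return An object of class `volume_sequence`.
#' @export
volume_sequence <- function(stacks, channel_labels = "fluorescent",
                            source_layout = "memory") {
  if (!length(stacks)) stop("'stacks' must contain at least one volume_stack")
  stopifnot(all(vapply(stacks, inherits, logical(1), "volume_stack")))
  dims <- vapply(stacks, function(s) dim(s$intensities), integer(3))
  if (any(dims != dims[, 1]))
    stop("all stacks must share dimensions; stack ",
         which(colSums(dims != dims[, 1]) > 0)[1], " differs")
  tt <- vapply(stacks, `[[`, integer(1), "time_index")
  if (any(diff(tt) <= 0)) stop("time_index must be strictly increasing")
  structure(
    list(stacks = stacks, channel_labels = channel_labels,
         source_layout = source_layout),
    class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  d <- dim(x$stacks[[1]]$intensities)
  cat(sprintf("<volume_sequence> %d time points, %dx%dx%d, layout=%s\n",
              length(x$stacks), d[1], d[2], d[3], x$source_layout))
  invisible(x)
}

#' @export
length.volume_sequence <- function(x) length(x$stacks)

.seq_dims <- function(seq) dim(seq$stacks[[1]]$intensities)

.tp_number <- function(names) {
  m <- regexpr("[0-9]+(?=[^0-9]*$)", names, perl = TRUE)
  out <- rep(NA_integer_, length(names))
  ok <- m > 0
  out[ok] <- as.integer(substr(names[ok], m[ok],
                               m[ok] + attr(m, "match.length")[ok] - 1L))
  out
}

.check_contiguous <- function(nums, what) {
  nums <- sort(nums)
  gaps <- which(diff(nums) > 1)
  if (length(gaps))
    stop(sprintf("missing %s %d (found %d then %d)", what,
                 nums[gaps[1]] + 1L, nums[gaps[1]], nums[gaps[1] + 1L]))
  invisible(nums)
}

.read_tiff_grid <- function(files_or_file, multipage) {
  if (multipage) {
    pages <- tiff::readTIFF(files_or_file, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    pages <- lapply(files_or_file, tiff::readTIFF, as.is = TRUE)
  }
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

.read_metadata_sidecar <- function(path, config) {
  meta <- list()
  side <- file.path(path, "metadata.json")
  if (dir.exists(path) && file.exists(side))
    meta <- jsonlite::fromJSON(side)
  for (f in c("voxel_size", "frame_interval", "bit_depth"))
    if (!is.null(config[[f]])) meta[[f]] <- config[[f]]
  meta
}

#' Read a time-lapse volume sequence from disk
#'
#' Three layouts are supported: `slice_folders` (one directory per time
#' point, one single-page TIFF per z-slice), `multipage_tiff` (one
#' multi-page TIFF per time point, either as files in a directory or a
#' single file), and `serialized` (one versioned `.rds` grid container per
#' time point, as written by [write_sequence()]). Time points are ordered by
#' the trailing number in directory/file names and must be contiguous.
#' Voxel size and frame interval are taken from a `metadata.json` sidecar in
#' the directory if present, overridden by `config`.
#'
#' @param path directory (or single multi-page TIFF file).
#' @param layout one of `"slice_folders"`, `"multipage_tiff"`,
#'   `"serialized"`.
#' @param config optional named list with `voxel_size`, `frame_interval`,
#'   `bit_depth`.
#' @return A [volume_sequence()].
#' @export
read_sequence <- function(path,
                          layout = c("slice_folders", "multipage_tiff",
                                     "serialized"),
                          config = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("path does not exist: ", path)
  meta <- .read_metadata_sidecar(path, config)
  vs <- meta$voxel_size %||% c(1, 1, 1)
  fi <- meta$frame_interval %||% 1
  bd <- meta$bit_depth %||% 16L

  if (layout == "multipage_tiff" && !dir.exists(path)) {
    arr <- .read_tiff_grid(path, multipage = TRUE)
    return(volume_sequence(list(volume_stack(arr, 1L, vs, fi, bd)),
                           source_layout = layout))
  }
  if (layout == "slice_folders") {
    dirs <- list.dirs(path, recursive = FALSE)
    if (!length(dirs)) stop("no time-point folders under ", path)
    nums <- .tp_number(basename(dirs))
    if (anyNA(nums)) stop("time-point folder without a number: ",
                          basename(dirs)[which(is.na(nums))[1]])
    .check_contiguous(nums, "time point")
    dirs <- dirs[order(nums)]
    stacks <- vector("list", length(dirs))
    for (i in seq_along(dirs)) {
      fs <- list.files(dirs[i], pattern = "\\.tiff?$", full.names = TRUE,
                       ignore.case = TRUE)
      if (!length(fs)) stop("no TIFF slices in ", dirs[i])
      fs <- fs[order(.tp_number(basename(fs)))]
      arr <- if (length(fs) == 1L) .read_tiff_grid(fs[1], multipage = TRUE)
             else .read_tiff_grid(fs, multipage = FALSE)
      stacks[[i]] <- volume_stack(arr, i, vs, fi, bd)
    }
  } else {
    pat <- if (layout == "multipage_tiff") "\\.tiff?$" else "\\.rds$"
    fs <- list.files(path, pattern = pat, full.names = TRUE,
                     ignore.case = TRUE)
    if (!length(fs)) stop("no ", layout, " time points under ", path)
    nums <- .tp_number(basename(fs))
    if (anyNA(nums)) stop("time-point file without a number: ",
                          basename(fs)[which(is.na(nums))[1]])
    .check_contiguous(nums, "time point")
    fs <- fs[order(nums)]
    stacks <- vector("list", length(fs))
    for (i in seq_along(fs)) {
      if (layout == "multipage_tiff") {
        arr <- .read_tiff_grid(fs[i], multipage = TRUE)
        stacks[[i]] <- volume_stack(arr, i, vs, fi, bd)
      } else {
        obj <- readRDS(fs[i])
        if (!identical(obj$format, "phagotrack-grid"))
          stop("not a phagotrack serialized grid: ", fs[i])
        stacks[[i]] <- volume_stack(obj$intensities, i,
                                    obj$voxel_size %||% vs,
                                    obj$frame_interval %||% fi,
                                    obj$bit_depth %||% bd)
      }
    }
  }
  d <- vapply(stacks, function(s) dim(s$intensities), integer(3))
  bad <- which(colSums(d != d[, 1]) > 0)
  if (length(bad))
    stop("mixed stack dimensions at time point ", bad[1])
  volume_sequence(stacks, source_layout = layout)
}

#' Write a volume sequence to disk
#'
#' Inverse of [read_sequence()]. Integer intensities round-trip bit-exactly
#' through the TIFF layouts at the sequence's bit depth.
#'
#' @param seq a [volume_sequence()].
#' @param path output directory (created if missing).
#' @param layout output layout, see [read_sequence()].
#' @param bit_depth TIFF bit depth (8 or 16); defaults to the stacks'.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path,
                           layout = c("slice_folders", "multipage_tiff",
                                      "serialized"),
                           bit_depth = NULL) {
  layout <- match.arg(layout)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  bd <- bit_depth %||% seq$stacks[[1]]$bit_depth
  if (layout != "serialized" && !bd %in% c(8L, 16L))
    stop("TIFF output supports bit depths 8 and 16")
  maxv <- 2^bd - 1
  for (i in seq_along(seq$stacks)) {
    st <- seq$stacks[[i]]
    if (layout == "serialized") {
      saveRDS(list(format = "phagotrack-grid", version = 1L,
                   intensities = st$intensities, voxel_size = st$voxel_size,
                   frame_interval = st$frame_interval,
                   time_index = st$time_index, bit_depth = st$bit_depth),
              file.path(path, sprintf("t%04d.rds", i)))
      next
    }
    arr <- pmin(pmax(st$intensities, 0), maxv) / maxv
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    if (layout == "multipage_tiff") {
      tiff::writeTIFF(pages, file.path(path, sprintf("t%04d.tif", i)),
                      bits.per.sample = bd)
    } else {
      tdir <- file.path(path, sprintf("t%04d", i))
      dir.create(tdir, showWarnings = FALSE)
      for (k in seq_along(pages))
        tiff::writeTIFF(pages[[k]], file.path(tdir, sprintf("z%03d.tif", k)),
                        bits.per.sample = bd)
    }
  }
  meta <- list(voxel_size = seq$stacks[[1]]$voxel_size,
               frame_interval = seq$stacks[[1]]$frame_interval,
               bit_depth = seq$stacks[[1]]$bit_depth)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify channels as fluorescent or DIC from their histograms
#'
#' Fluorescent channels concentrate most voxels at low intensities while
#' transmitted-light (DIC) channels peak mid-range. A channel is tagged
#' `fluorescent` when the fraction of voxels in the lowest
#' `low_range_fraction` of its observed dynamic range reaches `cutoff`.
#' The statistic is computed on the per-channel dynamic range, so the
#' classification is invariant to global intensity rescaling.
#'
#' @param channels a [volume_sequence()], a [volume_stack()], a 3D array, or
#'   a list of any of these (one element per channel, in acquisition order).
#' @param low_range_fraction fraction of the dynamic range counted as "low".
#' @param cutoff minimum low fraction for the `fluorescent` tag.
#' @param override optional character vector of tags to force per channel
#'   (`NA` entries keep the inferred tag).
#' @return A list of `channel_profile` objects with fields `histogram`,
#'   `low_fraction`, `inferred_type`.
#' @export
classify_channels <- function(channels, low_range_fraction = 0.25,
                              cutoff = 0.85, override = NULL) {
  as_values <- function(ch) {
    if (inherits(ch, "volume_sequence"))
      return(unlist(lapply(ch$stacks, function(s) as.vector(s$intensities))))
    if (inherits(ch, "volume_stack")) return(as.vector(ch$intensities))
    if (is.array(ch) || is.numeric(ch)) return(as.vector(ch))
    stop("unsupported channel object")
  }
  if (inherits(channels, c("volume_sequence", "volume_stack")) ||
      is.array(channels))
    channels <- list(channels)
  out <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    v <- as_values(channels[[i]])
    if (!length(v)) stop("channel ", i, " is empty")
    rng <- range(v)
    lowf <- if (rng[2] > rng[1])
      mean(v < rng[1] + low_range_fraction * diff(rng)) else 1
    type <- if (lowf >= cutoff) "fluorescent" else "dic"
    if (!is.null(override) && !is.na(override[i])) type <- override[i]
    h <- graphics::hist(v, breaks = 64, plot = FALSE)
    out[[i]] <- structure(
      list(histogram = list(mids = h$mids, counts = h$counts),
           low_fraction = lowf, inferred_type = type),
      class = "channel_profile")
  }
  out
}

#' Reduce a stack by in-plane 2x2 averaging
#'
#' Groups of four contiguous voxels on each z-slice are averaged into one
#' voxel of the output, halving rows and columns while leaving the slice
#' count unchanged; this trades spatial resolution for an improved
#' signal-to-noise ratio. A trailing odd row/column is cropped. The in-plane
#' voxel size doubles.
#'
#' @param stack a [volume_stack()] (rows and cols at least 2).
#' @return The reduced [volume_stack()].
#' @export
reduce_stack <- function(stack) {
  x <- stack$intensities
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2) stop("need at least 2 rows and 2 columns")
  nr <- d[1] %/% 2L; nc <- d[2] %/% 2L
  x <- x[seq_len(2L * nr), seq_len(2L * nc), , drop = FALSE]
  odd_r <- seq(1L, 2L * nr, by = 2L); odd_c <- seq(1L, 2L * nc, by = 2L)
  red <- (x[odd_r, odd_c, , drop = FALSE] +
          x[odd_r + 1L, odd_c, , drop = FALSE] +
          x[odd_r, odd_c + 1L, , drop = FALSE] +
          x[odd_r + 1L, odd_c + 1L, , drop = FALSE]) / 4
  volume_stack(red, stack$time_index,
               stack$voxel_size * c(2, 2, 1), stack$frame_interval,
               stack$bit_depth)
}

#' @rdname reduce_stack
#' @param seq a [volume_sequence()].
#' @export
reduce_sequence <- function(seq) {
  volume_sequence(lapply(seq$stacks, reduce_stack),
                  channel_labels = seq$channel_labels,
                  source_layout = seq$source_layout)
}

#' Map coordinates between the original and the 2x2-reduced grid
#'
#' Voxel centres 1 and 2 of the original grid average into voxel centre 1 of
#' the reduced grid, so `x_reduced = (x_original + 0.5) / 2` in-plane; z is
#' unchanged.
#'
#' @param xy numeric vector or matrix of in-plane coordinates.
#' @return Transformed coordinates.
#' @export
to_reduced_coords <- function(xy) (xy + 0.5) / 2

#' @rdname to_reduced_coords
#' @export
to_original_coords <- function(xy) 2 * xy - 0.5

`%||%` <- function(a, b) if (is.null(a)) b else a
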