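#' Segmentation parameters
#'
#' @param threshold_fraction multiplier applied to both automatically
#'   determined thresholds (1 = use them as computed; the robustness sweep
#'   varies this between 0.4 and 1.4).
#' @param connectivity 3D voxel connectivity, 6 or 26.
#' @param outlier_k number of standard deviations above the pooled mean
#'   volume beyond which an object is treated as two merged cells.
#' @param n_bins number of histogram bins for the Otsu threshold scan.
#' @param background_trim restrict the Otsu histogram to voxels above a
#'   robust background floor (median + `trim_k` * 1.4826 * MAD). For the
#'   sparse foregrounds typical of fluorescence volumes (well below 1% of
#'   voxels) the raw-histogram two-threshold optimum degenerates to a split
#'   of the dominant background mode; trimming removes that mode so the
#'   scan separates signal from the background tail. Set `FALSE` for the
#'   literal full-histogram scan.
#' @param trim_k MAD multiplier for the background floor.
#' @param per_timepoint compute thresholds per time point instead of once
#'   from the pooled histogram of the whole dataset.
#' @param erode_in_plane restrict outlier-splitting erosion to a 3x3x1
#'   element (useful when the z step is much larger than the pixel pitch).
#' @param max_erosions cap on sequential erosions when splitting an
#'   outlier; an object still unsplit is left intact and flagged.
#' @param min_volume minimum object volume in voxels; smaller connected
#'   components (isolated noise excursions, far below any credible cell
#'   cross-section) are discarded after labelling. 0 disables.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_fraction = 1, connectivity = 26,
                                outlier_k = 3, n_bins = 256,
                                background_trim = TRUE, trim_k = 3,
                                per_timepoint = FALSE,
                                erode_in_plane = FALSE, max_erosions = 30,
                                min_volume = 5) {
  if (threshold_fraction <= 0) stop("'threshold_fraction' must be positive")
  if (!connectivity %in% c(6, 26)) stop("'connectivity' must be 6 or 26")
  structure(list(threshold_fraction = threshold_fraction,
                 connectivity = as.integer(connectivity),
                 outlier_k = outlier_k, n_bins = as.integer(n_bins),
                 background_trim = isTRUE(background_trim), trim_k = trim_k,
                 per_timepoint = isTRUE(per_timepoint),
                 erode_in_plane = isTRUE(erode_in_plane),
                 max_erosions = as.integer(max_erosions),
                 min_volume = min_volume),
            class = "segmentation_params")
}

# Exhaustive 3-class Otsu: maximise between-class variance over all
# threshold pairs of an n-bin histogram. Returns the two bin-boundary
# intensities (first maximum in scan order on ties).
.otsu3 <- function(values, n_bins = 256) {
  rng <- range(values)
  if (rng[1] == rng[2]) stop("intensity distribution is constant; no threshold exists")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_bins)
  p <- cnt / sum(cnt)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  P <- cumsum(p)                 # P[i] = mass of bins 1..i
  S <- cumsum(p * mid)           # first-moment cumulative
  Ptot <- P[n_bins]; Stot <- S[n_bins]
  best <- -Inf; best_t <- c(1L, 2L)
  for (t1 in seq_len(n_bins - 2L)) {
    w1 <- P[t1]; s1 <- S[t1]
    t2 <- seq(t1 + 1L, n_bins - 1L)
    w2 <- P[t2] - w1; s2 <- S[t2] - s1
    w3 <- Ptot - P[t2]; s3 <- Stot - S[t2]
    # between-class variance up to the constant global mean square
    v <- ifelse(w1 > 0, s1^2 / w1, 0) + ifelse(w2 > 0, s2^2 / w2, 0) +
      ifelse(w3 > 0, s3^2 / w3, 0)
    j <- which.max(v)
    if (v[j] > best) { best <- v[j]; best_t <- c(t1, t2[j]) }
  }
  c(low = breaks[best_t[1] + 1L], high = breaks[best_t[2] + 1L])
}

.pool_values <- function(x) {
  if (inherits(x, "volume_sequence"))
    return(unlist(lapply(x$stacks, function(s) as.vector(s$intensities))))
  if (inherits(x, "volume_stack")) return(as.vector(x$intensities))
  if (is.array(x) || is.numeric(x)) return(as.vector(x))
  stop("unsupported input for thresholding")
}

#' Automatic hysteresis thresholds via three-class Otsu
#'
#' The lower and upper hysteresis thresholds are the two boundaries of a
#' 3-class Otsu partition of the intensity histogram (exhaustive
#' between-class-variance maximisation over all threshold pairs), each then
#' multiplied by `threshold_fraction`. By default the histogram is pooled
#' over the whole dataset and restricted to voxels above a robust
#' background floor; see [segmentation_params()].
#'
#' @param x a [volume_sequence()], [volume_stack()] or 3D array.
#' @param params a [segmentation_params()].
#' @return Named numeric `c(low, high)`, with `low < high`.
#' @export
auto_thresholds <- function(x, params = segmentation_params()) {
  v <- .pool_values(x)
  if (min(v) == max(v)) stop("intensity distribution is constant; no threshold exists")
  use <- v
  if (params$background_trim) {
    floorv <- median(v) + params$trim_k * mad(v)
    keep <- v > floorv
    # fall back to the full histogram when trimming degenerates
    if (sum(keep) >= 50 && diff(range(v[keep])) > 0) use <- v[keep]
  }
  th <- .otsu3(use, params$n_bins) * params$threshold_fraction
  if (th[1] >= th[2]) th[2] <- th[1] + .Machine$double.eps * abs(th[1])
  th
}

#' Double-threshold hysteresis mask
#'
#' Voxels below `low` are background; voxels at or above `high` are seeds;
#' voxels in between are foreground only when they belong to a connected
#' component of `{v >= low}` containing at least one seed (Schmitt-trigger
#' hysteresis).
#'
#' @param x a [volume_stack()] or 3D array.
#' @param low,high thresholds, `low <= high`.
#' @param connectivity 6 or 26.
#' @return Logical 3D array.
#' @export
hysteresis_mask <- function(x, low, high, connectivity = 26) {
  if (low > high) stop("'low' must not exceed 'high'")
  arr <- if (inherits(x, "volume_stack")) x$intensities else x
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  mask <- arr >= low
  seed <- arr >= high
  out <- .cpp_flood_from_seeds(as.logical(mask), as.logical(seed),
                               dim(arr), as.integer(connectivity))
  dim(out) <- dim(arr)
  out
}

#' Label connected components and measure them
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @param intensities optional 3D array for per-region mean intensity and
#'   (if `weighted_centroid`) intensity-weighted centroids.
#' @param weighted_centroid use intensity-weighted centroids (off by
#'   default: plain voxel centroids).
#' @return List with `labels` (integer 3D array, consecutive labels from 1)
#'   and `records` (data frame: label, x, y, z, volume, mean_intensity and
#'   bounding box columns).
#' @export
label_regions <- function(mask, connectivity = 26, intensities = NULL,
                          weighted_centroid = FALSE) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  lab <- .cpp_label3d(as.logical(mask), dim(mask), as.integer(connectivity))
  dim(lab) <- dim(mask)
  list(labels = lab, records = .region_records(lab, intensities,
                                               weighted_centroid))
}

.region_records <- function(lab, intensities = NULL,
                            weighted_centroid = FALSE) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      z = numeric(), volume = numeric(),
                      mean_intensity = numeric(),
                      x0 = integer(), x1 = integer(), y0 = integer(),
                      y1 = integer(), z0 = integer(), z1 = integer()))
  li <- lab[idx]
  co <- arrayInd(idx, dim(lab))
  n <- max(li)
  vol <- tabulate(li, n)
  w <- if (weighted_centroid && !is.null(intensities))
    as.numeric(intensities[idx]) else rep(1, length(idx))
  sw <- as.vector(rowsum(w, li))
  cx <- as.vector(rowsum(w * co[, 2], li)) / sw
  cy <- as.vector(rowsum(w * co[, 1], li)) / sw
  cz <- as.vector(rowsum(w * co[, 3], li)) / sw
  mi <- if (!is.null(intensities))
    as.vector(rowsum(as.numeric(intensities[idx]), li)) / vol else NA_real_
  li <- factor(li, levels = seq_len(n))
  data.frame(label = seq_len(n), x = cx, y = cy, z = cz, volume = vol,
             mean_intensity = mi,
             x0 = as.integer(tapply(co[, 2], li, min)),
             x1 = as.integer(tapply(co[, 2], li, max)),
             y0 = as.integer(tapply(co[, 1], li, min)),
             y1 = as.integer(tapply(co[, 1], li, max)),
             z0 = as.integer(tapply(co[, 3], li, min)),
             z1 = as.integer(tapply(co[, 3], li, max)),
             row.names = NULL)
}

#' Segment one stack with hysteresis thresholding
#'
#' @param stack a [volume_stack()].
#' @param low,high hysteresis thresholds.
#' @param params a [segmentation_params()].
#' @return A `labeled_stack`: list with `labels`, `records` and
#'   `time_index`.
#' @export
segment_stack <- function(stack, low, high,
                          params = segmentation_params()) {
  mask <- hysteresis_mask(stack, low, high, params$connectivity)
  lr <- label_regions(mask, params$connectivity, stack$intensities)
  if (params$min_volume > 0 &&
      any(small <- lr$records$volume < params$min_volume)) {
    keep <- lr$records$label[!small]
    remap <- integer(max(lr$records$label)); remap[keep] <- seq_along(keep)
    idx <- which(lr$labels > 0)
    lr$labels[idx] <- remap[lr$labels[idx]]
    lr$records <- lr$records[!small, , drop = FALSE]
    lr$records$label <- seq_len(nrow(lr$records))
    rownames(lr$records) <- NULL
  }
  structure(list(labels = lr$labels, records = lr$records,
                 time_index = stack$time_index),
            class = "labeled_stack")
}

#' Segment every time point of a sequence
#'
#' Thresholds are determined once from the pooled dataset histogram (or per
#' time point when `params$per_timepoint`), multiplied by
#' `params$threshold_fraction`, and applied to every stack. Precomputed
#' thresholds can be supplied to bypass the automatic selection.
#'
#' @param seq a [volume_sequence()].
#' @param params a [segmentation_params()].
#' @param thresholds optional `c(low, high)` (already scaled).
#' @return List of `labeled_stack` objects, with the thresholds used in
#'   `attr(, "thresholds")`.
#' @export
segment_sequence <- function(seq, params = segmentation_params(),
                             thresholds = NULL) {
  if (is.null(thresholds) && !params$per_timepoint)
    thresholds <- auto_thresholds(seq, params)
  out <- vector("list", length(seq$stacks))
  for (i in seq_along(seq$stacks)) {
    th <- if (is.null(thresholds))
      auto_thresholds(seq$stacks[[i]], params) else thresholds
    out[[i]] <- segment_stack(seq$stacks[[i]], th[1], th[2], params)
  }
  attr(out, "thresholds") <- thresholds
  out
}

#' Split volume outliers by sequential erosion
#'
#' The distribution of object volumes is pooled over all time points; any
#' object whose volume exceeds `mean + outlier_k * sd` is assumed to be two
#' cells merged by the segmentation. The object is eroded with a 3x3x3
#' element (3x3x1 when `erode_in_plane`) until it separates into two or
#' more components; every original voxel is then reassigned to the nearest
#' surviving component, geodesically within the object, so total foreground
#' volume is conserved. Objects that vanish before separating are left
#' intact and flagged `unsplittable`. Labels are refreshed to consecutive
#' integers afterwards.
#'
#' @param labeled list of `labeled_stack` objects (from
#'   [segment_sequence()]).
#' @param params a [segmentation_params()].
#' @return The updated list; each `records` data frame gains a
#'   `split_flag` column (`none`, `split` or `unsplittable`).
#' @export
split_volume_outliers <- function(labeled, params = segmentation_params()) {
  vols <- unlist(lapply(labeled, function(l) l$records$volume))
  for (i in seq_along(labeled))
    if (nrow(labeled[[i]]$records))
      labeled[[i]]$records$split_flag <- "none"
  if (length(vols) < 2) return(labeled)
  thr <- mean(vols) + params$outlier_k * sd(vols)
  for (i in seq_along(labeled)) {
    rec <- labeled[[i]]$records
    out_labs <- rec$label[rec$volume > thr]
    if (!length(out_labs)) next
    lab <- labeled[[i]]$labels
    for (lb in out_labs) {
      res <- .split_object(lab, lb, params)
      lab <- res$labels
    }
    flag_tab <- attr(lab, "split_flags")
    # refresh labels to consecutive integers and rebuild records
    idx <- which(lab > 0)
    old <- sort(unique(lab[idx]))
    remap <- integer(max(old)); remap[old] <- seq_along(old)
    lab[idx] <- remap[lab[idx]]
    attr(lab, "split_flags") <- NULL
    rec2 <- .region_records(lab, NULL)
    rec2$split_flag <- "none"
    if (!is.null(flag_tab)) {
      keep <- flag_tab$label <= length(remap) & remap[flag_tab$label] > 0
      rec2$split_flag[remap[flag_tab$label[keep]]] <- flag_tab$flag[keep]
    }
    labeled[[i]]$labels <- lab
    labeled[[i]]$records <- rec2
  }
  labeled
}

# Erode one labelled object until it splits; reassign voxels to the nearest
# surviving component. Returns the updated label array and a flag.
.split_object <- function(lab, lb, params) {
  d <- dim(lab)
  obj <- lab == lb
  idx <- which(obj)
  co <- arrayInd(idx, d)
  pad <- 1L
  rr <- max(1L, min(co[, 1]) - pad):min(d[1], max(co[, 1]) + pad)
  cc <- max(1L, min(co[, 2]) - pad):min(d[2], max(co[, 2]) + pad)
  ss <- max(1L, min(co[, 3]) - pad):min(d[3], max(co[, 3]) + pad)
  sub <- obj[rr, cc, ss, drop = FALSE]
  dim(sub) <- c(length(rr), length(cc), length(ss))
  eroded <- sub
  flag <- "unsplittable"
  for (it in seq_len(params$max_erosions)) {
    nxt <- .cpp_erode3d(as.logical(eroded), dim(sub), params$erode_in_plane)
    dim(nxt) <- dim(sub)
    if (!any(nxt)) break                       # vanished before splitting
    comp <- .cpp_label3d(as.logical(nxt), dim(sub), 26L)
    ncomp <- max(comp)
    if (ncomp >= 2L) {
      part <- .cpp_geodesic_partition(as.logical(sub), comp, dim(sub))
      dim(part) <- dim(sub)
      newmax <- max(lab)
      # component 1 keeps the original label, others get fresh labels
      full <- array(0L, d)
      full[rr, cc, ss] <- part
      sel <- which(full > 1L & obj)
      lab[sel] <- newmax + full[sel] - 1L
      flag <- "split"
      fl <- data.frame(label = c(lb, newmax + seq_len(ncomp - 1L)),
                       flag = "split")
      sf <- attr(lab, "split_flags")
      attr(lab, "split_flags") <- rbind(sf, fl)
      return(list(labels = lab, flag = flag))
    }
    eroded <- nxt
  }
  sf <- attr(lab, "split_flags")
  attr(lab, "split_flags") <- rbind(sf, data.frame(label = lb,
                                                   flag = "unsplittable"))
  list(labels = lab, flag = flag)
}
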