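#' Specification of a synthetic benchmark dataset
#'
#' Describes a time-lapse of Gaussian-blob cells moving along parametric
#' paths through a 3D field, to be rendered noiselessly and then corrupted
#' with calibrated noise. The default geometry is 98 time points of 11
#' slices of 275 x 275 pixels with six cells whose paths realise different
#' conditions of tortuosity, time to activation and proximity to other
#' cells.
#'
#' @param n_cells number of cells.
#' @param n_timepoints number of frames.
#' @param rows,cols,slices field dimensions.
#' @param shape `"anisotropic_gaussian"` (elongated blobs with per-cell
#'   orientation) or `"irregular"` (a basic isotropic Gaussian overlapped
#'   with six isotropic Gaussians at random x/y offsets, a lumpier, more
#'   realistic cell shape).
#' @param amplitude peak blob intensity above background.
#' @param background background intensity level.
#' @param bit_depth bit depth defining the valid range `[0, 2^bit - 1]`
#'   used when clipping noisy intensities and quantising on export.
#' @param width_xy in-plane Gaussian widths (major, minor), pixels.
#' @param width_z Gaussian width along z, slices.
#' @param path_styles character vector of per-cell path styles, recycled;
#'   see Details.
#' @param truncation blobs are rendered out to this many widths.
#' @param volume_gradient when non-zero, cell widths scale so that cell
#'   volume grows linearly with column position: volume proportional to
#'   `1 + volume_gradient * x / cols` (emulates swelling on approach to a
#'   wound at the right edge).
#' @param irregular_shift maximum random x/y offset (pixels) of the six
#'   satellite Gaussians of the irregular shape.
#'
#' @details Path styles: `straight` (constant velocity), `sinuous` and
#' `tortuous` (sinusoidal lateral motion of moderate and high tortuosity),
#' `delayed` (idle for 30 frames, then straight: late activation),
#' `proximity_a`/`proximity_b` (a pair that approaches to about two cell
#' diameters and separates again), `crossing_a`/`crossing_b` (a pair whose
#' paths actually cross, approaching closer than one cell diameter),
#' `transit` (fast straight traversal of the whole field width, with
#' per-cell stagger; used for position-dependent volume experiments). The
#' default set is `straight, sinuous, tortuous, delayed, proximity_a,
#' proximity_b`.
#'
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 6, n_timepoints = 98, rows = 275,
                           cols = 275, slices = 11,
                           shape = c("anisotropic_gaussian", "irregular"),
                           amplitude = 200, background = 15,
                           bit_depth = 8L, width_xy = c(3.5, 2.3),
                           width_z = 1.3, path_styles = NULL,
                           truncation = 3, volume_gradient = 0,
                           irregular_shift = 2.5) {
  shape <- match.arg(shape)
  if (any(c(rows, cols, slices, n_timepoints, n_cells) < 1))
    stop("dimensions and counts must be positive")
  if (amplitude <= background)
    stop("'amplitude' must exceed the background level")
  if (truncation * max(width_xy) * 2 > min(rows, cols))
    stop("cells are larger than the field")
  if (is.null(path_styles))
    path_styles <- c("straight", "sinuous", "tortuous", "delayed",
                     "proximity_a", "proximity_b")
  structure(list(n_cells = as.integer(n_cells),
                 n_timepoints = as.integer(n_timepoints),
                 rows = as.integer(rows), cols = as.integer(cols),
                 slices = as.integer(slices), shape = shape,
                 amplitude = amplitude, background = background,
                 bit_depth = as.integer(bit_depth),
                 width_xy = width_xy, width_z = width_z,
                 path_styles = rep_len(path_styles, n_cells),
                 truncation = truncation,
                 volume_gradient = volume_gradient,
                 irregular_shift = irregular_shift),
            class = "synthetic_spec")
}

# Parametric path library. Returns data.frame(cell, t, x, y, z, theta).
.synthetic_paths <- function(spec) {
  tt <- seq_len(spec$n_timepoints)
  n <- spec$n_timepoints
  sx <- spec$cols / 275; sy <- spec$rows / 275  # scale to the field
  mkpath <- function(cell, style) {
    th <- (cell - 1) * pi / spec$n_cells
    p <- switch(
      style,
      straight = list(x = 30 + (tt - 1) * 195 / max(n - 1, 1),
                      y = rep(45, n)),
      sinuous = list(x = 28 + (tt - 1) * 200 / max(n - 1, 1),
                     y = 95 + 22 * sin(2 * pi * tt / 40)),
      tortuous = list(x = 30 + (tt - 1) * 160 / max(n - 1, 1),
                      y = 150 + 12 * sin(2 * pi * tt / 24)),
      delayed = list(x = 40 + pmax(tt - 31, 0) * 160 / max(n - 31, 1),
                     y = rep(190, n)),
      transit = list(x = 5.5 + (((tt - 1) * 264 / max(n - 1, 1)) +
                                  (cell - 1) * 264 / spec$n_cells) %% 264,
                     y = rep(275 * (0.1 + 0.8 * (cell - 1) /
                                      max(spec$n_cells - 1, 1)), n)),
      proximity_a = list(x = 35 + (tt - 1) * 180 / max(n - 1, 1),
                         y = 221 + 8 * exp(-((tt - n / 2) / (n / 6))^2)),
      proximity_b = list(x = 35 + (tt - 1) * 180 / max(n - 1, 1),
                         y = 253 - 8 * exp(-((tt - n / 2) / (n / 6))^2)),
      crossing_a = list(x = 35 + (tt - 1) * 180 / max(n - 1, 1),
                        y = 140 - 25 + 50 * (tt - 1) / max(n - 1, 1)),
      crossing_b = list(x = 35 + (tt - 1) * 180 / max(n - 1, 1),
                        y = 140 + 25 - 50 * (tt - 1) / max(n - 1, 1)),
      stop("unknown path style: ", style))
    z <- spec$slices / 2 + 0.5 +
      min(1.2, spec$slices / 8) * sin(2 * pi * tt / 50 + cell)
    data.frame(cell = cell, t = tt, x = p$x * sx, y = p$y * sy, z = z,
               theta = th)
  }
  do.call(rbind, lapply(seq_len(spec$n_cells),
                        function(i) mkpath(i, spec$path_styles[i])))
}

# Width scale factor realising a linear volume gradient along x.
.width_scale <- function(spec, x) {
  if (spec$volume_gradient == 0) return(1)
  (1 + spec$volume_gradient * x / spec$cols)^(1 / 3)
}

# Render one cell's intensity contribution into the frame array.
.render_cell <- function(arr, spec, cx, cy, cz, theta, offsets = NULL) {
  d <- dim(arr)
  s <- .width_scale(spec, cx)
  wx <- spec$width_xy[1] * s; wy <- spec$width_xy[2] * s
  wz <- spec$width_z * s
  ext_xy <- spec$truncation * max(wx, wy)
  rr <- max(1, floor(cy - ext_xy)):min(d[1], ceiling(cy + ext_xy))
  cc <- max(1, floor(cx - ext_xy)):min(d[2], ceiling(cx + ext_xy))
  ss <- max(1, floor(cz - spec$truncation * wz)):
    min(d[3], ceiling(cz + spec$truncation * wz))
  if (!length(rr) || !length(cc) || !length(ss)) return(arr)
  dy <- rr - cy; dx <- cc - cx; dz <- ss - cz
  gx <- outer(dy * 0, dx, `+`); gy <- outer(dy, dx * 0, `+`)
  if (spec$shape == "anisotropic_gaussian" || is.null(offsets)) {
    u <- cos(theta) * gx + sin(theta) * gy
    v <- -sin(theta) * gx + cos(theta) * gy
    q2d <- (u / wx)^2 + (v / wy)^2
    prof <- lapply(dz, function(ddz) {
      q <- q2d + (ddz / wz)^2
      val <- spec$amplitude * exp(-q / 2)
      val[q > spec$truncation^2] <- 0
      val
    })
  } else {
    # irregular: max over base blob and satellite isotropic blobs
    w0 <- mean(spec$width_xy) * s
    prof <- lapply(dz, function(ddz) {
      best <- (gx / w0)^2 + (gy / w0)^2 + (ddz / wz)^2
      for (o in seq_len(nrow(offsets))) {
        q <- ((gx - offsets[o, 1]) / w0)^2 +
          ((gy - offsets[o, 2]) / w0)^2 + (ddz / wz)^2
        best <- pmin(best, q)
      }
      val <- spec$amplitude * exp(-best / 2)
      val[best > spec$truncation^2] <- 0
      val
    })
  }
  for (k in seq_along(ss))
    arr[rr, cc, ss[k]] <- arr[rr, cc, ss[k]] + prof[[k]]
  arr
}

#' Generate a synthetic benchmark dataset with gold-standard tracks
#'
#' Renders the noiseless time-lapse described by `spec`: each cell is a
#' Gaussian blob (anisotropic, with per-cell orientation, or an irregular
#' overlap of isotropic Gaussians) moving along its parametric path, summed
#' onto a constant background. The gold standard records each cell's exact
#' centroid per frame and its rendered half-maximum volume.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (used for the irregular shape offsets; the
#'   anisotropic rendering is fully deterministic).
#' @return List with `sequence` (a noiseless [volume_sequence()], floating
#'   point) and `gold` (data frame `cell, t, x, y, z, volume`).
#' @export
generate_dataset <- function(spec, seed = 1L) {
  paths <- .synthetic_paths(spec)
  offsets <- NULL
  if (spec$shape == "irregular") {
    set.seed(seed)
    offsets <- lapply(seq_len(spec$n_cells), function(i)
      matrix(stats::runif(12, -spec$irregular_shift, spec$irregular_shift),
             ncol = 2))
  }
  half <- spec$background + spec$amplitude / 2
  stacks <- vector("list", spec$n_timepoints)
  gold_vol <- numeric(nrow(paths))
  for (t in seq_len(spec$n_timepoints)) {
    arr <- array(spec$background,
                 c(spec$rows, spec$cols, spec$slices))
    pt <- paths[paths$t == t, , drop = FALSE]
    for (i in seq_len(nrow(pt)))
      arr <- .render_cell(arr, spec, pt$x[i], pt$y[i], pt$z[i],
                          pt$theta[i],
                          if (!is.null(offsets)) offsets[[pt$cell[i]]])
    # half-maximum volumes per cell (local count around each centroid)
    for (i in seq_len(nrow(pt))) {
      gold_vol[paths$t == t & paths$cell == pt$cell[i]] <-
        .halfmax_volume(arr, spec, pt$x[i], pt$y[i], pt$z[i], half)
    }
    stacks[[t]] <- volume_stack(arr, t, bit_depth = spec$bit_depth)
  }
  gold <- paths[, c("cell", "t", "x", "y", "z")]
  gold$volume <- gold_vol
  rownames(gold) <- NULL
  list(sequence = volume_sequence(stacks), gold = gold)
}

.halfmax_volume <- function(arr, spec, cx, cy, cz, half) {
  d <- dim(arr)
  ext <- spec$truncation * max(spec$width_xy) *
    .width_scale(spec, cx)
  rr <- max(1, floor(cy - ext)):min(d[1], ceiling(cy + ext))
  cc <- max(1, floor(cx - ext)):min(d[2], ceiling(cx + ext))
  sum(arr[rr, cc, ] >= half)
}

#' Half-maximum cell mask of a noiseless frame
#'
#' The voxels whose noiseless intensity reaches background + amplitude/2:
#' the "cell" class used for Bhattacharyya-distance and SNR estimation.
#'
#' @param stack a noiseless [volume_stack()] from [generate_dataset()].
#' @param spec the [synthetic_spec()] it was generated from.
#' @return Logical 3D array.
#' @export
gold_mask <- function(stack, spec) {
  stack$intensities >= spec$background + spec$amplitude / 2
}

#' Add noise to a volume sequence
#'
#' `white_gaussian` adds i.i.d. `N(0, sigma^2)` noise; `poisson_gaussian`
#' replaces each voxel by a Poisson draw with its noiseless intensity as
#' mean (photon shot noise) and then adds `N(0, sigma^2)` read noise — a
#' better model of multiphoton/confocal acquisition. Intensities are
#' clipped to the valid range `[0, 2^bit_depth - 1]`.
#'
#' @param seq a [volume_sequence()].
#' @param model `"white_gaussian"` or `"poisson_gaussian"`.
#' @param sigma Gaussian noise standard deviation (0 allowed for
#'   `poisson_gaussian`).
#' @param seed integer seed.
#' @return The noisy [volume_sequence()] (floating point; quantisation
#'   happens on export).
#' @export
add_noise <- function(seq, model = c("white_gaussian", "poisson_gaussian"),
                      sigma, seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (model == "white_gaussian" && sigma == 0) return(seq)
  set.seed(seed)
  out <- seq
  for (i in seq_along(seq$stacks)) {
    st <- seq$stacks[[i]]
    maxv <- 2^st$bit_depth - 1
    x <- st$intensities
    if (model == "poisson_gaussian")
      x <- array(rpois(length(x), as.vector(x)), dim(x))
    if (sigma > 0)
      x <- x + array(rnorm(length(x), 0, sigma), dim(x))
    x[x < 0] <- 0
    x[x > maxv] <- maxv
    out$stacks[[i]]$intensities <- x
  }
  out
}

#' Intensity-class statistics
#'
#' Mean, variance (population) and count of a set of voxel intensities, as
#' used by [bhattacharyya_distance()] and [snr_db()].
#'
#' @param values numeric vector of intensities.
#' @return List of class `class_stats` with `mean`, `var`, `n`.
#' @export
class_stats <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for class statistics")
  m <- mean(values)
  structure(list(mean = m, var = mean((values - m)^2), n = n),
            class = "class_stats")
}

#' Cell/background class statistics of a sequence
#'
#' Splits every voxel of `noisy` into the cell class (inside the
#' half-maximum gold mask derived from the matching noiseless sequence) and
#' the background class (everything else), and accumulates each class's
#' mean and variance.
#'
#' @param noisy the noisy [volume_sequence()].
#' @param clean the matching noiseless [volume_sequence()].
#' @param spec the [synthetic_spec()].
#' @return List with `signal` and `background` [class_stats()].
#' @export
empirical_class_stats <- function(noisy, clean, spec) {
  acc <- function() c(s = 0, s2 = 0, n = 0)
  a_sig <- acc(); a_bg <- acc()
  half <- spec$background + spec$amplitude / 2
  for (i in seq_along(noisy$stacks)) {
    m <- as.vector(clean$stacks[[i]]$intensities) >= half
    v <- as.vector(noisy$stacks[[i]]$intensities)
    vs <- v[m]; vb <- v[!m]
    a_sig <- a_sig + c(sum(vs), sum(vs^2), length(vs))
    a_bg <- a_bg + c(sum(vb), sum(vb^2), length(vb))
  }
  mk <- function(a) {
    m <- unname(a[1] / a[3])
    structure(list(mean = m, var = unname(a[2] / a[3]) - m^2,
                   n = unname(a[3])),
              class = "class_stats")
  }
  list(signal = mk(a_sig), background = mk(a_bg))
}

#' Bhattacharyya distance between two intensity classes
#'
#' Separability measure computed from the class means and variances:
#' `BD = 1/4 log(1/4 (v1/v2 + v2/v1 + 2)) + 1/4 (m1 - m2)^2 / (v1 + v2)`.
#' Symmetric, non-negative, zero only for identical statistics; larger
#' values mean more separable cell and background intensities.
#'
#' @param a,b [class_stats()] (or lists with `mean` and `var`).
#' @return The Bhattacharyya distance.
#' @export
bhattacharyya_distance <- function(a, b) {
  if (a$var <= 0 || b$var <= 0)
    stop("class variances must be positive")
  0.25 * log(0.25 * (a$var / b$var + b$var / a$var + 2)) +
    0.25 * (a$mean - b$mean)^2 / (a$var + b$var)
}

#' Signal-to-noise ratio between two intensity classes, in dB
#'
#' `20 log10` of the ratio of the root-mean-squared deviation of the cell
#' intensities about their class mean to that of the background.
#'
#' @param signal,background [class_stats()].
#' @return SNR in decibels.
#' @export
snr_db <- function(signal, background) {
  if (background$var <= 0) stop("background RMS must be positive")
  20 * log10(sqrt(signal$var) / sqrt(background$var))
}

# ---- noise calibration -----------------------------------------------------

# Noiseless per-class intensity profiles (weighted value tables) for the
# calibration model. The background, which is overwhelmingly the constant
# background level, is compressed into a weighted histogram.
#' Noiseless class intensity profiles for noise calibration
#'
#' @param clean a noiseless [volume_sequence()] from [generate_dataset()].
#' @param spec the matching [synthetic_spec()].
#' @param bg_bins histogram bins used to compress the background class.
#' @return List of class `class_profiles` with weighted value tables for
#'   the cell and background classes.
#' @export
clean_class_profiles <- function(clean, spec, bg_bins = 2048L) {
  half <- spec$background + spec$amplitude / 2
  top <- spec$background + spec$amplitude
  breaks <- seq(0, top, length.out = bg_bins + 1L)
  sig_vals <- NULL
  bg_cnt <- numeric(bg_bins)
  for (i in seq_along(clean$stacks)) {
    v <- as.vector(clean$stacks[[i]]$intensities)
    m <- v >= half
    sig_vals <- c(sig_vals, v[m])
    bg_cnt <- bg_cnt + tabulate(findInterval(v[!m], breaks,
                                             all.inside = TRUE), bg_bins)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- bg_cnt > 0
  structure(list(
    signal = data.frame(value = sig_vals, weight = 1),
    background = data.frame(value = mids[keep], weight = bg_cnt[keep]),
    max_value = 2^spec$bit_depth - 1), class = "class_profiles")
}

# Mean and variance of clip(v + N(0, sigma^2), 0, M) integrated over a
# weighted table of clean values v: exact censored-normal moments, so the
# calibration model matches the empirical statistics of the clipped noisy
# data without simulation.
.censored_class_stats <- function(tab, sigma, M) {
  v <- tab$value; w <- tab$weight / sum(tab$weight)
  if (sigma == 0) {
    vc <- pmin(pmax(v, 0), M)
    m <- sum(w * vc)
    return(list(mean = m, var = sum(w * vc^2) - m^2))
  }
  a <- (0 - v) / sigma; b <- (M - v) / sigma
  Pa <- pnorm(a); Pb <- pnorm(b); pa <- dnorm(a); pb <- dnorm(b)
  P <- Pb - Pa
  m1 <- M * (1 - Pb) + v * P + sigma * (pa - pb)
  m2 <- M^2 * (1 - Pb) + v^2 * P + 2 * v * sigma * (pa - pb) +
    sigma^2 * (P + a * pa - b * pb)
  mu <- sum(w * m1)
  list(mean = mu, var = sum(w * m2) - mu^2)
}

#' Model-predicted Bhattacharyya distance at a given noise level
#'
#' @param profiles [clean_class_profiles()] of the noiseless dataset.
#' @param sigma white Gaussian noise standard deviation.
#' @return The predicted BD between the noisy cell and background classes
#'   (clipping to the valid range accounted for exactly).
#' @export
model_bd <- function(profiles, sigma) {
  s <- .censored_class_stats(profiles$signal, sigma, profiles$max_value)
  b <- .censored_class_stats(profiles$background, sigma,
                             profiles$max_value)
  if (b$var <= 0) return(Inf)
  bhattacharyya_distance(s, b)
}

#' Calibrate the noise level to a target Bhattacharyya distance
#'
#' Finds, by deterministic bisection, the white-Gaussian noise standard
#' deviation at which the cell/background Bhattacharyya distance of the
#' noisy dataset equals `target_bd`. The model predicts the BD in closed
#' form from the noiseless class profiles, including the effect of
#' clipping to the valid intensity range, so the returned level reproduces
#' the target when the BD is re-estimated empirically from generated
#' voxels.
#'
#' @param profiles [clean_class_profiles()] (or a [synthetic_spec()], in
#'   which case the noiseless dataset is generated internally).
#' @param target_bd desired Bhattacharyya distance.
#' @param tolerance acceptable `|BD - target|`.
#' @return The calibrated sigma, with the achieved model BD as attribute
#'   `model_bd`.
#' @export
calibrate_noise <- function(profiles, target_bd, tolerance = 1e-4) {
  if (inherits(profiles, "synthetic_spec"))
    profiles <- clean_class_profiles(generate_dataset(profiles)$sequence,
                                     profiles)
  if (target_bd <= 0) stop("'target_bd' must be positive")
  lo <- 1e-6 * profiles$max_value
  hi <- 0.05 * profiles$max_value
  f <- function(s) model_bd(profiles, s) - target_bd
  if (f(lo) < 0)
    stop("target BD exceeds the attainable range (BD at near-zero noise is ",
         format(model_bd(profiles, lo), digits = 4), ")")
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 100 * profiles$max_value)
      stop("target BD below the attainable range")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tolerance) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  structure(mid, model_bd = fm + target_bd)
}

#' Noise levels matching a decreasing series of target separabilities
#'
#' @param profiles [clean_class_profiles()] or a [synthetic_spec()].
#' @param targets decreasing Bhattacharyya distances; the default is the
#'   benchmark series `1.61, 1.25, 1, 0.66, 0.45` (level 1 = most
#'   separable).
#' @param tolerance bisection tolerance on the BD.
#' @return Numeric vector of calibrated sigmas, one per target.
#' @export
calibrate_noise_levels <- function(profiles,
                                   targets = c(1.61, 1.25, 1, 0.66, 0.45),
                                   tolerance = 1e-4) {
  if (inherits(profiles, "synthetic_spec"))
    profiles <- clean_class_profiles(generate_dataset(profiles)$sequence,
                                     profiles)
  vapply(targets, function(tb)
    as.numeric(calibrate_noise(profiles, tb, tolerance)), numeric(1))
}
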