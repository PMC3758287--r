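test_that("three-class Otsu matches an independent exhaustive scan", {
  set.seed(21)
  # balanced bimodal mixture on a 64-bin histogram, scanned independently
  v <- c(rnorm(6000, 40, 6), rnorm(4000, 180, 15))
  v <- pmin(pmax(v, 0), 255)
  th <- phagotrack:::.otsu3(v, 64)
  # oracle: direct double loop over all threshold pairs
  breaks <- seq(min(v), max(v), length.out = 65)
  cnt <- tabulate(findInterval(v, breaks, all.inside = TRUE), 64)
  mid <- (breaks[-1] + breaks[-65]) / 2
  best <- -Inf; bt <- NULL
  for (t1 in 1:62) for (t2 in (t1 + 1):63) {
    w <- c(sum(cnt[1:t1]), sum(cnt[(t1 + 1):t2]), sum(cnt[(t2 + 1):64]))
    if (any(w == 0)) m <- c(0, 0, 0)
    m <- c(sum(cnt[1:t1] * mid[1:t1]),
           sum(cnt[(t1 + 1):t2] * mid[(t1 + 1):t2]),
           sum(cnt[(t2 + 1):64] * mid[(t2 + 1):64]))
    sb <- sum(ifelse(w > 0, m^2 / w, 0))
    if (sb > best) { best <- sb; bt <- c(breaks[t1 + 1], breaks[t2 + 1]) }
  }
  expect_equal(unname(th), unname(bt))
  expect_lt(th[1], th[2])
})

test_that("threshold_fraction scales both automatic thresholds", {
  set.seed(4)
  arr <- array(c(rnorm(8000, 20, 3), rnorm(2000, 200, 12)), c(100, 100, 1))
  arr <- pmax(arr, 0)
  p1 <- segmentation_params(background_trim = FALSE)
  p04 <- segmentation_params(threshold_fraction = 0.4,
                             background_trim = FALSE)
  expect_equal(auto_thresholds(arr, p04), 0.4 * auto_thresholds(arr, p1))
})

test_that("degenerate intensity distributions are handled", {
  expect_error(auto_thresholds(array(7, c(5, 5, 2))), "constant")
  # two-valued image: thresholds land in the gap, hysteresis == simple
  arr <- array(c(rep(0, 900), rep(100, 100)), c(10, 10, 10))
  th <- auto_thresholds(arr, segmentation_params(background_trim = FALSE))
  expect_true(th[1] > 0 && th[2] < 100 && th[1] < th[2])
  expect_equal(hysteresis_mask(arr, th[1], th[2]), arr >= th[2])
})

test_that("hysteresis keeps between-voxels only when connected to a seed", {
  prof <- array(c(0, 3, 7, 3, 0), c(5, 1, 1))
  expect_equal(as.vector(hysteresis_mask(prof, 2, 6)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(hysteresis_mask(array(c(0, 3, 3, 3, 0), c(5, 1, 1)),
                                   2, 6)))
})

test_that("hysteresis properties: threshold equality, monotonicity, class bounds", {
  set.seed(9)
  # random bump field: smooth structure plus noise
  arr <- array(runif(20^3, 0, 35), c(20, 20, 20))
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  for (b in 1:6) {
    cc <- runif(3, 4, 17)
    bump <- 90 * exp(-rowSums(sweep(idx, 2, cc)^2) / (2 * 9))
    arr <- arr + array(bump, c(20, 20, 20))
  }
  # low == high collapses to simple thresholding
  for (t in c(30, 55, 80))
    expect_equal(hysteresis_mask(arr, t, t), arr >= t)
  m0 <- hysteresis_mask(arr, 40, 70)
  # raising either threshold never adds foreground
  expect_true(all(m0 | !hysteresis_mask(arr, 50, 70)))
  expect_true(all(m0 | !hysteresis_mask(arr, 40, 85)))
  # no foreground voxel below low; every component holds a seed
  expect_true(all(arr[m0] >= 40))
  lab <- label_regions(m0)$labels
  for (lb in seq_len(max(lab)))
    expect_true(any(arr[lab == lb] >= 70))
})

test_that("connected-component labelling obeys the chosen connectivity", {
  a <- array(FALSE, c(3, 3, 1)); a[1, 1, 1] <- TRUE; a[2, 2, 1] <- TRUE
  expect_equal(max(label_regions(a, 26)$labels), 1)
  expect_equal(max(label_regions(a, 6)$labels), 2)

  b <- array(FALSE, c(10, 10, 4))
  b[1:3, 1:3, 1:2] <- TRUE
  b[7:9, 7:9, 3:4] <- TRUE
  lr <- label_regions(b, 26)
  expect_equal(nrow(lr$records), 2)
  expect_equal(sort(lr$records$volume), c(18, 18))
  expect_equal(nrow(label_regions(array(FALSE, c(4, 4, 2)))$records), 0)
})

test_that("region records carry centroids inside bounding boxes", {
  st <- sphere_stack(c(20, 15, 6), r = 4)
  lr <- label_regions(st$intensities > 100, 26, st$intensities)
  expect_equal(nrow(lr$records), 1)
  r <- lr$records
  expect_equal(r$x, 20, tolerance = 0.05)
  expect_equal(r$y, 15, tolerance = 0.05)
  expect_true(r$x >= r$x0 && r$x <= r$x1 && r$y >= r$y0 && r$y <= r$y1)
  expect_equal(r$mean_intensity, 210)
})

test_that("volume outliers are split by erosion with volume conserved", {
  # twelve normal spheres plus one dumbbell (two spheres + 1-voxel neck)
  dims <- c(60, 170, 14)
  arr <- array(0, dims)
  put_sphere <- function(arr, cc, r) {
    xs <- floor(cc[1] - r):ceiling(cc[1] + r)
    zs <- max(1, floor(cc[3] - r)):min(dims[3], ceiling(cc[3] + r))
    ys <- seq_len(dims[1])
    for (z in zs) for (x in xs) {
      d2 <- (x - cc[1])^2 + (ys - cc[2])^2 + (z - cc[3])^2
      arr[ys[d2 <= r^2], x, z] <- 1
    }
    arr
  }
  for (i in 1:12)
    arr <- put_sphere(arr, c(10 + 12 * ((i - 1) %% 6), 12 + 24 * (i > 6), 4),
                      3)
  arr <- put_sphere(arr, c(60, 45, 8), 5)
  arr <- put_sphere(arr, c(74, 45, 8), 5)
  arr[45, 60:74, 8] <- 1  # the bridging neck
  lab <- label_regions(arr == 1, 26)
  ls <- structure(list(labels = lab$labels, records = lab$records,
                       time_index = 1L), class = "labeled_stack")
  n_before <- sum(lab$labels > 0)
  expect_equal(nrow(lab$records), 13)
  out <- split_volume_outliers(list(ls), segmentation_params())
  rec <- out[[1]]$records
  expect_equal(nrow(rec), 14)              # dumbbell became two objects
  expect_equal(sum(rec$volume), n_before)  # voxel count conserved
  expect_equal(sum(out[[1]]$labels > 0), n_before)
  expect_equal(sum(rec$split_flag == "split"), 2)
  # the two halves are balanced
  halves <- sort(rec$volume[rec$split_flag == "split"])
  expect_gt(halves[1] / halves[2], 0.7)
})

test_that("a convex outlier is left intact and flagged unsplittable", {
  dims <- c(60, 170, 14)
  arr <- array(0, dims)
  put_sphere <- function(arr, cc, r) {
    xs <- floor(cc[1] - r):ceiling(cc[1] + r)
    zs <- max(1, floor(cc[3] - r)):min(dims[3], ceiling(cc[3] + r))
    ys <- seq_len(dims[1])
    for (z in zs) for (x in xs) {
      d2 <- (x - cc[1])^2 + (ys - cc[2])^2 + (z - cc[3])^2
      arr[ys[d2 <= r^2], x, z] <- 1
    }
    arr
  }
  for (i in 1:12)
    arr <- put_sphere(arr, c(10 + 12 * ((i - 1) %% 6), 12 + 24 * (i > 6), 4),
                      3)
  arr <- put_sphere(arr, c(80, 45, 7), 6.5)
  lab <- label_regions(arr == 1, 26)
  ls <- structure(list(labels = lab$labels, records = lab$records,
                       time_index = 1L), class = "labeled_stack")
  n_before <- sum(lab$labels > 0)
  out <- split_volume_outliers(list(ls), segmentation_params())
  rec <- out[[1]]$records
  expect_equal(nrow(rec), 13)
  expect_equal(sum(rec$volume), n_before)
  expect_equal(sum(rec$split_flag == "unsplittable"), 1)
})

test_that("sequences without outliers pass through unchanged", {
  sts <- lapply(1:2, function(t) sphere_stack(c(20, 20, 6), r = 4,
                                              time_index = t))
  labeled <- segment_sequence(volume_sequence(sts),
                              thresholds = c(50, 150))
  out <- split_volume_outliers(labeled, segmentation_params())
  expect_equal(out[[1]]$records$volume, labeled[[1]]$records$volume)
  expect_true(all(out[[1]]$records$split_flag == "none"))
})

test_that("min_volume discards sub-threshold specks and relabels", {
  arr <- array(0, c(20, 20, 4))
  arr[5:9, 5:9, 1:3] <- 200     # 75 voxels
  arr[15, 15, 2] <- 200         # single-voxel speck
  st <- volume_stack(arr + 10, bit_depth = 8L)
  ls <- segment_stack(st, 50, 150, segmentation_params(min_volume = 5))
  expect_equal(nrow(ls$records), 1)
  expect_equal(ls$records$label, 1)
  expect_equal(ls$records$volume, 75)
  ls2 <- segment_stack(st, 50, 150, segmentation_params(min_volume = 0))
  expect_equal(nrow(ls2$records), 2)
})
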