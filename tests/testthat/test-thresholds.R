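toy_volume <- function(slice_values, nx = 7, ny = 7) {
  v <- array(rep(slice_values, each = nx * ny), dim = c(nx, ny, length(slice_values)))
  image_volume(v, c(1, 1, 1))
}

test_that("reference slice is the argmax of the aorta-ROI means, ties to the smallest index", {
  vol <- toy_volume(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 100, 0, 0, 0, 0, 0, 0, 0, 0, 0, 250,
                      0, 0, 0, 0, 0, 0, 0, 0, 0, 200))
  rois <- roi_set(tibble::tibble(x_mm = 3, y_mm = 3, slice = c(10L, 20L, 30L),
                                 radius_mm = 1.2), target = "aorta")
  expect_identical(locate_reference_slice(vol, rois), 20L)

  flat <- toy_volume(rep(7, 5))
  rois_all <- roi_set(tibble::tibble(x_mm = 3, y_mm = 3, slice = NA_integer_,
                                     radius_mm = 1.2), target = "aorta")
  expect_identical(locate_reference_slice(flat, rois_all), 1L)
  expect_error(locate_reference_slice(flat, rois_all[0, ]), "")
})

test_that("reference-slice search equals a brute-force scan on a graded stack", {
  set.seed(4)
  vals <- round(stats::runif(24, 50, 280))
  vol <- toy_volume(vals)
  rois <- roi_set(tibble::tibble(x_mm = 3, y_mm = 3, slice = NA_integer_,
                                 radius_mm = 2), target = "aorta")
  expect_identical(locate_reference_slice(vol, rois), which.max(vals))
})

test_that("contrast value is the mean of the three per-slice ROI maxima", {
  # slices 10 apart in mm; reference at the brightest, offsets +-10 mm
  vals <- rep(100, 21); vals[11] <- 310; vals[1] <- 300; vals[21] <- 290
  vol <- image_volume(array(rep(vals, each = 25), dim = c(5, 5, 21)),
                      c(1, 1, 1))
  rois <- roi_set(tibble::tibble(x_mm = 2, y_mm = 2, slice = NA_integer_,
                                 radius_mm = 1.5), target = "aorta")
  expect_equal(compute_contrast_value(vol, rois), mean(c(300, 310, 290)))
  # uniform aorta: the value is the constant
  flat <- image_volume(array(220, dim = c(5, 5, 21)), c(1, 1, 1))
  expect_warning(v <- compute_contrast_value(flat, rois), "clamped")
  expect_equal(v, 220)
})

test_that("contrast value on a noisy phantom matches direct sampling of the same voxels", {
  spec <- tiny_phantom_spec(noise_sd = 5, seed = 8)
  ph <- generate_phantom(spec)
  rois <- phantom_roi_sets(spec, ph$volume, "CTA")
  # the uniform aorta puts the reference slice at the stack end: offsets clamp
  got <- suppressWarnings(compute_contrast_value(ph$volume, rois$aorta))
  # oracle: find the best-mean slice and average the three slice maxima by
  # direct voxel indexing
  vol <- ph$volume
  d <- dim(vol$values)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  r <- rois$aorta
  disc <- outer((xs - r$x_mm[1])^2, (ys - r$y_mm[1])^2, "+") <= r$radius_mm[1]^2
  means <- vapply(seq_len(d[3]), function(k) mean(vol$values[, , k][disc]),
                  numeric(1))
  ref <- which.max(means)
  off <- round(10 / vol$spacing[3])
  sl <- pmin(pmax(ref + c(-off, 0, off), 1), d[3])
  expected <- mean(vapply(sl, function(k) max(vol$values[, , k][disc]),
                          numeric(1)))
  expect_equal(got, expected)
  # and the value is the analytic lumen intensity up to noise order statistics
  expect_lt(abs(got - 300), 5 * 4)
})

test_that("background value averages per-ROI means and enforces ROI counts", {
  vol <- image_volume(array(0, dim = c(40, 40, 3)), c(1, 1, 1))
  centers <- cbind(c(5, 15, 25, 35), c(5, 15, 25, 35))
  for (i in 1:4) {
    vol$values[centers[i, 1] + 1, centers[i, 2] + 1, 2] <- 0  # placeholder
  }
  # paint uniform patches with means {60, 62, 58, 60}
  patch_vals <- c(60, 62, 58, 60)
  xs <- 0:39
  for (i in 1:4) {
    disc <- outer((xs - centers[i, 1])^2, (xs - centers[i, 2])^2, "+") <= 4
    sl <- vol$values[, , 2]; sl[disc] <- patch_vals[i]
    vol$values[, , 2] <- sl
  }
  rois <- roi_set(tibble::tibble(x_mm = centers[, 1], y_mm = centers[, 2],
                                 slice = 2L, radius_mm = 2), target = "psoas")
  expect_equal(compute_background_value(vol, rois), 60)
  expect_error(compute_background_value(vol, rois[1:3, ]), "strict")
  expect_equal(compute_background_value(vol, rois[1:3, ], strict = FALSE),
               mean(patch_vals[1:3]))
  # single-voxel ROIs: mean of the three values
  vol$values[11, 11, 1] <- 7; vol$values[21, 21, 1] <- 9; vol$values[31, 31, 1] <- 14
  tiny <- roi_set(tibble::tibble(x_mm = c(10, 20, 30), y_mm = c(10, 20, 30),
                                 slice = 1L, radius_mm = 0.4),
                  target = "vertebral")
  expect_equal(compute_background_value(vol, tiny), (7 + 9 + 14) / 3)
})

test_that("the lower threshold formula and its algebraic properties hold", {
  expect_identical(compute_lower_threshold(300, 60), 140)
  expect_identical(compute_lower_threshold(450, 30), 170)
  set.seed(1)
  for (i in 1:100) {
    a <- stats::runif(1, 100, 500); b <- stats::runif(1, 0, 100)
    k <- stats::runif(1, 0.5, 3)
    lt <- compute_lower_threshold(a, b)
    expect_equal(compute_lower_threshold(k * a, k * b), k * lt)   # linearity
    expect_equal(compute_lower_threshold(a, a), a)                # fixed point
    expect_true(lt > b && lt < a)                                 # convexity
  }
  expect_error(compute_lower_threshold(Inf, 60), "finite")
})

test_that("upper threshold exists only for CTA and ignores plaque outside the ROIs", {
  spec <- tiny_phantom_spec()
  ph <- cached("cta_tiny", generate_phantom(tiny_phantom_spec()))
  rois <- phantom_roi_sets(spec, ph$volume, "CTA")
  expect_error(compute_upper_threshold(ph$volume, rois$aorta, modality = "MRA"),
               "MRA")
  ut_clean <- suppressWarnings(compute_upper_threshold(ph$volume, rois$aorta))
  # plaque far from the aorta ROIs must not move the UT
  specp <- tiny_phantom_spec()
  specp$plaques <- tibble::tibble(x_mm = 14, y_mm = 6, z_mm = 15,
                                  radius_mm = 1.5, intensity = 800)
  php <- generate_phantom(specp)
  roisp <- phantom_roi_sets(specp, php$volume, "CTA")
  ut_plaque <- suppressWarnings(compute_upper_threshold(php$volume, roisp$aorta))
  expect_equal(ut_plaque, ut_clean)
})

test_that("estimated thresholds on the noise-free phantom are exact and scale linearly", {
  spec <- tiny_phantom_spec()   # lumen 300, background 60
  ph <- cached("cta_tiny", generate_phantom(tiny_phantom_spec()))
  rois <- phantom_roi_sets(spec, ph$volume, "CTA")
  thr <- suppressWarnings(estimate_thresholds(ph$volume, rois$aorta,
                                              rois$background, "CTA"))
  expect_equal(thr$aorta_value, 300)
  expect_equal(thr$background_value, 60)
  expect_equal(thr$LT, 140)
  expect_equal(thr$UT, 300)
  # doubling every intensity doubles all four quantities
  vol2 <- image_volume(2 * ph$volume$values, ph$volume$spacing, ph$volume$origin)
  thr2 <- suppressWarnings(estimate_thresholds(vol2, rois$aorta,
                                               rois$background, "CTA"))
  expect_equal(thr2$aorta_value, 2 * thr$aorta_value)
  expect_equal(thr2$background_value, 2 * thr$background_value)
  expect_equal(thr2$LT, 2 * thr$LT)
  expect_equal(thr2$UT, 2 * thr$UT)
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back$LT, thr$LT)
  expect_equal(back$UT, thr$UT)
  expect_equal(back$modality, "CTA")
  unlink(path)
})

test_that("threshold_set enforces its ordering invariants", {
  expect_error(threshold_set(300, 60, "CTA", UT = 250), "upper threshold")
  ts <- threshold_set(300, 60, "MRA", UT = 999)  # UT ignored for MRA
  expect_true(is.na(ts$UT))
})
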