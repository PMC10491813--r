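test_that("four equal, disjoint ROIs are placed in the water ring", {
  v <- quick_scan(small_stent(), fast_kernel(0.5, 0))
  rois <- place_background_rois(v)
  expect_equal(nrow(rois$centers), 4L)
  expect_equal(rois$radius, sqrt(100 / pi), tolerance = 1e-12)
  # pairwise disjoint
  d <- as.matrix(dist(rois$centers))
  expect_true(all(d[upper.tri(d)] > 2 * rois$radius))
  # every ROI clears the stent by the requested 5 mm
  ctr <- rois$stent_center
  gap <- sqrt(rowSums(sweep(rois$centers, 2, ctr)^2)) - rois$radius -
    rois$stent_outer_radius
  expect_equal(gap, rep(5, 4), tolerance = 1e-9)
  # voxel-counted area within one pixel of 100 mm^2
  cvr <- coefficient_of_variation(v, rois)
  expect_length(cvr$per_roi_mean, 4L)
})

test_that("too little water around the stent raises a margin error", {
  v <- quick_scan(small_stent(8.0, 15.0), fast_kernel(0.5, 0),
                  half_width = 16)
  expect_error(place_background_rois(v), "water region too small")
})

test_that("noise-free constant region has sigma_bar 0 and CV 0", {
  v <- water_volume(5, dims = c(120, 120, 5), spacing = c(0.4, 0.4, 1))
  v$provenance$stent_outer_radius <- 2
  v$axis_hint <- list(point = c(24, 24, 0), direction = c(0, 0, 1))
  cvr <- coefficient_of_variation(v)
  expect_equal(cvr$sigma_bar, 0)
  expect_equal(cvr$cv, 0)
})

test_that("CV is scale-invariant and flips sign with the mean", {
  set.seed(5)
  vox <- array(rnorm(120 * 120 * 3, mean = -4, sd = 15), c(120, 120, 3))
  mk <- function(a) {
    vv <- ct_volume(a, c(0.4, 0.4, 1))
    vv$provenance$stent_outer_radius <- 2
    vv$axis_hint <- list(point = c(24, 24, 0), direction = c(0, 0, 1))
    vv
  }
  cv1 <- coefficient_of_variation(mk(vox))
  cv2 <- coefficient_of_variation(mk(3 * vox))
  cv3 <- coefficient_of_variation(mk(-vox))
  expect_equal(cv2$cv, cv1$cv, tolerance = 1e-12)
  expect_equal(cv3$cv, -cv1$cv, tolerance = 1e-12)
  # water below 0 HU: CV negative with |cv| ~ sd/|mean|
  expect_lt(cv1$cv, 0)
  expect_equal(cv1$cv_abs, 15 / 4, tolerance = 0.25)
})

test_that("sigma_bar recovers the injected noise SD", {
  sb <- vapply(1:3, function(s) {
    v <- quick_scan(small_stent(), fast_kernel(0.5, noise_sd = 15), seed = s)
    coefficient_of_variation(v)$sigma_bar
  }, 0)
  expect_equal(mean(sb), 15, tolerance = 0.1)
})

test_that("lower noise gives strictly smaller |CV| at fixed mean", {
  # fix the water mean away from 0 HU so CV has a stable denominator
  cvs <- vapply(c(5, 15, 30), function(nsd) {
    v <- quick_scan(small_stent(), fast_kernel(0.5, noise_sd = nsd), seed = 2,
                    geom = phantom_geometry(water_hu = -4))
    coefficient_of_variation(v)$cv_abs
  }, 0)
  expect_true(all(diff(cvs) > 0))
})
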