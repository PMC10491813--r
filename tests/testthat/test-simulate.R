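test_that("material map contains only the declared material values", {
  spec <- small_stent(strut_hu = 1200)
  geom <- phantom_geometry(lumen_hu = 300)
  map <- build_material_map(spec, geom, supersample = 2)
  mats <- sort(unique(as.vector(map$voxels)))
  expect_true(all(mats %in% c(geom$water_hu, geom$lumen_hu,
                              geom$tube_wall_hu, 1200)))
  expect_true(1200 %in% mats)  # shell voxels present
  # voxels strictly inside the lumen (on the axis) equal lumen_hu
  d <- dim(map$voxels)
  mid <- round(d[3] / 2)
  expect_equal(map$voxels[round(d[1] / 2), round(d[2] / 2), mid], 300)
  expect_false(is.null(map$axis_hint))
})

test_that("stent that does not fit the grid raises a margin error", {
  expect_error(build_material_map(small_stent(3.0), half_width = 11),
               "margin")
  expect_error(build_material_map(small_stent(3.0, length = 30),
                                  z_extent = 40), "margin")
})

test_that("blurred noise-free volumes stay in the convex hull of materials", {
  spec <- small_stent()
  geom <- phantom_geometry()
  v <- quick_scan(spec, fast_kernel(0.5, noise_sd = 0), geom = geom)
  expect_gte(min(v$voxels), geom$water_hu - 1e-6)
  expect_lte(max(v$voxels), spec$strut_hu + 1e-6)
})

test_that("simulation is deterministic and seed-sensitive", {
  k <- fast_kernel(0.5, noise_sd = 20)
  v1 <- quick_scan(kernel = k, seed = 11)
  v2 <- quick_scan(kernel = k, seed = 11)
  v3 <- quick_scan(kernel = k, seed = 12)
  expect_identical(v1$voxels, v2$voxels)
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("simulate_scan equals build_material_map + apply_kernel", {
  spec <- small_stent(); geom <- phantom_geometry()
  k <- fast_kernel(0.5, noise_sd = 15)
  map <- build_material_map(spec, geom, supersample = 2,
                            base_spacing = c(0.4, 0.4, 0.4))
  v1 <- apply_kernel(map, k, seed = 7)
  v2 <- quick_scan(spec, k, seed = 7)
  expect_equal(dim(v1$voxels), dim(v2$voxels))
  expect_equal(v1$voxels, v2$voxels, tolerance = 1e-10)
  expect_equal(v1$axis_hint, v2$axis_hint)
})

test_that("blur narrower than the grid step is rejected", {
  map <- build_material_map(small_stent(), supersample = 2)
  expect_error(apply_kernel(map, fast_kernel(0.05)), "unresolvable")
})

test_that("uniform regions pass through blur and downsampling unchanged", {
  v <- ct_volume(array(250, c(32, 32, 16)), c(0.2, 0.2, 0.2))
  out <- apply_kernel(v, fast_kernel(0.5, noise_sd = 0))
  expect_equal(as.vector(out$voxels), rep(250, length(out$voxels)),
               tolerance = 1e-12)
})

test_that("background noise SD matches the kernel noise_sd", {
  v <- quick_scan(kernel = fast_kernel(0.5, noise_sd = 20), seed = 3)
  corner <- v$voxels[1:25, 1:25, ]          # pure water region
  expect_gt(length(corner), 1e4)
  expect_equal(sd(corner), 20, tolerance = 0.05)
})

test_that("stent axial extent matches the nominal length", {
  spec <- small_stent(3.0, length = 24.0)
  v <- quick_scan(spec, fast_kernel(0.4, noise_sd = 0))
  an <- analyze_stent(v)
  # detected extent was trimmed one slice thickness at each end
  detected <- diff(an$stent_extent) + 2 * v$provenance$slice_thickness
  expect_lt(abs(detected - 24.0), v$provenance$slice_thickness + 1e-9)
})

test_that("sharper kernels give strictly steeper edges", {
  spec <- small_stent()
  e <- vapply(c(0.7, 0.5, 0.35), function(sg)
    analyze_stent(quick_scan(spec, fast_kernel(sg, 0),
                             supersample = 4))$metrics$ers_mean, 0)
  expect_true(all(diff(e) > 0))
})
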