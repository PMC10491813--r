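test_that("profile stack arithmetic follows the section geometry", {
  # 24 mm stent sampled every 0.3 mm -> 80 rows
  pos <- seq(-5, 5, by = 0.1)
  rows <- (1:100 - 0.5) * 0.3
  sec <- structure(list(pixels = matrix(rep(sin(pos), each = 100), 100),
                        row_positions = rows, col_positions = pos,
                        row_spacing = 0.3, col_spacing = 0.1,
                        provenance = list()),
                   class = "section_image")
  st <- profile_stack(sec, c(0, 24))
  expect_equal(st$n_rows, 80L)
  # uniform section: every profile identical, stack means = 2-D row means
  expect_true(all(apply(st$profiles, 2, function(x) all(x == x[1]))))
  expect_equal(mean_profile(st)$hu, sin(pos))
  expect_error(profile_stack(sec, c(5, 5)), "empty")
  expect_error(profile_stack(sec, c(40, 50)), "no section rows")
})

test_that("mean_profile averages rows and obeys the noise law", {
  pos <- seq(-2, 2, by = 0.1)
  one <- matrix(cos(pos), 1)
  st1 <- structure(list(profiles = one, positions = pos, n_rows = 1L),
                   class = "profile_stack")
  expect_equal(mean_profile(st1)$hu, cos(pos))
  st2 <- structure(list(profiles = rbind(cos(pos), -cos(pos)), positions = pos,
                        n_rows = 2L), class = "profile_stack")
  expect_equal(mean_profile(st2)$hu, rep(0, length(pos)))
  # SD of the mean of 80 noisy rows ~ sd/sqrt(80)
  set.seed(99)
  sds <- replicate(200, {
    m <- matrix(rnorm(80 * 50, sd = 26), 80)
    st <- structure(list(profiles = m, positions = 1:50, n_rows = 80L),
                    class = "profile_stack")
    sd(mean_profile(st)$hu)
  })
  expect_equal(mean(sds), 26 / sqrt(80), tolerance = 0.15)
})

test_that("locate_features finds peaks, lumen minimum and baseline", {
  x <- seq(-10, 10, by = 0.02)
  y <- 50 + 600 * (dnorm(x, -3, 0.5) + dnorm(x, 3, 0.5)) / dnorm(0, 0, 0.5)
  pr <- structure(list(positions = x, hu = y), class = "mean_profile")
  f <- locate_features(pr)
  expect_equal(f$left_peak_pos, -3, tolerance = 1e-6)
  expect_equal(f$right_peak_pos, 3, tolerance = 1e-6)
  expect_equal(f$lumen_min_pos, 0, tolerance = 1e-6)
  expect_equal(f$baseline_hu, 50, tolerance = 0.01)
  expect_lt(f$lumen_min_hu, f$left_peak_hu)
  flat <- structure(list(positions = x, hu = rep(7, length(x))),
                    class = "mean_profile")
  expect_error(locate_features(flat), "no stent signature")
})

test_that("edge metrics are exact on a linear ramp", {
  pr <- ramp_profile(slope = 1000, A = 800)
  f <- plateau_features(pr)
  m <- edge_rise_metrics(pr, f)
  expect_equal(m$ers_left, 1000, tolerance = 1e-9)
  expect_equal(m$ers_right, 1000, tolerance = 1e-9)
  expect_equal(m$erd_left, 0.8 * 800 / 1000, tolerance = 1e-9)
  expect_equal(m$ers_mean, (m$ers_left + m$ers_right) / 2)
})

test_that("a Gaussian-blurred step edge has ERD = 2.5631 sigma", {
  for (sg in c(0.3, 0.6)) {
    pr <- erf_bump_profile(sg)
    m <- edge_rise_metrics(pr, plateau_features(pr))
    expect_equal(m$erd_left, 2 * qnorm(0.9) * sg, tolerance = 0.005)
    expect_equal(m$erd_right, m$erd_left, tolerance = 1e-6)
  }
})

test_that("mirror-symmetric profiles give equal left and right ERS", {
  v <- quick_scan(small_stent(), fast_kernel(0.5, 0), supersample = 4)
  m <- analyze_stent(v)$metrics
  expect_equal(m$ers_left, m$ers_right, tolerance = 0.02)
  expect_equal(m$ers_mean, (m$ers_left + m$ers_right) / 2)
})

test_that("ers_mean is invariant under transverse coordinate reversal", {
  v <- quick_scan(small_stent(), fast_kernel(0.5, 0), supersample = 4)
  an <- analyze_stent(v)
  pr <- an$profile
  rev_pr <- structure(list(positions = rev(-pr$positions), hu = rev(pr$hu),
                           n_rows_averaged = pr$n_rows_averaged),
                      class = "mean_profile")
  m1 <- edge_rise_metrics(pr, locate_features(pr))
  m2 <- edge_rise_metrics(rev_pr, locate_features(rev_pr))
  expect_equal(m2$ers_mean, m1$ers_mean, tolerance = 1e-10)
  expect_equal(m2$ers_left, m1$ers_right, tolerance = 1e-10)
})

test_that("edge unresolved and missing-signature errors are stage-labeled", {
  v <- water_volume(0, dims = c(40, 40, 40), spacing = c(0.5, 0.5, 0.5))
  expect_error(analyze_stent(v, axis = list(point = c(10, 10, 0),
                                            direction = c(0, 0, 1))),
               "no stent signature")
  expect_error(analyze_stent(v), "\\[detect_axis\\]")
})

test_that("blur monotonicity: ERD rises and ERS falls with psf_sigma", {
  spec <- stent_spec("cov8", 8.0, 15.0, covered = TRUE)
  sigmas <- c(0.3, 0.5, 0.75, 1.0)
  res <- vapply(sigmas, function(sg) {
    k <- kernel_model("k", sg, 0, 0.4, 0.4, 0.3)
    m <- analyze_stent(simulate_scan(spec, kernel = k, seed = 1,
                                     supersample = 2, noise = FALSE))$metrics
    c((m$erd_left + m$erd_right) / 2, m$ers_mean)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
})
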