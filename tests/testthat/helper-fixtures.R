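# shared fixtures: small stents, fast kernels, analytic profiles

small_stent <- function(diameter = 3.0, length = 15.0, ...)
  stent_spec("test_stent", diameter, length, ...)

fast_kernel <- function(sigma = 0.5, noise_sd = 0, pixel = 0.4)
  kernel_model(sprintf("test-s%.2f", sigma), sigma, noise_sd, pixel,
               slice_thickness = 0.4, increment = 0.3)

# simulate a small scan quickly (supersample 2 keeps tests snappy)
quick_scan <- function(spec = small_stent(), kernel = fast_kernel(),
                       seed = 1, noise = TRUE, supersample = 2,
                       geom = phantom_geometry(), ...)
  simulate_scan(spec, geom, kernel, seed = seed,
                supersample = supersample, noise = noise, ...)

# symmetric double-erf "stent-like" bump: baseline -> plateau of height A,
# edges at +/- half_width blurred with sigma; features must be supplied by
# hand because the top is flat
erf_bump_profile <- function(sigma, A = 800, half_width = 10, dx = 0.01,
                             span = 15) {
  x <- seq(-span, span, by = dx)
  hu <- A * (pnorm((x + half_width) / sigma) - pnorm((x - half_width) / sigma))
  structure(list(positions = x, hu = hu, n_rows_averaged = 1L),
            class = "mean_profile")
}

plateau_features <- function(profile, at = 0.5) {
  # peaks placed mid-plateau on each side of the center
  n <- length(profile$positions)
  list(left_peak_pos = -abs(at), right_peak_pos = abs(at),
       left_peak_hu = max(profile$hu), right_peak_hu = max(profile$hu),
       lumen_min_pos = 0, lumen_min_hu = max(profile$hu),
       baseline_hu = 0)
}

# trapezoid: linear ramps of given slope up to height A, flat top wide
# enough that the mid-plateau feature points sit on the plateau
ramp_profile <- function(slope = 1000, A = 800, dx = 0.005) {
  edge_at <- A / slope + 1.5
  span <- edge_at + 2
  x <- seq(-span, span, by = dx)
  up <- (x + edge_at) * slope
  down <- (edge_at - x) * slope
  hu <- pmin(pmax(pmin(up, down), 0), A)
  structure(list(positions = x, hu = hu, n_rows_averaged = 1L),
            class = "mean_profile")
}

# uniform-water volume with optional constant HU
water_volume <- function(hu = 0, dims = c(40, 40, 10), spacing = c(1, 1, 1))
  ct_volume(array(hu, dims), spacing)

# null-model ratings (all reconstructions equal quality)
null_reader_model <- function(n_readers = 5, n_stents = 12, k = 4)
  reader_model(n_readers = n_readers, n_stents = n_stents,
               latent_quality = stats::setNames(rep(3, k), paste0("K", 1:k)),
               criteria = "overall_quality")
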