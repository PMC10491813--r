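#' Build the high-resolution material map of a stented tube phantom
#'
#' Lays out, on a supersampled grid, the noise-free HU map of a
#' contrast-filled silicone tube holding a stent, surrounded by water.  The
#' stent is a thin cylindrical shell at the lumen wall: evenly spaced strut
#' rings for bare stents (axial pitch `ring_pitch`), a continuous membrane
#' for covered stents.  The stent axis runs along z through the transverse
#' grid center and is recorded in `axis_hint`.
#'
#' @param spec a [stent_spec].
#' @param geom a [phantom_geometry]; its margins set the default grid size.
#' @param supersample integer >= 1; the grid step is
#'   `base_spacing / supersample`.
#' @param base_spacing target reconstruction spacing `(dx, dy, dz)` in mm
#'   that the supersampling is relative to.
#' @param half_width optional transverse half-width of the grid, mm.  Must
#'   leave at least 10 mm of water beyond the tube outer wall.
#' @param z_extent optional axial grid extent, mm (>= stent length plus
#'   10 mm margin at both ends).
#' @return A [ct_volume] material map containing only the declared material
#'   HU values, with `axis_hint` set and materials recorded in provenance.
#' @export
build_material_map <- function(spec, geom = phantom_geometry(),
                               supersample = 4,
                               base_spacing = c(0.4, 0.4, 0.4),
                               half_width = NULL, z_extent = NULL) {
  stopifnot(inherits(spec, "stent_spec"), inherits(geom, "phantom_geometry"))
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("`supersample` must be >= 1")
  g <- phantom_grid(spec, geom, supersample, base_spacing, half_width, z_extent)
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  vox <- array(0, dim = c(nx, ny, nz))
  tmpl <- plane_templates(spec, geom, g)
  strut_z <- strut_z_mask(spec, g)
  for (k in seq_len(nz)) {
    vox[, , k] <- if (strut_z[k]) tmpl$strut else tmpl$tube
  }
  ct_volume(vox, spacing = g$spacing,
            axis_hint = list(point = c(g$half_width, g$half_width, 0),
                             direction = c(0, 0, 1)),
            provenance = list(
              source = "build_material_map",
              materials = g$materials,
              stent_z = g$stent_z,
              stent_outer_radius = spec$diameter / 2 +
                geom$tube_wall_thickness,
              supersample = supersample))
}

# resolve grid axes, spacing and material HU roster; errors if the stent
# does not fit with the mandatory 10 mm water margin
phantom_grid <- function(spec, geom, supersample, base_spacing,
                         half_width = NULL, z_extent = NULL) {
  sp <- base_spacing / supersample
  r_wall_out <- spec$diameter / 2 + geom$tube_wall_thickness
  min_hw <- r_wall_out + 10
  if (is.null(half_width))
    half_width <- r_wall_out + geom$transverse_margin
  if (half_width < min_hw)
    stop(sprintf(paste0("grid half-width %.1f mm leaves less than the required",
                        " 10 mm water margin around the %.1f mm tube",
                        " (need >= %.1f mm)"),
                 half_width, 2 * r_wall_out, min_hw))
  min_zext <- spec$length + 20
  if (is.null(z_extent))
    z_extent <- spec$length + 2 * geom$axial_margin
  if (z_extent < min_zext)
    stop(sprintf(paste0("axial extent %.1f mm leaves less than the required",
                        " 10 mm water margin beyond the %.1f mm stent ends",
                        " (need >= %.1f mm)"),
                 z_extent, spec$length, min_zext))
  nx <- ceiling(2 * half_width / sp[1])
  ny <- ceiling(2 * half_width / sp[2])
  nz <- ceiling(z_extent / sp[3])
  z0 <- (nz * sp[3] - spec$length) / 2
  materials <- c(water = geom$water_hu, lumen = geom$lumen_hu,
                 tube_wall = geom$tube_wall_hu, strut = spec$strut_hu)
  if (spec$covered) materials <- c(materials, cover = spec$cover_hu)
  list(x = (seq_len(nx) - 0.5) * sp[1], y = (seq_len(ny) - 0.5) * sp[2],
       z = (seq_len(nz) - 0.5) * sp[3], spacing = sp,
       half_width = half_width, stent_z = c(z0, z0 + spec$length),
       materials = materials)
}

# two transverse material templates: the plain tube plane and the plane
# through a strut ring (or the covered membrane)
plane_templates <- function(spec, geom, g) {
  r <- sqrt(outer((g$x - g$half_width)^2, (g$y - g$half_width)^2, "+"))
  r_lumen <- spec$diameter / 2
  r_wall_out <- r_lumen + geom$tube_wall_thickness
  r_shell_in <- r_lumen - spec$strut_thickness
  tube <- matrix(geom$water_hu, nrow(r), ncol(r))
  tube[r <= r_wall_out] <- geom$tube_wall_hu
  tube[r <= r_lumen] <- geom$lumen_hu
  strut <- tube
  shell_hu <- if (spec$covered) spec$cover_hu else spec$strut_hu
  strut[r <= r_lumen & r > r_shell_in] <- shell_hu
  list(tube = tube, strut = strut)
}

# logical mask over fine z samples: does a strut (or the cover) occupy z?
strut_z_mask <- function(spec, g) {
  z <- g$z; z0 <- g$stent_z[1]; z1 <- g$stent_z[2]
  inside <- z >= z0 & z <= z1
  if (spec$covered) return(inside)
  s <- spec$strut_thickness
  # rings centered within the stent span: leftover pitch is split evenly
  # between the two ends so the strut envelope is symmetric
  n_rings <- floor((z1 - z0 - s) / spec$ring_pitch) + 1
  slack <- (z1 - z0) - ((n_rings - 1) * spec$ring_pitch + s)
  centers <- z0 + s / 2 + slack / 2 + (seq_len(n_rings) - 1) * spec$ring_pitch
  on_ring <- rep(FALSE, length(z))
  zi <- z[inside]
  # distance to nearest ring center
  dist <- vapply(zi, function(zz) min(abs(zz - centers)), 0)
  on_ring[inside] <- dist <= s / 2
  on_ring
}

# one-dimensional blur-and-downsample operator: rows are output samples
# (box of width `width` centered every `step`), columns fine-grid samples.
# Gaussian tails and boxes truncated at the grid are renormalized.
resample_operator <- function(fine_coords, sigma, step, width = step,
                              extent = max(fine_coords) + diff(fine_coords[1:2]) / 2) {
  h <- fine_coords[2] - fine_coords[1]
  if (sigma < h)
    stop(sprintf("psf_sigma %.4g mm is below the supersampled grid step %.4g mm (blur unresolvable)",
                 sigma, h))
  n_out <- floor(extent / step + 1e-9)
  # center the output grid on the field of view so that objects on the
  # grid center stay on a pixel center after downsampling
  offset <- (extent - n_out * step) / 2
  centers <- offset + (seq_len(n_out) - 0.5) * step
  # box weights: overlap of each fine cell with the output box
  lo <- pmax(centers - width / 2, 0)
  hi <- pmin(centers + width / 2, extent)
  cell_lo <- fine_coords - h / 2
  cell_hi <- fine_coords + h / 2
  box <- matrix(0, n_out, length(fine_coords))
  for (i in seq_len(n_out)) {
    ov <- pmin(cell_hi, hi[i]) - pmax(cell_lo, lo[i])
    ov[ov < 0] <- 0
    box[i, ] <- ov
  }
  box <- box / rowSums(box)
  # Gaussian convolution matrix on the fine grid, truncation-renormalized
  gk <- stats::dnorm(outer(fine_coords, fine_coords, "-") / sigma)
  gk <- gk / rowSums(gk)
  w <- box %*% gk
  list(w = w, centers = centers, step = step, offset = offset)
}

# contract a 3-D array with per-dimension operators (any may be NULL)
contract3 <- function(a, wx = NULL, wy = NULL, wz = NULL) {
  d <- dim(a)
  if (!is.null(wx)) {
    a <- wx %*% matrix(a, d[1], d[2] * d[3])
    d[1] <- nrow(wx); dim(a) <- d
  }
  if (!is.null(wy)) {
    a <- aperm(a, c(2, 1, 3))
    a <- wy %*% matrix(a, d[2], d[1] * d[3])
    d[2] <- nrow(wy); dim(a) <- c(d[2], d[1], d[3])
    a <- aperm(a, c(2, 1, 3))
  }
  if (!is.null(wz)) {
    a <- matrix(a, d[1] * d[2], d[3]) %*% t(wz)
    d[3] <- nrow(wz); dim(a) <- d
  }
  a
}

#' Emulate a reconstruction kernel on a material map
#'
#' Applies the kernel's isotropic Gaussian blur to a supersampled material
#' map, box-averages down to the reconstruction grid
#' (`pixel_size` in-plane; slices of `slice_thickness` sampled every
#' `increment`), and finally adds zero-mean white Gaussian noise of SD
#' `noise_sd` using `seed`.  Blur and downsampling are applied as one
#' separable linear operator per dimension, so the noise-free result is in
#' the convex hull of the map's material values.
#'
#' @param map a supersampled material map from [build_material_map()].
#' @param kernel a [kernel_model].
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_sd = 0`).
#' @return A [ct_volume] on the reconstruction grid; provenance records the
#'   kernel name and seed.
#' @export
apply_kernel <- function(map, kernel, seed = 1L) {
  stopifnot(inherits(map, "ct_volume"), inherits(kernel, "kernel_model"))
  d <- dim(map$voxels); sp <- map$spacing
  ox <- resample_operator((seq_len(d[1]) - 0.5) * sp[1], kernel$psf_sigma,
                          step = kernel$pixel_size, extent = d[1] * sp[1])
  oy <- resample_operator((seq_len(d[2]) - 0.5) * sp[2], kernel$psf_sigma,
                          step = kernel$pixel_size, extent = d[2] * sp[2])
  oz <- resample_operator((seq_len(d[3]) - 0.5) * sp[3], kernel$psf_sigma,
                          step = kernel$increment,
                          width = kernel$slice_thickness,
                          extent = d[3] * sp[3])
  out <- contract3(map$voxels, ox$w, oy$w, oz$w)
  finalize_scan(out, map, kernel, seed,
                offsets = c(ox$offset, oy$offset, oz$offset))
}

# shared tail of apply_kernel / simulate_scan: noise + metadata; `offsets`
# translate the world origin to the centered output grid
finalize_scan <- function(out, map, kernel, seed, offsets = c(0, 0, 0)) {
  if (kernel$noise_sd > 0) {
    out <- out + with_preserved_rng(seed, {
      stats::rnorm(length(out), sd = kernel$noise_sd)
    })
  }
  prov <- map$provenance
  prov$source <- "simulated_scan"
  prov$kernel <- kernel$name
  prov$psf_sigma <- kernel$psf_sigma
  prov$noise_sd <- kernel$noise_sd
  prov$slice_thickness <- kernel$slice_thickness
  prov$seed <- seed
  if (!is.null(prov$stent_z)) prov$stent_z <- prov$stent_z - offsets[3]
  axis <- map$axis_hint
  if (!is.null(axis)) axis$point <- axis$point - offsets
  ct_volume(out, spacing = c(kernel$pixel_size, kernel$pixel_size,
                             kernel$increment),
            axis_hint = axis, provenance = prov)
}

# evaluate expr with a local RNG state, restoring the caller's state
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a reconstructed CT scan of a stented phantom
#'
#' Composes [build_material_map()] and [apply_kernel()], but streams the
#' computation through the axial structure of the phantom (only two distinct
#' transverse material planes exist) so full stent rosters simulate in
#' seconds without materializing the supersampled grid.
#'
#' @inheritParams build_material_map
#' @inheritParams apply_kernel
#' @param noise set `FALSE` to skip the noise draw regardless of the
#'   kernel's `noise_sd` (noise-free runs of the quantitative pipeline).
#' @return A [ct_volume] on the kernel's reconstruction grid with
#'   `axis_hint` preserved.
#' @export
simulate_scan <- function(spec, geom = phantom_geometry(), kernel, seed = 1L,
                          supersample = 4, half_width = NULL, z_extent = NULL,
                          noise = TRUE) {
  stopifnot(inherits(spec, "stent_spec"), inherits(geom, "phantom_geometry"),
            inherits(kernel, "kernel_model"))
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("`supersample` must be >= 1")
  base <- c(kernel$pixel_size, kernel$pixel_size, kernel$slice_thickness)
  g <- phantom_grid(spec, geom, supersample, base, half_width, z_extent)
  ox <- resample_operator(g$x, kernel$psf_sigma, step = kernel$pixel_size,
                          extent = length(g$x) * g$spacing[1])
  oy <- resample_operator(g$y, kernel$psf_sigma, step = kernel$pixel_size,
                          extent = length(g$y) * g$spacing[2])
  oz <- resample_operator(g$z, kernel$psf_sigma, step = kernel$increment,
                          width = kernel$slice_thickness,
                          extent = length(g$z) * g$spacing[3])
  tmpl <- plane_templates(spec, geom, g)
  strut_z <- strut_z_mask(spec, g)
  # transverse blur+downsample once per distinct plane
  ds_tube <- ox$w %*% tmpl$tube %*% t(oy$w)
  ds_strut <- ox$w %*% tmpl$strut %*% t(oy$w)
  nxo <- nrow(ds_tube); nyo <- ncol(ds_tube); nzf <- length(g$z)
  stack <- matrix(0, nxo * nyo, nzf)
  vt <- as.vector(ds_tube); vs <- as.vector(ds_strut)
  for (k in seq_len(nzf)) stack[, k] <- if (strut_z[k]) vs else vt
  out <- stack %*% t(oz$w)
  dim(out) <- c(nxo, nyo, length(oz$centers))
  fake_map <- list(provenance = list(
    materials = g$materials, stent_z = g$stent_z,
    stent_outer_radius = spec$diameter / 2 + geom$tube_wall_thickness,
    supersample = supersample, stent_id = spec$stent_id,
    diameter = spec$diameter),
    axis_hint = list(point = c(g$half_width, g$half_width, 0),
                     direction = c(0, 0, 1)))
  k2 <- kernel
  if (!noise) k2$noise_sd <- 0
  finalize_scan(out, fake_map, k2, seed,
                offsets = c(ox$offset, oy$offset, oz$offset))
}
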