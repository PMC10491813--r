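#' Stent specification
#'
#' Describes one physical stent as modeled by the simulator: a thin
#' high-attenuation cylindrical shell (evenly spaced strut rings for bare
#' stents, a continuous membrane for covered stents) sitting at the lumen
#' wall of a contrast-filled tube.
#'
#' @param stent_id character label.
#' @param diameter outer lumen diameter of the tube segment, mm.
#' @param length stent length along the axis, mm.
#' @param strut_thickness radial (and axial, for rings) strut size, mm.
#'   Defaults to 0.3 mm, a deliberately coarse desk-scale strut that keeps
#'   the two-peak transverse profile resolvable on sub-mm grids.
#' @param covered logical; covered stents are modeled as a continuous shell.
#' @param strut_hu attenuation of the strut material, HU; must exceed the
#'   300 HU lumen contrast so the transverse profile has two maxima.  The
#'   3000 HU default reflects solid metal at 120 kVp; much lower values let
#'   the strut signal sink below the blurred contrast dome of small stents
#'   under soft kernels, which is not how metallic struts image.
#' @param cover_hu attenuation of the cover membrane, HU (used only when
#'   `covered = TRUE`; defaults to `strut_hu`).
#' @param ring_pitch center-to-center axial spacing of strut rings, mm;
#'   default `2 * strut_thickness`.
#'
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(stent_id, diameter, length, strut_thickness = 0.3,
                       covered = FALSE, strut_hu = 3000,
                       cover_hu = strut_hu, ring_pitch = 2 * strut_thickness) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L,
            is.numeric(length), base::length(length) == 1L)
  if (length <= 0) stop("`length` must be positive")
  if (strut_thickness <= 0) stop("`strut_thickness` must be positive")
  if (strut_hu <= 300)
    stop("`strut_hu` must exceed the 300 HU lumen contrast")
  if (ring_pitch < strut_thickness)
    stop("`ring_pitch` must be at least `strut_thickness`")
  if (strut_thickness >= diameter / 2)
    stop("`strut_thickness` must be smaller than the lumen radius")
  structure(
    list(stent_id = as.character(stent_id), diameter = diameter,
         length = length, strut_thickness = strut_thickness,
         covered = isTRUE(covered), strut_hu = strut_hu, cover_hu = cover_hu,
         ring_pitch = ring_pitch),
    class = "stent_spec")
}

#' @export
print.stent_spec <- function(x, ...) {
  cat(sprintf("<stent_spec> %s: %.1f x %.1f mm, %s, struts %.2f mm @ %.0f HU\n",
              x$stent_id, x$diameter, x$length,
              if (x$covered) "covered" else "bare", x$strut_thickness,
              x$strut_hu))
  invisible(x)
}

#' Phantom geometry and material attenuations
#'
#' Materials of the water-filled phantom holding the stented tube.  Only the
#' simulated sub-volume around the stent is gridded, so the outer PMMA shell
#' never enters the picture; its attenuation is kept for completeness.
#'
#' @param phantom_length,phantom_width outer phantom size, cm (bookkeeping).
#' @param water_hu background water attenuation, HU (near 0).  Defaults to
#'   -4 HU: tap water typically reads a few HU below zero at 120 kVp, and a
#'   mean slightly below zero is what makes water-background CV readings
#'   negative and finite; at exactly 0 HU the CV denominator is pure noise.
#' @param lumen_hu contrast-filled lumen attenuation, HU (300 HU emulates
#'   iodinated contrast diluted for 120 kVp).
#' @param tube_wall_hu silicone tube wall attenuation, HU.
#' @param tube_wall_thickness silicone wall thickness, mm.
#' @param shell_material_hu PMMA shell attenuation, HU.
#' @param transverse_margin water margin beyond the tube outer wall, mm.
#'   Must be at least 10 mm; the 17 mm default also leaves room for the
#'   four 100 mm2 background ROIs of the homogeneity analysis.
#' @param axial_margin water margin beyond each stent end, mm (>= 10).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(phantom_length = 36.0, phantom_width = 24.5,
                             water_hu = -4, lumen_hu = 300, tube_wall_hu = 100,
                             tube_wall_thickness = 1.0,
                             shell_material_hu = 120,
                             transverse_margin = 17, axial_margin = 10) {
  if (transverse_margin < 10 || axial_margin < 10)
    stop("water margins must be at least 10 mm on every side of the stent")
  if (tube_wall_thickness < 0) stop("`tube_wall_thickness` must be >= 0")
  structure(
    list(phantom_length = phantom_length, phantom_width = phantom_width,
         water_hu = water_hu, lumen_hu = lumen_hu, tube_wall_hu = tube_wall_hu,
         tube_wall_thickness = tube_wall_thickness,
         shell_material_hu = shell_material_hu,
         transverse_margin = transverse_margin, axial_margin = axial_margin),
    class = "phantom_geometry")
}

#' Reconstruction kernel emulation model
#'
#' A named reconstruction is emulated by an isotropic Gaussian point-spread
#' blur (`psf_sigma`), the reconstruction grid (`pixel_size` in-plane,
#' `slice_thickness` box-averaged along the axis, sampled every
#' `increment`), and additive white noise (`noise_sd`).
#'
#' @param name kernel label, e.g. `"PCD-Bv56"`.
#' @param psf_sigma Gaussian blur width, mm (> 0); smaller = sharper.
#' @param noise_sd additive HU noise SD on the reconstructed grid.
#' @param pixel_size in-plane pixel size, mm.
#' @param slice_thickness reconstructed slice thickness, mm.
#' @param increment slice sampling increment, mm (defaults to
#'   `slice_thickness`).
#' @return An object of class `kernel_model`.
#' @export
kernel_model <- function(name, psf_sigma, noise_sd, pixel_size,
                         slice_thickness, increment = slice_thickness) {
  if (psf_sigma <= 0) stop("`psf_sigma` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (pixel_size <= 0 || slice_thickness <= 0 || increment <= 0)
    stop("grid spacings must be positive")
  structure(
    list(name = as.character(name), psf_sigma = psf_sigma, noise_sd = noise_sd,
         pixel_size = pixel_size, slice_thickness = slice_thickness,
         increment = increment),
    class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("<kernel_model> %s: sigma %.2f mm, noise %.0f HU, grid %.2f/%.2f/%.2f mm\n",
              x$name, x$psf_sigma, x$noise_sd, x$pixel_size, x$slice_thickness,
              x$increment))
  invisible(x)
}

#' Default kernel calibration
#'
#' Four emulated reconstructions: the photon-counting vascular kernel family
#' Bv40/Bv48/Bv56 (0.4 mm pixels, 0.4 mm slices at 0.3 mm increment) and the
#' energy-integrating reference Bv40 (0.6 mm pixels, 0.5 mm slices).  Blur
#' widths decrease and noise increases with kernel strength, encoding the
#' sharpness/noise trade-off of real vascular kernels.  These are stand-in
#' calibrations chosen to reproduce the qualitative orderings of kernel
#' comparisons, not measurements of any scanner: the blur widths correspond
#' to 10-90 percent edge rises of roughly 0.7-1.6 mm, the regime in which a
#' 3 mm stent still shows the two-peak profile the analysis requires (wider
#' blurs merge its struts with the contrast dome into a single maximum).
#'
#' @return Named list of [kernel_model] objects in increasing sharpness
#'   order: `EID-Bv40`, `PCD-Bv40`, `PCD-Bv48`, `PCD-Bv56`.
#' @export
default_kernels <- function() {
  ks <- list(
    kernel_model("EID-Bv40", psf_sigma = 0.70, noise_sd = 14,
                 pixel_size = 0.6, slice_thickness = 0.5, increment = 0.5),
    kernel_model("PCD-Bv40", psf_sigma = 0.65, noise_sd = 12,
                 pixel_size = 0.4, slice_thickness = 0.4, increment = 0.3),
    kernel_model("PCD-Bv48", psf_sigma = 0.48, noise_sd = 18,
                 pixel_size = 0.4, slice_thickness = 0.4, increment = 0.3),
    kernel_model("PCD-Bv56", psf_sigma = 0.30, noise_sd = 26,
                 pixel_size = 0.4, slice_thickness = 0.4, increment = 0.3))
  names(ks) <- vapply(ks, `[[`, "", "name")
  validate_kernel_family(ks)
  ks
}

# within the PCD family, sharper name must mean smaller sigma, larger noise
validate_kernel_family <- function(kernels) {
  pcd <- kernels[grepl("^PCD-Bv", names(kernels))]
  if (length(pcd) >= 2) {
    strength <- as.numeric(sub("^PCD-Bv", "", names(pcd)))
    o <- order(strength)
    sig <- vapply(pcd, `[[`, 0, "psf_sigma")[o]
    nsd <- vapply(pcd, `[[`, 0, "noise_sd")[o]
    if (any(diff(sig) >= 0))
      stop("PCD kernel family: psf_sigma must strictly decrease with kernel strength")
    if (any(diff(nsd) <= 0))
      stop("PCD kernel family: noise_sd must strictly increase with kernel strength")
  }
  invisible(TRUE)
}

#' Packaged stent roster
#'
#' The twelve coronary and peripheral stents used in the phantom
#' experiments: diameters 3.0-8.0 mm, lengths 15-100 mm, three covered
#' (membrane) stents.  Shipped as a CSV under `extdata/`.
#'
#' @return data.frame with columns `stent_no`, `diameter_mm`, `length_mm`,
#'   `product_name`, `manufacturer`, `covered`.
#' @export
stent_table <- function() {
  path <- system.file("extdata", "stent_table.csv", package = "ctstent",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$covered <- as.logical(tab$covered)
  stopifnot(nrow(tab) == 12L,
            all(tab$diameter_mm >= 3.0 & tab$diameter_mm <= 8.0))
  tab
}

#' Build stent_spec objects from the roster
#'
#' @param table a roster data.frame as returned by [stent_table()]; defaults
#'   to the packaged roster.
#' @param ... further arguments (strut defaults, attenuations) passed to
#'   [stent_spec()].
#' @return list of [stent_spec], named by stent number.
#' @export
stent_specs_from_table <- function(table = stent_table(), ...) {
  specs <- lapply(seq_len(nrow(table)), function(i)
    stent_spec(stent_id = sprintf("S%02d_%s", table$stent_no[i],
                                  gsub("[^A-Za-z0-9]+", "_",
                                       table$product_name[i])),
               diameter = table$diameter_mm[i], length = table$length_mm[i],
               covered = table$covered[i], ...))
  names(specs) <- sprintf("stent_%02d", table$stent_no)
  specs
}

#' Filter a roster or report to small-diameter stents
#'
#' The subgroup analysis of small coronary stents keeps diameters at or
#' below a cutoff (default 3.5 mm).
#'
#' @param x data.frame with a `diameter_mm` column.
#' @param max_diameter inclusive diameter cutoff, mm.
#' @return the filtered data.frame.
#' @export
subgroup_small <- function(x, max_diameter = 3.5) {
  stopifnot(is.data.frame(x), "diameter_mm" %in% names(x))
  x[x$diameter_mm <= max_diameter, , drop = FALSE]
}
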