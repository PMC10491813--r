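#' Place the four background ROIs around the stent
#'
#' Four circular ROIs of equal area (default 100 mm^2, radius about
#' 5.64 mm) are placed in the water at 0, 90, 180 and 270 degrees around
#' the stent on an axial slice, with their nearest edge 5 mm from the
#' stent's outer wall.  By default the mid-stent slice is used and the
#' stent center/radius are taken from the volume's provenance.
#'
#' @param volume a [ct_volume].
#' @param stent_center length-2 (x, y) world mm; default from `axis_hint`.
#' @param stent_outer_radius outer radius of the tube wall, mm; default
#'   from provenance.
#' @param slice_index axial slice; default the mid-stent slice.
#' @param roi_area area per ROI, mm^2.
#' @param clearance gap between the stent outer wall and the nearest ROI
#'   edge, mm (default 5, i.e. 0.5 cm).
#' @return An object of class `roi_set`: ROI centers (4 x 2 mm), `radius`,
#'   `slice_index`, `pixel_area`.
#' @export
place_background_rois <- function(volume, stent_center = NULL,
                                  stent_outer_radius = NULL,
                                  slice_index = NULL, roi_area = 100,
                                  clearance = 5) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels); sp <- volume$spacing
  if (is.null(stent_center)) {
    if (is.null(volume$axis_hint))
      stop("no `stent_center` given and the volume has no axis_hint")
    stent_center <- volume$axis_hint$point[1:2]
  }
  if (is.null(stent_outer_radius)) {
    stent_outer_radius <- volume$provenance$stent_outer_radius
    if (is.null(stent_outer_radius))
      stop("no `stent_outer_radius` given and none recorded in provenance")
  }
  if (is.null(slice_index)) {
    sz <- volume$provenance$stent_z
    zc <- if (!is.null(sz)) mean(sz) else d[3] * sp[3] / 2
    slice_index <- max(1L, min(d[3], round(zc / sp[3] + 0.5)))
  }
  r_roi <- sqrt(roi_area / pi)
  ring <- stent_outer_radius + clearance + r_roi
  # farthest ROI point from the stent center
  need <- ring + r_roi
  room <- min(stent_center[1], d[1] * sp[1] - stent_center[1],
              stent_center[2], d[2] * sp[2] - stent_center[2])
  if (need > room)
    stop(sprintf(paste0("water region too small for the background ROIs:",
                        " need %.1f mm of water around the stent center,",
                        " volume provides %.1f mm"), need, room))
  ang <- c(0, 90, 180, 270) * pi / 180
  centers <- cbind(stent_center[1] + ring * cos(ang),
                   stent_center[2] + ring * sin(ang))
  # adjacent ROI centers are ring*sqrt(2) apart; must exceed one diameter
  if (ring * sqrt(2) <= 2 * r_roi)
    stop("background ROIs would overlap; increase the clearance")
  structure(
    list(centers = centers, radius = r_roi, slice_index = slice_index,
         roi_area = roi_area, pixel_area = sp[1] * sp[2],
         stent_center = stent_center,
         stent_outer_radius = stent_outer_radius),
    class = "roi_set")
}

#' Coefficient of variation over the four background ROIs
#'
#' Per ROI, the mean and SD of the HU values of all voxels whose centers
#' fall inside the circle are computed; then
#' `CV = sigma_bar / mean_hu`, with `sigma_bar` the mean of the four SDs
#' and `mean_hu` the mean of the four means.  With a background near 0 HU
#' the denominator is small, so CV is large in magnitude and takes the sign
#' of the mean; the absolute value is reported alongside.
#'
#' @param volume a [ct_volume].
#' @param rois a [place_background_rois()] result.
#' @return An object of class `cv_result`: `cv`, `cv_abs`, `sigma_bar`,
#'   `mean_hu`, and the per-ROI means/SDs.
#' @export
coefficient_of_variation <- function(volume, rois = place_background_rois(volume)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(rois, "roi_set"))
  d <- dim(volume$voxels); sp <- volume$spacing
  if (rois$slice_index < 1 || rois$slice_index > d[3])
    stop("ROI slice outside volume")
  slice <- volume$voxels[, , rois$slice_index]
  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  per_mean <- per_sd <- numeric(4)
  for (i in 1:4) {
    inx <- abs(xc - rois$centers[i, 1]) <= rois$radius
    iny <- abs(yc - rois$centers[i, 2]) <= rois$radius
    sub <- slice[inx, iny, drop = FALSE]
    r2 <- outer((xc[inx] - rois$centers[i, 1])^2,
                (yc[iny] - rois$centers[i, 2])^2, "+")
    vals <- sub[r2 <= rois$radius^2]
    if (length(vals) < 2) stop("ROI contains fewer than two voxels")
    per_mean[i] <- mean(vals)
    per_sd[i] <- stats::sd(vals)
  }
  sigma_bar <- mean(per_sd)
  mean_hu <- mean(per_mean)
  if (mean_hu == 0)
    stop(sprintf("CV undefined at zero mean (sigma_bar = %.3f HU)", sigma_bar))
  structure(
    list(cv = sigma_bar / mean_hu, cv_abs = abs(sigma_bar / mean_hu),
         sigma_bar = sigma_bar, mean_hu = mean_hu,
         per_roi_mean = per_mean, per_roi_sd = per_sd),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> CV = %.3f (sigma_bar %.2f HU / mean %.2f HU)\n",
              x$cv, x$sigma_bar, x$mean_hu))
  invisible(x)
}
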