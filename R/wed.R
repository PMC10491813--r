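#' Region-of-interest mask on one slice
#'
#' @param slice_index index of the axial slice the mask refers to.
#' @param mask logical matrix congruent with the slice (`dim(volume)[1:2]`).
#' @param pixel_area area of one pixel, mm^2.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(slice_index, mask, pixel_area) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("`mask` must contain at least one pixel")
  if (pixel_area <= 0) stop("`pixel_area` must be positive")
  structure(list(slice_index = as.integer(slice_index), mask = mask,
                 pixel_area = pixel_area),
            class = "roi_mask")
}

#' Water-equivalent diameter of a slice region (AAPM TG220)
#'
#' Computes the diameter of the water cylinder with the same total
#' attenuation as the region:
#' `D_W = 2 * sqrt((mean_HU / 1000 + 1) * A_ROI / pi)`,
#' where `A_ROI` is the summed pixel area.  The region may be a whole slice
#' including surrounding air: air pixels at -1000 HU contribute area but no
#' attenuation and cancel exactly in the continuum limit.
#'
#' @param volume a [ct_volume].
#' @param roi a [roi_mask]; alternatively `NULL` to use the whole slice
#'   given by `slice_index`.
#' @param slice_index slice to use when `roi` is `NULL`.
#' @return A list of class `wed_result`: `d_w` (cm), `mean_hu` (HU), `area`
#'   (cm^2).
#' @export
water_equivalent_diameter <- function(volume, roi = NULL, slice_index = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(roi)) {
    if (is.null(slice_index))
      stop("supply a `roi_mask` or a `slice_index` for the whole slice")
    d <- dim(volume$voxels)
    roi <- roi_mask(slice_index, matrix(TRUE, d[1], d[2]),
                    pixel_area = volume$spacing[1] * volume$spacing[2])
  }
  d <- dim(volume$voxels)
  if (roi$slice_index < 1 || roi$slice_index > d[3])
    stop("`slice_index` outside volume")
  if (!all(dim(roi$mask) == d[1:2]))
    stop("ROI mask is not congruent with the slice")
  hu <- volume$voxels[, , roi$slice_index][roi$mask]
  mean_hu <- mean(hu)
  if (mean_hu < -1000)
    stop("mean HU below -1000: not a physically possible region")
  area_mm2 <- sum(roi$mask) * roi$pixel_area
  d_w_mm <- 2 * sqrt((mean_hu / 1000 + 1) * area_mm2 / pi)
  structure(list(d_w = d_w_mm / 10, mean_hu = mean_hu,
                 area = area_mm2 / 100),
            class = "wed_result")
}

#' @export
print.wed_result <- function(x, ...) {
  cat(sprintf("<wed_result> D_W = %.3f cm (mean %.1f HU over %.2f cm^2)\n",
              x$d_w, x$mean_hu, x$area))
  invisible(x)
}
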