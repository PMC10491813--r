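#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of Hounsfield units together with its
#' physical voxel spacing and optional provenance.  Voxel centers follow the
#' half-voxel convention: voxel `[i, j, k]` is centered at world coordinate
#' `((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz)` in mm, so world
#' coordinate 0 is the lower grid face along every axis.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all
#'   components must be positive.
#' @param axis_hint optional list with elements `point` (length-3, mm) and
#'   `direction` (length-3, unit vector) marking the stent axis.
#' @param provenance named list of free-form metadata (kernel name, seed,
#'   source).
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, axis_hint = NULL, provenance = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (!all(is.finite(voxels)))
    stop("HU values must be finite")
  if (!is.null(axis_hint)) {
    axis_hint <- as_axis(axis_hint)
    if (!axis_intersects(axis_hint, dim(voxels), spacing))
      stop("`axis_hint` does not intersect the voxel grid")
  }
  structure(
    list(voxels = voxels, spacing = spacing, axis_hint = axis_hint,
         provenance = provenance),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  if (!is.null(x$axis_hint))
    cat(sprintf("  axis through (%.2f, %.2f, %.2f) direction (%.3f, %.3f, %.3f)\n",
                x$axis_hint$point[1], x$axis_hint$point[2], x$axis_hint$point[3],
                x$axis_hint$direction[1], x$axis_hint$direction[2],
                x$axis_hint$direction[3]))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# normalize an axis spec to list(point, direction-unit-vector)
as_axis <- function(axis) {
  if (is.null(axis$point) || is.null(axis$direction))
    stop("axis must have `point` and `direction`")
  p <- as.numeric(axis$point); d <- as.numeric(axis$direction)
  if (length(p) != 3L || length(d) != 3L) stop("axis point/direction must be length 3")
  n <- sqrt(sum(d^2))
  if (n == 0) stop("axis direction must be non-zero")
  list(point = p, direction = d / n)
}

# does the infinite line intersect the grid bounding box [0, dim*spacing]?
axis_intersects <- function(axis, dims, spacing) {
  lo <- rep(0, 3); hi <- dims * spacing
  p <- axis$point; d <- axis$direction
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    if (abs(d[k]) < 1e-12) {
      if (p[k] < lo[k] || p[k] > hi[k]) return(FALSE)
    } else {
      t1 <- (lo[k] - p[k]) / d[k]; t2 <- (hi[k] - p[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  tmax >= tmin
}

#' Trilinear interpolation of a CT volume
#'
#' Samples HU values at arbitrary world coordinates (mm) by trilinear
#' interpolation between voxel centers.  Points outside the volume (beyond
#' the outermost voxel centers plus half a voxel) yield `NA`, unless
#' `rule = "clamp"`, which clamps to the nearest voxel center.
#'
#' @param volume a [ct_volume].
#' @param points numeric matrix with 3 columns (x, y, z world mm).
#' @param rule `"na"` or `"clamp"` for out-of-volume points.
#' @return numeric vector of interpolated HU, one per row of `points`.
#' @export
interp_volume <- function(volume, points, rule = c("na", "clamp")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(points), ncol(points) == 3L)
  d <- dim(volume$voxels); sp <- volume$spacing
  # fractional voxel-center index: world w maps to index w/sp + 0.5
  fi <- sweep(points, 2, sp, "/") + 0.5
  outside <- fi[, 1] < 0.5 | fi[, 1] > d[1] + 0.5 |
             fi[, 2] < 0.5 | fi[, 2] > d[2] + 0.5 |
             fi[, 3] < 0.5 | fi[, 3] > d[3] + 0.5
  # clamp into the interpolable core for the arithmetic
  for (k in 1:3) fi[, k] <- pmin(pmax(fi[, k], 1), d[k])
  i0 <- floor(fi); frac <- fi - i0
  for (k in 1:3) {
    hi <- max(d[k] - 1L, 1L)
    over <- i0[, k] > hi
    frac[over, k] <- if (d[k] > 1L) 1 else 0
    i0[over, k] <- hi
  }
  v <- volume$voxels
  # upper-neighbor index is clamped; its weight is zero whenever it matters
  idx <- function(ox, oy, oz)
    v[cbind(pmin(i0[, 1] + ox, d[1]), pmin(i0[, 2] + oy, d[2]),
            pmin(i0[, 3] + oz, d[3]))]
  fx <- frac[, 1]; fy <- frac[, 2]; fz <- frac[, 3]
  val <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    idx(1, 1, 0) * fx       * fy       * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 0, 1) * fx       * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy       * fz +
    idx(1, 1, 1) * fx       * fy       * fz
  if (rule == "na") val[outside] <- NA_real_
  val
}
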