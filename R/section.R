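#' Extract the planar section through the stent axis
#'
#' Resamples, by trilinear interpolation, the plane that contains the stent
#' axis onto a regular grid: rows run along the axis, columns transverse to
#' it, with the transverse coordinate zero on the axis.  This is the
#' multiplanar reformation feeding the profile analysis.
#'
#' @param volume a [ct_volume].
#' @param axis list with `point` and `direction` (mm world coordinates);
#'   defaults to the volume's `axis_hint`.
#' @param row_spacing spacing along the axis, mm; default the axial voxel
#'   spacing.
#' @param col_spacing transverse sampling, mm; default a quarter of the
#'   in-plane pixel size (sub-pixel sampling for the level crossings).
#' @param col_halfwidth transverse half-extent, mm; default as wide as the
#'   volume allows around the axis.
#' @return An object of class `section_image`: `pixels` (rows x cols HU),
#'   `row_positions` (mm along the axis), `col_positions` (mm, 0 on the
#'   axis), spacings, and the axis used.
#' @export
extract_section <- function(volume, axis = NULL, row_spacing = NULL,
                            col_spacing = NULL, col_halfwidth = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(axis)) axis <- volume$axis_hint
  if (is.null(axis)) stop("no axis given and the volume carries no axis_hint")
  axis <- as_axis(axis)
  d <- dim(volume$voxels); sp <- volume$spacing
  if (!axis_intersects(axis, d, sp)) stop("axis lies outside the volume")
  if (is.null(row_spacing)) row_spacing <- sp[3]
  if (is.null(col_spacing)) col_spacing <- sp[1] / 4
  # t-range of the axis inside the bounding box
  tr <- axis_t_range(axis, d, sp)
  u <- transverse_unit(axis$direction)
  if (is.null(col_halfwidth))
    col_halfwidth <- max_col_halfwidth(axis, u, tr, d, sp)
  if (col_halfwidth <= 0) stop("axis leaves no transverse room in the volume")
  trow <- seq(tr[1], tr[2], by = row_spacing)
  cols <- seq(-col_halfwidth, col_halfwidth, by = col_spacing)
  pts <- cbind(rep(trow, times = length(cols)), rep(cols, each = length(trow)))
  world <- cbind(axis$point[1] + pts[, 1] * axis$direction[1] + pts[, 2] * u[1],
                 axis$point[2] + pts[, 1] * axis$direction[2] + pts[, 2] * u[2],
                 axis$point[3] + pts[, 1] * axis$direction[3] + pts[, 2] * u[3])
  hu <- interp_volume(volume, world, rule = "clamp")
  structure(
    list(pixels = matrix(hu, nrow = length(trow), ncol = length(cols)),
         row_positions = trow, col_positions = cols,
         row_spacing = row_spacing, col_spacing = col_spacing,
         axis = axis, provenance = volume$provenance),
    class = "section_image")
}

# parameter range of axis point + t * direction inside the grid box,
# inset by half a voxel so interpolation stays within voxel centers
axis_t_range <- function(axis, dims, spacing) {
  lo <- spacing / 2; hi <- dims * spacing - spacing / 2
  tmin <- -Inf; tmax <- Inf
  for (k in 1:3) {
    dk <- axis$direction[k]
    if (abs(dk) < 1e-12) next
    t1 <- (lo[k] - axis$point[k]) / dk
    t2 <- (hi[k] - axis$point[k]) / dk
    tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
  }
  if (!is.finite(tmin)) tmin <- 0
  if (!is.finite(tmax)) tmax <- max(dims * spacing)
  c(tmin, tmax)
}

# unit vector orthogonal to the axis, preferring the world x direction
transverse_unit <- function(d) {
  e <- c(1, 0, 0)
  u <- e - sum(e * d) * d
  if (sqrt(sum(u^2)) < 1e-6) {
    e <- c(0, 1, 0)
    u <- e - sum(e * d) * d
  }
  u / sqrt(sum(u^2))
}

# widest symmetric transverse extent that keeps the mid-axis samples inside
# the grid; components of u below 1% (sub-voxel drift over the field of
# view, absorbed by clamped interpolation) are ignored
max_col_halfwidth <- function(axis, u, tr, dims, spacing) {
  lo <- spacing / 2; hi <- dims * spacing - spacing / 2
  cmax <- Inf
  p <- axis$point + mean(tr) * axis$direction
  for (k in 1:3) {
    if (abs(u[k]) < 0.01) next
    cands <- c((lo[k] - p[k]) / u[k], (hi[k] - p[k]) / u[k])
    cmax <- min(cmax, max(cands))
    cmax <- min(cmax, -min(cands))
  }
  cmax
}

#' Detect the stent axis in a CT volume
#'
#' Thresholds the volume midway between the contrast-lumen mode and the
#' strut peak, takes per-slice centroids of supra-threshold voxels, and fits
#' a 3-D least-squares line (first principal component) through them.
#'
#' @param volume a [ct_volume].
#' @param threshold optional HU threshold; by default the midpoint between
#'   the median supra-water attenuation (the lumen mode) and the maximum.
#' @return list with `point` and `direction` (unit vector, oriented towards
#'   positive z).
#' @export
detect_axis <- function(volume, threshold = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  bright <- v[v > 150]
  if (length(bright) == 0)
    stop("no supra-threshold voxels: volume contains no high-attenuation object")
  if (is.null(threshold))
    threshold <- (stats::median(bright) + max(bright)) / 2
  idx <- which(v > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no supra-threshold voxels above the chosen threshold")
  sp <- volume$spacing
  world <- sweep(idx - 0.5, 2, sp, "*")
  wt <- v[idx] - threshold               # supra-threshold attenuation weight
  zs <- split(seq_len(nrow(idx)), idx[, 3])
  # drop sparse slices (partial rings at the stent ends, noise specks):
  # their few pixels give unstable, biased centroids
  counts <- lengths(zs)
  zs <- zs[counts >= 0.25 * max(counts)]
  cent <- t(vapply(zs, function(i) {
    w <- wt[i] / sum(wt[i])
    colSums(world[i, , drop = FALSE] * w)
  }, numeric(3)))
  if (nrow(cent) < 2)
    stop("supra-threshold voxels span fewer than two slices; cannot fit an axis")
  ctr <- colMeans(cent)
  pc <- prcomp(cent, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  if (dir[3] < 0) dir <- -dir
  list(point = ctr, direction = dir / sqrt(sum(dir^2)))
}
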