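#' Per-row transverse attenuation profiles over the stent extent
#'
#' Slices the section image into one transverse HU profile per axial row
#' inside the stent extent.  The number of rows depends on the stent length
#' and the row spacing.
#'
#' @param section a [extract_section()] result.
#' @param stent_extent numeric length-2, interval along the axis (mm, in the
#'   section's row coordinates).
#' @return An object of class `profile_stack`: `profiles` (n_rows x n_pos
#'   matrix), shared `positions` (mm), `n_rows`.
#' @export
profile_stack <- function(section, stent_extent) {
  stopifnot(inherits(section, "section_image"), length(stent_extent) == 2L)
  if (diff(stent_extent) <= 0) stop("empty stent extent")
  keep <- section$row_positions >= stent_extent[1] &
          section$row_positions <= stent_extent[2]
  if (!any(keep)) stop("stent extent contains no section rows")
  structure(
    list(profiles = section$pixels[keep, , drop = FALSE],
         positions = section$col_positions, n_rows = sum(keep)),
    class = "profile_stack")
}

#' Average attenuation profile
#'
#' Pointwise arithmetic mean of all row profiles; averaging over many rows
#' suppresses noise by `1/sqrt(n_rows)`.
#'
#' @param stack a [profile_stack()] result.
#' @return An object of class `mean_profile`: `positions` (mm), `hu`,
#'   `n_rows_averaged`.
#' @export
mean_profile <- function(stack) {
  stopifnot(inherits(stack, "profile_stack"), stack$n_rows >= 1)
  structure(
    list(positions = stack$positions, hu = colMeans(stack$profiles),
         n_rows_averaged = stack$n_rows),
    class = "mean_profile")
}

#' Locate the stent signature in a mean profile
#'
#' Finds the two strut maxima (the global maximum on each side of the
#' profile center), the lumen minimum strictly between them, and the water
#' baseline (average of the medians of the outer 20 percent of positions on
#' each side).  A profile without two maxima rising at least three noise
#' floors above baseline is rejected.
#'
#' @param profile a [mean_profile()] (or any list with `positions` and
#'   `hu`).
#' @param center transverse position of the profile center, mm (default 0,
#'   the axis).
#' @return An object of class `peak_pair` with the peak/minimum positions
#'   and HU values plus `baseline_hu`.
#' @export
locate_features <- function(profile, center = 0) {
  x <- profile$positions; y <- profile$hu
  n <- length(x)
  if (n < 5 || length(y) != n) stop("profile too short")
  n_out <- max(2L, floor(0.2 * n))
  left_out <- y[seq_len(n_out)]
  right_out <- y[seq(n - n_out + 1L, n)]
  baseline <- (stats::median(left_out) + stats::median(right_out)) / 2
  noise_floor <- max(stats::sd(left_out), stats::sd(right_out), 1e-9)
  li <- which(x < center); ri <- which(x > center)
  if (!length(li) || !length(ri)) stop("profile does not straddle the center")
  ipl <- li[which.max(y[li])]
  ipr <- ri[which.max(y[ri])]
  if (y[ipl] <= baseline + 3 * noise_floor ||
      y[ipr] <= baseline + 3 * noise_floor)
    stop("no stent signature: profile maxima do not rise above the baseline")
  if (ipr - ipl < 2L) stop("no stent signature: maxima are adjacent")
  between <- seq(ipl + 1L, ipr - 1L)
  imin <- between[which.min(y[between])]
  if (y[ipl] <= y[imin] || y[ipr] <= y[imin])
    stop("no stent signature: no lumen minimum between the maxima")
  structure(
    list(left_peak_pos = x[ipl], right_peak_pos = x[ipr],
         left_peak_hu = y[ipl], right_peak_hu = y[ipr],
         lumen_min_pos = x[imin], lumen_min_hu = y[imin],
         baseline_hu = baseline,
         left_peak_index = ipl, right_peak_index = ipr),
    class = "peak_pair")
}

#' Edge-rise distance and slope of the stent edges
#'
#' On the outer (background-to-peak) flank of each side, the 10 and 90
#' percent levels of the rise above baseline are
#' `HU10 = baseline + 0.10 * (peak - baseline)` and
#' `HU90 = baseline + 0.90 * (peak - baseline)`.  Crossing positions are
#' found scanning outward from the peak with linear sub-sample
#' interpolation (the crossing nearest the peak, which on a monotone flank
#' is the unique one).  Then `ERD = |pos90 - pos10|` and
#' `ERS = (HU90 - HU10) / ERD`; `ers_mean` averages the two sides.
#'
#' @param profile a [mean_profile()].
#' @param features a [locate_features()] result for the same profile.
#' @return An object of class `edge_metrics` with per-side `erd`, `ers`,
#'   level values, `ers_mean` and `lumen_min_hu`.
#' @export
edge_rise_metrics <- function(profile, features) {
  x <- profile$positions; y <- profile$hu
  b <- features$baseline_hu
  ipl <- peak_index(features, profile, "left")
  ipr <- peak_index(features, profile, "right")
  left <- flank_crossings(x, y, peak = ipl, baseline = b, side = "left")
  right <- flank_crossings(x, y, peak = ipr, baseline = b, side = "right")
  ers_left <- (left$hu90 - left$hu10) / left$erd
  ers_right <- (right$hu90 - right$hu10) / right$erd
  structure(
    list(erd_left = left$erd, erd_right = right$erd,
         ers_left = ers_left, ers_right = ers_right,
         ers_mean = (ers_left + ers_right) / 2,
         hu10_left = left$hu10, hu90_left = left$hu90,
         hu10_right = right$hu10, hu90_right = right$hu90,
         baseline_hu = b, lumen_min_hu = features$lumen_min_hu),
    class = "edge_metrics")
}

# resolve the peak sample index from a peak_pair, tolerating features built
# by hand (positions only)
peak_index <- function(features, profile, side) {
  idx <- features[[paste0(side, "_peak_index")]]
  if (!is.null(idx)) return(idx)
  pos <- features[[paste0(side, "_peak_pos")]]
  which.min(abs(profile$positions - pos))
}

# scan outward from the peak for the 90 then the 10 percent crossing
flank_crossings <- function(x, y, peak, baseline, side) {
  p <- y[peak]
  hu10 <- baseline + 0.10 * (p - baseline)
  hu90 <- baseline + 0.90 * (p - baseline)
  step <- if (side == "left") -1L else 1L
  last <- if (side == "left") 1L else length(x)
  cross <- function(level, from) {
    i <- from
    while (i != last) {
      j <- i + step
      if ((y[i] >= level && y[j] <= level)) {
        if (y[i] == y[j]) return(list(pos = x[j], index = j))
        frac <- (level - y[i]) / (y[j] - y[i])
        return(list(pos = x[i] + frac * (x[j] - x[i]), index = j))
      }
      i <- j
    }
    stop(sprintf("edge unresolved: %s flank does not cross the %.1f HU level",
                 side, level))
  }
  c90 <- cross(hu90, peak)
  c10 <- cross(hu10, c90$index)
  erd <- abs(c90$pos - c10$pos)
  if (erd <= 0) stop("edge unresolved: degenerate 10-90 distance")
  list(erd = erd, hu10 = hu10, hu90 = hu90,
       pos10 = c10$pos, pos90 = c90$pos)
}

#' Full quantitative stent analysis of one volume
#'
#' Runs the whole profiling pipeline: axis (given, from `axis_hint`, or
#' auto-detected), section extraction, stent-extent detection, per-row
#' profiles, mean profile, feature location and edge-rise metrics.  Errors
#' are labeled with the stage that raised them.  All intermediates are kept
#' in the returned object.
#'
#' @param volume a [ct_volume].
#' @param axis optional axis (list with `point`, `direction`).
#' @param stent_extent optional interval (mm along the axis) overriding the
#'   automatic extent detection.
#' @param end_trim mm trimmed off each end of the detected extent to avoid
#'   end-cap partial volume; defaults to the reconstructed slice thickness.
#' @param ... passed to [extract_section()].
#' @return An object of class `stent_analysis`: `metrics`
#'   ([edge_rise_metrics()]), `features`, `profile`, `stack`, `section`,
#'   `axis`, `stent_extent`.
#' @export
analyze_stent <- function(volume, axis = NULL, stent_extent = NULL,
                          end_trim = NULL, ...) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(axis)) axis <- volume$axis_hint
  if (is.null(axis))
    axis <- in_stage("detect_axis", detect_axis(volume))
  section <- in_stage("extract_section", extract_section(volume, axis, ...))
  if (is.null(end_trim))
    end_trim <- volume$provenance$slice_thickness %||% volume$spacing[3]
  if (is.null(stent_extent))
    stent_extent <- in_stage("detect_extent",
                             detect_stent_extent(section, end_trim))
  stack <- in_stage("profile_stack", profile_stack(section, stent_extent))
  profile <- in_stage("mean_profile", mean_profile(stack))
  features <- in_stage("locate_features", locate_features(profile))
  metrics <- in_stage("edge_rise_metrics", edge_rise_metrics(profile, features))
  structure(
    list(metrics = metrics, features = features, profile = profile,
         stack = stack, section = section, axis = as_axis(axis),
         stent_extent = stent_extent),
    class = "stent_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

in_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# rows whose (smoothed) maximum rises at least halfway from the tube level
# to the stent level belong to the stent; strut rings make the per-row
# maximum oscillate, so the row signal is smoothed over ~1 mm and the
# extent is the first-to-last crossing, trimmed by `end_trim` at both ends
detect_stent_extent <- function(section, end_trim = 0) {
  rmax <- apply(section$pixels, 1, max)
  w <- max(3L, 2L * floor(0.5 / section$row_spacing) + 1L)
  if (length(rmax) > w) {
    sm <- stats::filter(rmax, rep(1 / w, w), sides = 2)
    pad <- (w - 1L) / 2L
    sm[seq_len(pad)] <- sm[pad + 1L]
    sm[seq(length(sm) - pad + 1L, length(sm))] <- sm[length(sm) - pad]
    rmax <- as.numeric(sm)
  }
  lo <- stats::median(sort(rmax)[seq_len(max(2L, floor(0.15 * length(rmax))))])
  hi <- max(rmax)
  if (hi - lo < 1e-6) stop("no stent signature: section rows are uniform")
  above <- which(rmax > lo + 0.5 * (hi - lo))
  ext <- c(section$row_positions[min(above)] + end_trim,
           section$row_positions[max(above)] - end_trim)
  if (diff(ext) <= 0) stop("detected stent extent shorter than the end trim")
  ext
}

#' @export
print.edge_metrics <- function(x, ...) {
  cat(sprintf("<edge_metrics> ERS_mean %.1f HU/mm (L %.1f, R %.1f); ERD L %.3f / R %.3f mm; lumen min %.1f HU\n",
              x$ers_mean, x$ers_left, x$ers_right, x$erd_left, x$erd_right,
              x$lumen_min_hu))
  invisible(x)
}

#' @export
print.stent_analysis <- function(x, ...) {
  cat(sprintf("<stent_analysis> extent %.1f..%.1f mm, %d rows averaged\n",
              x$stent_extent[1], x$stent_extent[2],
              x$profile$n_rows_averaged))
  print(x$metrics)
  invisible(x)
}
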