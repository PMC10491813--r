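#' Configuration of a full phantom experiment
#'
#' @param kernels named list of [kernel_model] objects.
#' @param stents list of [stent_spec] objects (default: the packaged
#'   roster).
#' @param geometry a [phantom_geometry].
#' @param seeds integer vector of unique noise seeds; one full stent-by-
#'   kernel pass is simulated per seed.
#' @param supersample simulator supersampling factor.
#' @param noise simulate noise (`FALSE` for noise-free quantitative runs).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(kernels = default_kernels(),
                       stents = stent_specs_from_table(),
                       geometry = phantom_geometry(), seeds = 1L,
                       supersample = 4, noise = TRUE, output_dir = NULL) {
  if (!length(kernels) || !length(stents))
    stop("need at least one kernel and one stent")
  if (anyDuplicated(seeds)) stop("seeds must be unique")
  if (is.null(names(kernels)))
    names(kernels) <- vapply(kernels, `[[`, "", "name")
  structure(
    list(kernels = kernels, stents = stents, geometry = geometry,
         seeds = as.integer(seeds), supersample = supersample,
         noise = isTRUE(noise), output_dir = output_dir),
    class = "run_config")
}

#' Run the full simulate-analyze-compare experiment
#'
#' For every (stent, kernel, seed) triple: simulate the scan, run the
#' edge-rise-slope pipeline and the four-ROI coefficient of variation, and
#' collect one result row.  Edge metrics are then compared across kernels
#' with a repeated-measures ANOVA (subjects = stents), for the full roster
#' and for the small-diameter (<= 3.5 mm) subgroup.  Per-case failures are
#' recorded and do not stop the run.
#'
#' @param config a [run_config].
#' @return list of class `experiment_report`: `results` (one row per
#'   case), `anova` (list of `ct_test` per metric), `subgroup` (same
#'   structure for the <= 3.5 mm subset), `failures`, `config`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  rows <- list(); failures <- character()
  for (si in seq_along(config$stents)) {
    spec <- config$stents[[si]]
    for (kn in names(config$kernels)) {
      kernel <- config$kernels[[kn]]
      for (seed in config$seeds) {
        case <- sprintf("%s/%s/seed%d", spec$stent_id, kn, seed)
        res <- tryCatch({
          vol <- simulate_scan(spec, config$geometry, kernel, seed = seed,
                               supersample = config$supersample,
                               noise = config$noise)
          an <- analyze_stent(vol)
          cv <- coefficient_of_variation(vol, place_background_rois(vol))
          m <- an$metrics
          data.frame(
            stent = spec$stent_id, diameter_mm = spec$diameter,
            length_mm = spec$length, covered = spec$covered,
            kernel = kn, psf_sigma = kernel$psf_sigma, seed = seed,
            ers_mean = m$ers_mean, ers_left = m$ers_left,
            ers_right = m$ers_right, erd_left = m$erd_left,
            erd_right = m$erd_right, lumen_min_hu = m$lumen_min_hu,
            baseline_hu = m$baseline_hu, cv = cv$cv, cv_abs = cv$cv_abs,
            sigma_bar = cv$sigma_bar, roi_mean_hu = cv$mean_hu,
            package_version = as.character(utils::packageVersion("ctstent")),
            stringsAsFactors = FALSE)
        }, error = function(e) {
          failures[[case]] <<- conditionMessage(e)
          NULL
        })
        if (!is.null(res)) rows[[case]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  report <- structure(
    list(results = results,
         anova = experiment_anova(results),
         subgroup = {
           sub <- subgroup_small(results)
           list(results = sub, anova = experiment_anova(sub))
         },
         failures = failures, config = config),
    class = "experiment_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# RM-ANOVA (subjects = stents, within = kernel) for ERS and CV, averaging
# over seeds first when several were run; NULL when the table is too small
experiment_anova <- function(results) {
  if (is.null(results) || !nrow(results)) return(NULL)
  out <- list()
  for (metric in c("ers_mean", "cv")) {
    agg <- stats::aggregate(results[[metric]],
                            by = list(stent = results$stent,
                                      reconstruction = results$kernel),
                            FUN = mean)
    names(agg)[3] <- "value"
    out[[metric]] <- tryCatch(repeated_measures_anova(agg),
                              error = function(e) NULL)
  }
  out
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  stats_json <- list(
    anova = lapply(report$anova, unclass),
    subgroup_anova = lapply(report$subgroup$anova, unclass),
    failures = as.list(report$failures))
  jsonlite::write_json(stats_json, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d result rows (%d stents x %d kernels x %d seeds), %d failures\n",
              if (is.null(x$results)) 0L else nrow(x$results),
              length(x$config$stents), length(x$config$kernels),
              length(x$config$seeds), length(x$failures)))
  if (!is.null(x$anova$ers_mean)) {
    cat("  ERS  "); print(x$anova$ers_mean)
  }
  if (!is.null(x$anova$cv)) {
    cat("  CV   "); print(x$anova$cv)
  }
  invisible(x)
}
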