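#' Latent-variable model for synthetic reader scores
#'
#' Ordinal 5-point Likert scores are generated from a latent image-quality
#' variable: `latent = latent_quality[reconstruction] + reader_bias[reader]
#' + noise`, discretized through four increasing cutpoints into scores 1-5.
#' This is a synthetic stand-in for a multi-reader reading session, built so
#' the downstream ordinal statistics have a controllable ground truth.
#'
#' @param n_readers number of readers (>= 2).
#' @param n_stents number of rated objects per reader and reconstruction.
#' @param latent_quality named numeric, one latent mean per reconstruction
#'   (on the score scale; 3 = neutral).
#' @param reader_bias per-reader additive offset, length `n_readers`
#'   (default 0).
#' @param noise_sd SD of the latent noise (default 0.5, under one Likert
#'   step of between-reader spread).
#' @param stent_effect_sd SD of a per-stent latent quality offset shared by
#'   all readers (default 0.8).  Stents genuinely differ in how well they
#'   image; this common signal is what lifts inter-reader agreement above
#'   chance.  The default dispersion pair places Fleiss' kappa of the
#'   generated tables in the fair band (about 0.25-0.33), the level
#'   typical of multi-reader ordinal image-quality studies.
#' @param cutpoints four strictly increasing thresholds mapping the latent
#'   value to scores 1-5; default `c(1.5, 2.5, 3.5, 4.5)`.
#' @param criteria character vector of rating criteria labels.
#' @return An object of class `reader_model`.
#' @export
reader_model <- function(n_readers = 5, n_stents = 12,
                         latent_quality = c("EID-Bv40" = 2.4,
                                            "PCD-Bv40" = 2.8,
                                            "PCD-Bv48" = 3.3,
                                            "PCD-Bv56" = 3.6),
                         reader_bias = rep(0, n_readers), noise_sd = 0.5,
                         stent_effect_sd = 0.8,
                         cutpoints = c(1.5, 2.5, 3.5, 4.5),
                         criteria = c("overall_quality", "sharpness", "noise",
                                      "blooming", "diagnostic_confidence")) {
  if (n_readers < 2) stop("`n_readers` must be >= 2")
  if (length(reader_bias) != n_readers)
    stop("`reader_bias` must have one entry per reader")
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0))
    stop("`cutpoints` must be 4 strictly increasing thresholds")
  if (is.null(names(latent_quality)))
    names(latent_quality) <- paste0("recon", seq_along(latent_quality))
  if (stent_effect_sd < 0) stop("`stent_effect_sd` must be non-negative")
  structure(
    list(n_readers = n_readers, n_stents = n_stents,
         latent_quality = latent_quality, reader_bias = reader_bias,
         noise_sd = noise_sd, stent_effect_sd = stent_effect_sd,
         cutpoints = cutpoints, criteria = criteria),
    class = "reader_model")
}

#' Simulate a reader-score table
#'
#' Draws one score per reader x stent x reconstruction x criterion from a
#' [reader_model], reproducibly for a given seed.  The same latent quality
#' drives all criteria (with independent noise), mimicking criteria that are
#' correlated facets of one perceived image quality.
#'
#' @param model a [reader_model].
#' @param seed integer seed.
#' @return A long-format data.frame of class `likert_table` with columns
#'   `reader`, `stent`, `reconstruction`, `criterion`, `score` (integer
#'   1-5).
#' @export
simulate_ratings <- function(model, seed = 1L) {
  stopifnot(inherits(model, "reader_model"))
  recons <- names(model$latent_quality)
  grid <- expand.grid(reader = paste0("R", seq_len(model$n_readers)),
                      stent = seq_len(model$n_stents),
                      reconstruction = recons,
                      criterion = model$criteria,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- model$latent_quality[grid$reconstruction] +
    model$reader_bias[as.integer(sub("^R", "", grid$reader))]
  draws <- with_preserved_rng(seed, {
    list(stent_effect = stats::rnorm(model$n_stents,
                                     sd = model$stent_effect_sd),
         noise = stats::rnorm(nrow(grid), sd = model$noise_sd))
  })
  latent <- latent + draws$stent_effect[grid$stent]
  grid$score <- discretize_latent(latent + draws$noise, model$cutpoints)
  class(grid) <- c("likert_table", "data.frame")
  grid
}

# map latent values through cutpoints to integer scores 1..5
discretize_latent <- function(latent, cutpoints) {
  score <- findInterval(latent, cutpoints) + 1L
  pmin(pmax(score, 1L), 5L)
}

#' Validate and coerce a long-format score table
#'
#' @param x data.frame with columns `reader`, `stent`, `reconstruction`,
#'   `criterion`, `score`.
#' @return `x` with class `likert_table`; errors on missing columns, scores
#'   outside 1-5, or incomplete reader x stent x reconstruction cells.
#' @export
as_likert_table <- function(x) {
  need <- c("reader", "stent", "reconstruction", "criterion", "score")
  if (!all(need %in% names(x)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  if (!all(x$score %in% 1:5)) stop("scores must be integers 1..5")
  counts <- table(x$reader, x$stent, x$reconstruction, x$criterion)
  if (any(counts != 1L))
    stop("score table must be complete: one score per reader x stent x reconstruction x criterion")
  class(x) <- unique(c("likert_table", class(x)))
  x
}
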