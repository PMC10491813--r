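#' Median and IQR of reading scores per reconstruction
#'
#' Scores for one criterion are pooled over readers and stents and
#' summarized as median and interquartile range per reconstruction, the
#' conventional presentation for ordinal reading data.
#'
#' @param table a `likert_table` (see [as_likert_table()]).
#' @param criterion criterion label to summarize.
#' @return data.frame with columns `reconstruction`, `median`, `q1`, `q3`,
#'   `n`.
#' @export
summarize_scores <- function(table, criterion = "overall_quality") {
  table <- as_likert_table(table)
  if (!criterion %in% table$criterion)
    stop(sprintf("unknown criterion '%s'", criterion))
  sub <- table[table$criterion == criterion, ]
  recons <- unique(sub$reconstruction)
  out <- do.call(rbind, lapply(recons, function(r) {
    s <- sub$score[sub$reconstruction == r]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(reconstruction = r, median = q[2], q1 = q[1], q3 = q[3],
               n = length(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Friedman rank test across reconstructions
#'
#' Complete-block rank ANOVA with blocks = (reader, stent) pairs and
#' treatments = reconstructions, using average ranks for ties and the
#' tie-corrected chi-square statistic
#' `Q = (k - 1) * sum((R_j - b(k+1)/2)^2) / (sum(r_ij^2) - b k (k+1)^2 / 4)`
#' on `df = k - 1`.
#'
#' @param table a `likert_table`.
#' @param criterion criterion to test.
#' @return list of class `ct_test`: `statistic`, `df`, `p_value`, `method`.
#' @export
friedman_test <- function(table, criterion = "overall_quality") {
  table <- as_likert_table(table)
  if (!criterion %in% table$criterion)
    stop(sprintf("unknown criterion '%s'", criterion))
  sub <- table[table$criterion == criterion, ]
  y <- score_matrix(sub)
  friedman_from_matrix(y)
}

# blocks x treatments score matrix from a long table (single criterion)
score_matrix <- function(sub) {
  block <- interaction(sub$reader, sub$stent, drop = TRUE)
  recon <- factor(sub$reconstruction)
  y <- matrix(NA_real_, nlevels(block), nlevels(recon),
              dimnames = list(levels(block), levels(recon)))
  y[cbind(as.integer(block), as.integer(recon))] <- sub$score
  if (anyNA(y)) stop("incomplete blocks: every block needs every reconstruction")
  y
}

#' Friedman test on a blocks-by-treatments matrix
#'
#' @param y numeric matrix, rows = blocks, columns = treatments.
#' @return list of class `ct_test`.
#' @export
friedman_from_matrix <- function(y) {
  stopifnot(is.matrix(y), !anyNA(y))
  k <- ncol(y); b <- nrow(y)
  if (k < 2) stop("need at least two treatments")
  r <- t(apply(y, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - b * (k + 1) / 2)^2)
  den <- sum(r^2) - b * k * (k + 1)^2 / 4
  stat <- if (den <= 0) 0 else num / den
  structure(
    list(statistic = stat, df = k - 1,
         p_value = if (den <= 0) 1 else
           stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
         method = "Friedman rank ANOVA (tie-corrected)"),
    class = "ct_test")
}

#' Pairwise Wilcoxon rank-sum comparisons with Bonferroni correction
#'
#' Tests every unordered pair of reconstructions with the rank-sum test
#' (normal approximation, continuity correction, tie-corrected variance),
#' pooling scores over readers and stents.  p-values are Bonferroni
#' corrected: `corrected = min(1, m * raw)`.  A signed-rank (paired)
#' variant is available via `paired = TRUE`.
#'
#' @param table a `likert_table`.
#' @param criterion criterion to test.
#' @param paired use the signed-rank test on (reader, stent)-matched pairs.
#' @return data.frame of class `pairwise_matrix` with columns `group_a`,
#'   `group_b`, `statistic`, `raw_p`, `corrected_p`, `degenerate`;
#'   attributes `m` and `correction`.
#' @export
pairwise_wilcoxon <- function(table, criterion = "overall_quality",
                              paired = FALSE) {
  table <- as_likert_table(table)
  if (!criterion %in% table$criterion)
    stop(sprintf("unknown criterion '%s'", criterion))
  sub <- table[table$criterion == criterion, ]
  y <- score_matrix(sub)
  recons <- colnames(y)
  if (length(recons) < 2) stop("need at least two reconstructions")
  pairs <- utils::combn(recons, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- y[, pairs[1, i]]; b <- y[, pairs[2, i]]
    degen <- length(unique(c(a, b))) == 1L
    if (degen) {
      w <- NA_real_; p <- 1
      warning(sprintf("all scores tied for %s vs %s; p set to 1",
                      pairs[1, i], pairs[2, i]), call. = FALSE)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                                exact = FALSE,
                                                correct = TRUE))
      w <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i], statistic = w,
               raw_p = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- pmin(1, m * out$raw_p)
  attr(out, "m") <- m
  attr(out, "correction") <- "bonferroni"
  class(out) <- c("pairwise_matrix", "data.frame")
  out
}

#' Fleiss' kappa for multi-reader agreement
#'
#' Chance-corrected agreement of all readers over items defined as the
#' (stent, reconstruction, criterion) cells, on the five score categories.
#' The agreement band follows the conventional interpretation: below 0.20
#' poor, 0.20-0.39 fair, 0.40-0.59 moderate, 0.60-0.79 substantial, above
#' 0.80 perfect.
#'
#' @param table a `likert_table`.
#' @param categories score categories (default 1..5).
#' @return list of class `kappa_result`: `kappa`, `band`, `n_items`,
#'   `n_raters`.
#' @export
fleiss_kappa <- function(table, categories = 1:5) {
  table <- as_likert_table(table)
  item <- interaction(table$stent, table$reconstruction, table$criterion,
                      drop = TRUE)
  n_raters <- length(unique(table$reader))
  if (n_raters < 2) stop("need at least two raters")
  counts <- base::table(item, factor(table$score, levels = categories))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts))
  if (any(rowSums(counts) != n_raters))
    stop("every item must be rated by every rater exactly once")
  n <- nrow(counts); r <- n_raters
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * r)
  p_e <- sum(p_j^2)
  kappa <- if (p_e >= 1) {
    if (p_bar >= 1) 1 else 0
  } else (p_bar - p_e) / (1 - p_e)
  structure(
    list(kappa = kappa, band = kappa_band(kappa), n_items = n,
         n_raters = r),
    class = "kappa_result")
}

#' Interpretation band for a kappa value
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return one of `"poor"`, `"fair"`, `"moderate"`, `"substantial"`,
#'   `"perfect"`.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (kappa < 0.20) "poor"
  else if (kappa < 0.40) "fair"
  else if (kappa < 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "perfect"
}

#' One-way repeated-measures ANOVA across reconstructions
#'
#' Subjects are stents, the within factor is the reconstruction.  Sums of
#' squares are partitioned as total = treatments + subjects + error, with
#' `F = MS_treatment / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom.
#'
#' @param metrics either a long data.frame with columns `stent`,
#'   `reconstruction`, `value`, or a complete numeric matrix with subjects
#'   in rows and reconstructions in columns.
#' @return list of class `ct_test` with `statistic` (F), `df` (length 2),
#'   `p_value`, and the SS partition in `ss`.
#' @export
repeated_measures_anova <- function(metrics) {
  y <- if (is.matrix(metrics)) metrics else {
    need <- c("stent", "reconstruction", "value")
    if (!all(need %in% names(metrics)))
      stop("long metrics need columns stent, reconstruction, value")
    s <- factor(metrics$stent); r <- factor(metrics$reconstruction)
    m <- matrix(NA_real_, nlevels(s), nlevels(r),
                dimnames = list(levels(s), levels(r)))
    m[cbind(as.integer(s), as.integer(r))] <- metrics$value
    m
  }
  if (anyNA(y)) stop("incomplete table: every stent needs every reconstruction")
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("need at least two stents and two reconstructions")
  gm <- mean(y)
  ss_treat <- n * sum((colMeans(y) - gm)^2)
  ss_subj <- k * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- max(ss_tot - ss_treat - ss_subj, 0)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_treat <- ss_treat / df1; ms_err <- ss_err / df2
  f <- if (ms_err == 0) { if (ms_treat == 0) 0 else Inf } else ms_treat / ms_err
  p <- if (ms_err == 0 && ms_treat == 0) 1 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(
    list(statistic = f, df = c(df1, df2), p_value = p,
         method = "one-way repeated-measures ANOVA",
         ss = c(treatment = ss_treat, subjects = ss_subj, error = ss_err,
                total = ss_tot)),
    class = "ct_test")
}

#' @export
print.ct_test <- function(x, ...) {
  cat(sprintf("<ct_test> %s: statistic %.4g, df %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> Fleiss' kappa = %.3f (%s; %d raters, %d items)\n",
              x$kappa, x$band, x$n_raters, x$n_items))
  invisible(x)
}
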