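test_that("score summaries reproduce order statistics", {
  m <- null_reader_model(n_readers = 2, n_stents = 2, k = 2)
  tab <- simulate_ratings(m, seed = 1)
  tab$score <- 4L
  s <- summarize_scores(tab)
  expect_equal(s$median, c(4, 4))
  expect_equal(s$q1, c(4, 4)); expect_equal(s$q3, c(4, 4))
  tab2 <- data.frame(reader = paste0("R", 1:5), stent = 1,
                     reconstruction = "K1", criterion = "overall_quality",
                     score = 1:5)
  s2 <- summarize_scores(as_likert_table(tab2), "overall_quality")
  expect_equal(s2$median, 3); expect_equal(s2$q1, 2); expect_equal(s2$q3, 4)
  expect_error(summarize_scores(tab, "nope"), "unknown criterion")
})

test_that("Friedman Q matches the brute-force rank formula on a toy table", {
  y <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2))
  # oracle: rank each block by hand, Q = 12/(bk(k+1)) sum Rj^2 - 3 b (k+1)
  ranks <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2))
  Rj <- colSums(ranks)
  q_oracle <- 12 / (3 * 3 * 4) * sum(Rj^2) - 3 * 3 * 4
  ft <- friedman_from_matrix(y)
  expect_equal(ft$statistic, q_oracle, tolerance = 1e-12)
  expect_equal(ft$statistic, 8 / 3, tolerance = 1e-12)
  expect_equal(ft$df, 2)
  # agreement with the reference implementation (tie-free data)
  ref <- stats::friedman.test(y)
  expect_equal(ft$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ft$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Friedman degenerates correctly and ranks ignore monotone maps", {
  y <- matrix(3, 6, 4)
  ft <- friedman_from_matrix(y)
  expect_equal(ft$statistic, 0); expect_equal(ft$p_value, 1)
  set.seed(8)
  y2 <- matrix(sample(1:5, 40, TRUE), 10, 4)
  f1 <- friedman_from_matrix(y2)
  f2 <- friedman_from_matrix(exp(y2))          # strictly monotone transform
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
  expect_error(friedman_from_matrix(y2[, 1, drop = FALSE]), "two treatments")
})

test_that("rank-sum statistic equals the exact permutation enumeration", {
  m <- null_reader_model(n_readers = 3, n_stents = 1, k = 2)
  tab <- simulate_ratings(m, seed = 1)
  tab$score <- ifelse(tab$reconstruction == "K1", c(1, 2, 3), c(3, 4, 5))
  pw <- suppressWarnings(pairwise_wilcoxon(tab))
  # oracle: Mann-Whitney U (ties count half) and its permutation law over
  # all 20 assignments of the pooled values into two groups of three
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(c(1, 2, 3), c(3, 4, 5))
  expect_equal(pw$statistic, u_obs)
  vals <- c(1, 2, 3, 3, 4, 5)
  u_all <- apply(combn(6, 3), 2, function(ix) u_stat(vals[ix], vals[-ix]))
  expect_equal(u_obs, min(u_all))              # observed split is extreme
  p_exact <- mean(pmin(u_all, 9 - u_all) <= min(u_obs, 9 - u_obs))
  expect_equal(pw$raw_p, p_exact, tolerance = 0.5)  # approx vs exact law
  expect_equal(pw$corrected_p, pmin(1, attr(pw, "m") * pw$raw_p))
})

test_that("Bonferroni correction caps at one and flags degenerate pairs", {
  m2 <- null_reader_model(n_readers = 3, n_stents = 4, k = 2)
  tab2 <- simulate_ratings(m2, seed = 2); tab2$score <- 3L
  expect_warning(pairwise_wilcoxon(tab2), "tied")
  m <- null_reader_model(n_readers = 3, n_stents = 4, k = 4)
  tab <- simulate_ratings(m, seed = 2)
  tab$score <- 3L                              # identical groups
  pw <- suppressWarnings(pairwise_wilcoxon(tab))
  expect_equal(nrow(pw), 6L)
  expect_true(all(pw$corrected_p == 1))
  expect_true(all(pw$degenerate))
  expect_true(all(pw$corrected_p >= pw$raw_p - 1e-15))
})

test_that("Fleiss kappa bands follow the stated thresholds exactly", {
  expect_equal(kappa_band(0.19), "poor")
  expect_equal(kappa_band(0.20), "fair")
  expect_equal(kappa_band(0.28), "fair")
  expect_equal(kappa_band(0.39), "fair")
  expect_equal(kappa_band(0.399), "fair")
  expect_equal(kappa_band(0.40), "moderate")
  expect_equal(kappa_band(0.60), "substantial")
  expect_equal(kappa_band(0.80), "substantial")
  expect_equal(kappa_band(0.81), "perfect")
})

test_that("Fleiss kappa is ~0 for random ratings and relabel-invariant", {
  m <- reader_model(n_readers = 5, n_stents = 200,
                    latent_quality = c(A = 3), noise_sd = 50,
                    criteria = "overall_quality")
  tab <- simulate_ratings(m, seed = 3)        # huge noise: ~uniform scores
  k <- fleiss_kappa(tab)
  expect_lt(abs(k$kappa), 0.05)
  relab <- tab; relab$score <- 6L - relab$score
  expect_equal(fleiss_kappa(relab)$kappa, k$kappa, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA partitions sums of squares correctly", {
  y <- rbind(c(1, 2, 3), c(2, 4, 3), c(5, 6, 10))
  # brute-force partition
  gm <- mean(y)
  ss_t <- 3 * sum((colMeans(y) - gm)^2)
  ss_s <- 3 * sum((rowMeans(y) - gm)^2)
  ss_e <- sum((y - gm)^2) - ss_t - ss_s
  rm <- repeated_measures_anova(y)
  expect_equal(unname(rm$ss["treatment"]), ss_t, tolerance = 1e-12)
  expect_equal(unname(rm$ss["error"]), ss_e, tolerance = 1e-12)
  expect_equal(rm$statistic, (ss_t / 2) / (ss_e / 4), tolerance = 1e-12)
  # cross-check against aov with an Error stratum
  df <- data.frame(v = as.vector(y), s = factor(rep(1:3, 3)),
                   r = factor(rep(1:3, each = 3)))
  a <- summary(stats::aov(v ~ r + Error(s), data = df))
  within <- a[["Error: Within"]][[1]]
  f_ref <- within[["F value"]][1]
  p_ref <- within[["Pr(>F)"]][1]
  expect_equal(rm$statistic, f_ref, tolerance = 1e-10)
  expect_equal(rm$p_value, p_ref, tolerance = 1e-10)
})

test_that("subject offsets alone give a null repeated-measures result", {
  y <- matrix(7, 5, 4) + 1:5                   # per-subject shifts only
  rm <- repeated_measures_anova(y)
  expect_equal(rm$statistic, 0)
  expect_equal(rm$p_value, 1)
  expect_error(repeated_measures_anova(matrix(c(1, 2, NA, 4), 2)),
               "incomplete")
})

test_that("repeated-measures power grows with the kernel effect", {
  pow <- vapply(c(0, 2), function(eff) {
    rej <- vapply(1:40, function(s) {
      set.seed(1000 + s)
      y <- matrix(rnorm(10 * 3), 10, 3) +
        matrix(rep(c(0, eff / 2, eff), each = 10), 10)
      repeated_measures_anova(y)$p_value < 0.05
    }, TRUE)
    mean(rej)
  }, 0)
  expect_lt(pow[1], 0.3)
  expect_gt(pow[2], 0.8)
})
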