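test_that("Levene check matches an ANOVA on absolute deviations", {
  # hand dataset, median centres
  df <- tibble::tibble(
    line_id = rep(c("a", "b", "c"), each = 4),
    pi = c(1, 2, 4, 7, 0, 0.5, 1, 1.5, 10, 20, 30, 40))
  res <- levene_check(df, "pi", "line_id")
  ad <- abs(df$pi - stats::ave(df$pi, df$line_id, FUN = stats::median))
  fit <- stats::anova(stats::lm(ad ~ factor(df$line_id)))
  expect_equal(res$statistic, fit$`F value`[1])
  expect_equal(res$p_value, fit$`Pr(>F)`[1])

  # all groups constant: no dispersion anywhere
  cdf <- tibble::tibble(line_id = rep(c("a", "b"), each = 3),
                        pi = rep(c(2, 5), each = 3))
  res0 <- levene_check(cdf)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # equal spread at large n: comfortably homoskedastic
  set.seed(101)
  big <- tibble::tibble(line_id = rep(c("a", "b"), each = 500),
                        pi = stats::rnorm(1000, rep(c(0, 1), each = 500), 1))
  expect_gt(levene_check(big)$p_value, 0.05)
})

test_that("Kruskal-Wallis and Dunn contrasts match the direct formulas", {
  # tie-free hand dataset
  df <- tibble::tibble(
    line_id = rep(c("empty_split", "lineA", "lineB"), each = 4),
    pi = c(0.1, 0.3, 0.2, 0.4, 0.9, 0.8, 0.7, 0.6, -0.5, -0.3, -0.2, -0.4))
  res <- kruskal_dunn_vs_control(df)
  # H agrees with the stock implementation
  kw <- stats::kruskal.test(pi ~ line_id, data = df)
  expect_equal(attr(res, "kruskal_H"), unname(kw$statistic))
  expect_equal(attr(res, "kruskal_p"), kw$p.value)
  # Dunn z from the textbook formula on pooled ranks (no ties)
  r <- rank(df$pi)
  N <- length(r)
  rb <- tapply(r, df$line_id, mean)
  for (ln in c("lineA", "lineB")) {
    z_direct <- (rb[[ln]] - rb[["empty_split"]]) /
      sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
    expect_equal(res$z[res$line_id == ln], z_direct)
    expect_equal(res$raw_p[res$line_id == ln],
                 2 * stats::pnorm(-abs(z_direct)))
  }

  # a treatment identical to the control: z = 0, p = 1
  df2 <- tibble::tibble(
    line_id = rep(c("empty_split", "same", "far"), each = 3),
    pi = c(1, 2, 3, 1, 2, 3, 10, 11, 12))
  res2 <- kruskal_dunn_vs_control(df2)
  expect_equal(res2$z[res2$line_id == "same"], 0)
  expect_equal(res2$raw_p[res2$line_id == "same"], 1)

  # permuting rows permutes nothing but the order
  df3 <- df[sample(nrow(df)), ]
  res3 <- kruskal_dunn_vs_control(df3)
  expect_equal(res3[order(res3$line_id), ]$raw_p,
               res[order(res$line_id), ]$raw_p)

  expect_error(kruskal_dunn_vs_control(
    tibble::tibble(line_id = rep(c("empty_split", "x"), each = 3),
                   pi = rep(1, 6))), "tied")
})

test_that("Dunn p-values agree with a permutation null on tiny samples", {
  set.seed(102)
  df <- tibble::tibble(line_id = rep(c("empty_split", "t1"), each = 10),
                       pi = stats::rnorm(20))
  obs <- kruskal_dunn_vs_control(df)
  z_obs <- abs(obs$z)
  # permutation distribution of |z| under label exchange
  n_perm <- 2000
  exceed <- 0
  for (i in seq_len(n_perm)) {
    dfp <- df
    dfp$pi <- sample(df$pi)
    zp <- abs(kruskal_dunn_vs_control(dfp)$z)
    if (zp >= z_obs - 1e-12) exceed <- exceed + 1
  }
  p_perm <- exceed / n_perm
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - obs$raw_p), 3 * se + 0.02)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.3), 0.3)
  # monotone on sorted input
  p_sorted <- sort(runif(20))
  expect_false(is.unsorted(adjust_fdr(p_sorted)))
  set.seed(103)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(adjust_fdr(p), oracle_bh(p))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(adjust_bonferroni(c(0.01, 0.2, 0.3, 0.04, 0.5)),
               c(0.05, 1, 1, 0.2, 1))
  expect_equal(adjust_bonferroni(c(0.5, 0.4, 0.3, 0.2)),
               pmin(1, 4 * c(0.5, 0.4, 0.3, 0.2)))
  expect_equal(adjust_bonferroni(0.3), 0.3)
})

test_that("the screen chain flags designed effects and respects the null", {
  scr <- generate_screen_data(n_lines = 10, n_per_group = 12,
                              effects = c(LH0001 = -0.8, LH0002 = 0.6),
                              seed = 104)
  res <- screen_lines(scr)
  expect_true(res$significant[res$line_id == "LH0001"])
  expect_true(res$significant[res$line_id == "LH0002"])
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_identical(res$significant, res$adjusted_p < 0.05)
  g <- glance(res)
  expect_equal(g$n_lines, 10)
  expect_gte(g$n_significant, 2)

  # Bonferroni path is at least as conservative
  resb <- screen_lines(scr, adjust = "bonferroni")
  expect_true(all(resb$adjusted_p >= res$adjusted_p - 1e-12))

  # under the global null, BH at the 10% level rarely flags lines
  fracs <- vapply(1:40, function(i) {
    null_scr <- generate_screen_data(n_lines = 20, n_per_group = 8,
                                     seed = 2000 + i)
    r <- kruskal_dunn_vs_control(null_scr)
    mean(adjust_fdr(r$raw_p) < 0.10)
  }, numeric(1))
  n_tot <- 40 * 20
  expect_lte(mean(fracs), 0.10 + 3 * sqrt(0.1 * 0.9 / n_tot))
})
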