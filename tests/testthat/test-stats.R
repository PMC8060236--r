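test_that("pooled t-test matches the textbook formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 4, 5, 6, 7)
  res <- t_test(x, y)
  orc <- oracle_pooled_t(x, y)
  expect_equal(res$statistic, -2)
  expect_equal(res$df, 8)
  expect_equal(res$statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  # random small samples against the moment oracle
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = 0.5)
    r <- t_test(a, b)
    o <- oracle_pooled_t(a, b)
    expect_equal(r$statistic, o$t, tolerance = 1e-9)
    expect_equal(r$p_value, o$p, tolerance = 1e-9)
  }
})

test_that("degenerate t-tests are flagged, not fatal", {
  x <- c(1, 2, 3, 4)
  r <- t_test(x, x, paired = TRUE)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  # constant non-zero difference: zero variance of differences, flagged
  r2 <- t_test(x, x + 1, paired = TRUE)
  expect_true(r2$degenerate)
  # two constant unpaired samples
  r3 <- t_test(rep(2, 4), rep(2, 5))
  expect_true(r3$degenerate)
  expect_error(t_test(1, c(1, 2)), "n >= 2")
  expect_error(t_test(c(1, 2, 3), c(1, 2), paired = TRUE), "equal-length")
})

test_that("one-way ANOVA matches hand computation and flags degeneracy", {
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 27, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  orc <- oracle_anova_F(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, orc$F, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  deg <- one_way_anova(list(rep(4, 3), rep(4, 3), rep(4, 3)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "n >= 2")
})

test_that("F equals t squared on two groups", {
  set.seed(9)
  for (i in 1:30) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.3)
    tt <- t_test(a, b)
    av <- one_way_anova(list(a, b))
    expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-9)
    expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches the moment oracle", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$statistic, 1)
  expect_equal(pearson_r(1:5, -(1:5))$statistic, -1)
  r <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$statistic, 0.8, tolerance = 1e-12)
  expect_equal(r$statistic, oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("ICC(2,1) behaves at the agreement limits", {
  set.seed(21)
  base <- rnorm(20, sd = 10)
  perfect <- icc(cbind(base, base))
  expect_equal(perfect$icc, 1, tolerance = 1e-9)
  noisy <- icc(cbind(base, rnorm(20, sd = 200)))
  expect_lt(noisy$icc, 0.2)
  expect_error(icc(cbind(base[1:4], base[1:4])), "5 subjects")
  expect_error(icc(matrix(base, ncol = 1)), "2 raters")
  mm <- cbind(base, base); mm[3, 2] <- NA
  expect_error(icc(mm), "missing")
})

test_that("ICC(2,1) recovers the analytic reliability of a two-way model", {
  set.seed(33)
  n <- 200; k <- 3
  s2_subj <- 25; s2_rater <- 1; s2_err <- 4
  subj <- rnorm(n, sd = sqrt(s2_subj))
  rater <- rnorm(k, sd = sqrt(s2_rater))
  y <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
    matrix(rnorm(n * k, sd = sqrt(s2_err)), n, k)
  target <- s2_subj / (s2_subj + s2_rater + s2_err)
  res <- icc(y)
  expect_lt(abs(res$icc - target), 0.05)
  expect_true(res$ci[1] < res$icc && res$icc < res$ci[2])
})

test_that("high-agreement raters reproduce the reported reliability regime", {
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    truth <- rnorm(20, mean = 100, sd = 10)
    ratings <- cbind(truth + rnorm(20, sd = 1), truth + rnorm(20, sd = 1))
    icc(ratings)$icc > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group summaries use t-test for 2 groups, ANOVA for more", {
  df <- data.frame(stent_type = rep(c("A", "B", "C"), each = 5),
                   m = c(rnorm(5, 1), rnorm(5, 2), rnorm(5, 3)))
  sg <- summarize_groups(df, "m", "stent_type")
  expect_equal(nrow(sg), 3L)
  expect_equal(attr(sg, "test"), "one-way ANOVA")
  df2 <- df[df$stent_type != "C", ]
  sg2 <- summarize_groups(df2, "m", "stent_type")
  tt <- t_test(df2$m[df2$stent_type == "A"], df2$m[df2$stent_type == "B"])
  expect_equal(attr(sg2, "p_value"), tt$p_value, tolerance = 1e-12)
  # degenerate constants: p reported as 1 with the zero-variance flag
  df3 <- data.frame(g = rep(c("A", "B"), each = 3), m = rep(7, 6))
  sg3 <- summarize_groups(df3, "m", "g")
  expect_equal(attr(sg3, "p_value"), 1)
  expect_true(attr(sg3, "degenerate"))
  expect_true(all(sg3$sd == 0))
})

test_that("significance stars follow the table legend", {
  expect_equal(stentgeom:::p_stars(0.04), "*")
  expect_equal(stentgeom:::p_stars(0.004), "***")
  expect_equal(stentgeom:::p_stars(0.5), "")
  expect_equal(stentgeom:::p_stars(0.005), "**")
})
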