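test_that("Bland-Altman handles exact and shifted agreement", {
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  expect_equal(ba0$rmse, 0)
  expect_equal(ba0$pearson_r, 1)

  ba <- bland_altman(a + 0.5, a)
  expect_equal(ba$bias, 0.5)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0.5, 0.5))
})

test_that("differences {-1, 0, 1} give bias 0 and LoA at -/+1.96", {
  b <- c(5, 6, 7)
  ba <- bland_altman(b + c(-1, 0, 1), b)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
})

test_that("Bland-Altman validates lengths, sizes, and percent-mode zeros", {
  expect_error(bland_altman(1:3, 1:4), class = "rhbreath_config_error")
  expect_error(bland_altman(1, 2), class = "rhbreath_config_error")
  expect_error(bland_altman(c(1, -1), c(-1, 1), mode = "percent"), "pair 1",
               class = "rhbreath_config_error")
  pc <- bland_altman(c(11, 22), c(9, 18), mode = "percent")
  expect_equal(pc$diffs, c(20, 20))
})

test_that("per-subject normalization rescales each subject to unit level", {
  a <- c(10, 12, 100, 120); b <- c(10, 10, 100, 100)
  subj <- c(1, 1, 2, 2)
  ba <- bland_altman(a, b, normalize = "per_subject_mean", subject = subj)
  # after normalization both subjects contribute comparably scaled diffs
  expect_lt(max(abs(ba$diffs)), 0.2)
  expect_error(bland_altman(a, b, normalize = "per_subject_mean"),
               class = "rhbreath_config_error")
})

test_that("log and mixed LoA modes keep the bias between the limits", {
  withr::with_seed(21, {
    subj <- rep(1:5, each = 12)
    b <- runif(60, 0.4, 0.8)
    a <- b * exp(rnorm(60, 0.02, 0.1)) + rep(rnorm(5, 0, 0.02), each = 12)
    for (mode in c("normal", "log", "mixed")) {
      ba <- bland_altman(a, b, subject = subj, loa = mode)
      expect_lte(ba$loa_lower, ba$bias)
      expect_lte(ba$bias, ba$loa_upper)
    }
    lg <- bland_altman(a, b, loa = "log")
    # log-scale limits are asymmetric around the back-transformed bias
    expect_false(isTRUE(all.equal(lg$bias - lg$loa_lower,
                                  lg$loa_upper - lg$bias)))
  })
})

test_that("normal-theory LoA cover at least 93% of large normal samples", {
  withr::with_seed(7, {
    d <- rnorm(2000, 0.3, 1.2)
    ba <- bland_altman(d + 10, rep(10, 2000))
    coverage <- mean(ba$diffs >= ba$loa_lower & ba$diffs <= ba$loa_upper)
    expect_gte(coverage, 0.93)
  })
})

test_that("one-way ANOVA reproduces the hand-computed two-group case", {
  tab <- one_way_anova(list(c(0, 1), c(2, 3)))
  expect_equal(tab$ss[tab$source == "between"], 4)
  expect_equal(tab$ss[tab$source == "within"], 1)
  expect_equal(tab$f[1], 8)
  expect_equal(tab$p[1], 0.1055728, tolerance = 1e-6)
  expect_equal(tab$df, c(1, 2, 3))
})

test_that("identical groups give F = 0 and P = 1", {
  tab <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(tab$ss[1], 0)
  expect_equal(tab$f[1], 0)
  expect_equal(tab$p[1], 1)
})

test_that("degenerate zero-within-variance groups are flagged with P = 0", {
  tab <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(tab$p[1], 0)
  expect_true(attr(tab, "degenerate"))
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  withr::with_seed(5, {
    for (i in 1:5) {
      g1 <- rnorm(8, 10, 2); g2 <- rnorm(11, 11, 2)
      tab <- one_way_anova(list(g1, g2))
      tt <- t.test(g1, g2, var.equal = TRUE)
      expect_equal(tab$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(tab$p[1], tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the sum-of-squares decomposition is exact", {
  withr::with_seed(8, {
    groups <- list(rnorm(10), rnorm(15, 0.5), rnorm(7, -0.3))
    tab <- one_way_anova(groups)
    all_v <- unlist(groups)
    expect_equal(tab$ss[3], sum((all_v - mean(all_v))^2), tolerance = 1e-9)
    expect_equal(tab$ss[3], tab$ss[1] + tab$ss[2], tolerance = 1e-9)
  })
})

test_that("ANOVA accepts a value/group data frame and rejects bad input", {
  df <- data.frame(value = c(0, 1, 2, 3), group = c("a", "a", "b", "b"))
  expect_equal(one_way_anova(df)$f[1], 8)
  expect_error(one_way_anova(list(1:3)), class = "rhbreath_config_error")
  expect_error(one_way_anova(list(1, 2)), class = "rhbreath_config_error")
})

test_that("a printed summary decomposition reproduces its mean squares and P", {
  tab <- anova_from_summary(0.002, 1, 39.09, 346)
  expect_equal(round(tab$ms[2], 2), 0.11)
  expect_equal(round(tab$p[1], 2), 0.89)
  expect_equal(tab$ss[3], 39.092)
  expect_equal(tab$df[3], 347)

  expect_equal(anova_from_summary(0, 1, 5, 10)$p[1], 1)
  expect_error(anova_from_summary(1, 0, 5, 10),
               class = "rhbreath_config_error")
})

test_that("summary-table reconstruction is self-consistent with the full ANOVA", {
  withr::with_seed(13, {
    tab <- one_way_anova(list(rnorm(20), rnorm(20, 0.4)))
    re <- anova_from_summary(tab$ss[1], tab$df[1], tab$ss[2], tab$df[2])
    expect_equal(re$f[1], tab$f[1], tolerance = 1e-12)
    expect_equal(re$p[1], tab$p[1], tolerance = 1e-12)
  })
})

test_that("RMSE and correlation cover the canonical cases", {
  expect_equal(rmse_and_correlation(1:5, 1:5),
               tibble::tibble(rmse = 0, pearson_r = 1))
  expect_equal(rmse_and_correlation(c(1, 2, 3), c(-1, -2, -3))$pearson_r, -1)
  expect_equal(rmse_and_correlation(c(1, 2, 3), c(2, 2, 4))$rmse,
               sqrt(2 / 3))
  expect_warning(out <- rmse_and_correlation(c(2, 2, 2), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(out$pearson_r))
  expect_equal(out$rmse, sqrt(2 / 3))
  expect_error(rmse_and_correlation(1:3, 1:2), class = "rhbreath_config_error")
})

test_that("box summaries use type-7 quartiles and 1.5 IQR fences", {
  b <- box_summary(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$n_outliers, 0)
  expect_equal(c(b$whisker_low, b$whisker_high), c(1, 5))

  one <- box_summary(7)
  expect_true(all(unlist(one[c("median", "q1", "q3", "whisker_low",
                               "whisker_high")]) == 7))

  out <- box_summary(c(1, 2, 3, 100))
  expect_equal(out$outliers[[1]], 100)
  expect_lte(out$whisker_high, 3)
  expect_error(box_summary(numeric()), class = "rhbreath_config_error")
})

test_that("tidy and glance expose agreement results as tibbles", {
  ba <- bland_altman(c(1, 2, 3), c(1.1, 2.2, 2.9))
  expect_equal(names(tidy(ba)), c("mean", "diff"))
  g <- glance(ba)
  expect_equal(g$bias, ba$bias)
  tab <- one_way_anova(list(c(0, 1), c(2, 3)))
  expect_equal(glance(tab)$f, 8)
  expect_s3_class(tidy(tab), "tbl_df")
})

test_that("autoplot builds Bland-Altman and comparison figures", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1.2, 1.9, 3.3, 3.8))
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
  bx <- plot_box_comparison(tibble::tibble(rhs = rnorm(10), pnt = rnorm(10)))
  expect_s3_class(bx, "ggplot")
})
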