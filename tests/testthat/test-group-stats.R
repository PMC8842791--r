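test_that("summary-statistic t-test matches closed-form worked examples", {
  # pooled Student on the gammaH2AX positive:negative summaries
  r <- t_from_summary(group_summary(0.36, 0.13, 8),
                      group_summary(0.22, 0.09, 8), "student")
  expect_equal(r$statistic, 2.504396, tolerance = 1e-6)
  expect_equal(r$df, 14)
  expect_equal(r$p, 0.02525125, tolerance = 1e-6)
  # Welch on the cardia/BE ratio summaries
  w <- t_from_summary(group_summary(0.87, 0.23, 8),
                      group_summary(0.45, 0.18, 5), "welch")
  expect_equal(w$statistic, 3.670608, tolerance = 1e-6)
  expect_equal(w$df, 10.23728, tolerance = 1e-5)
  expect_equal(w$p, 0.004147926, tolerance = 1e-6)
  # identical groups
  same <- t_from_summary(c(1, 0.5, 5), c(1, 0.5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("degenerate zero-variance summaries follow the stated conventions", {
  expect_message(eq <- t_from_summary(c(2, 0, 4), c(2, 0, 4)), "zero")
  expect_equal(eq$p, 1)
  expect_message(ne <- t_from_summary(c(2, 0, 4), c(3, 0, 4)), "zero")
  expect_equal(ne$p, 0)
})

test_that("raw-data t-test equals its own summary form and the stats oracle", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(sample(3:12, 1), 1, 2)
    y <- rnorm(sample(3:12, 1), 0.2, 1)
    for (variant in c("student", "welch")) {
      a <- t_unpaired(x, y, variant)
      b <- t_from_summary(summarize_group(x), summarize_group(y), variant)
      expect_identical(a$statistic, b$statistic)
      expect_identical(a$p, b$p)
      o <- stats::t.test(x, y, var.equal = (variant == "student"))
      expect_equal(a$statistic, unname(o$statistic), tolerance = 1e-12)
      expect_equal(a$df, unname(o$parameter), tolerance = 1e-12)
      expect_equal(a$p, o$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Welch df never exceeds the pooled df", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = 3)
    w <- t_unpaired(x, y, "welch")
    expect_lte(w$df, length(x) + length(y) - 2)
  }
})

test_that("paired t-test matches hand computation and is order-invariant", {
  u <- c(1, 2, 3); v <- c(2, 3, 5)
  r <- t_paired(u, v)
  expect_equal(abs(r$statistic), 4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.05719096, tolerance = 1e-6)
  o <- stats::t.test(u, v, paired = TRUE)
  expect_equal(r$p, o$p.value, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  r2 <- t_paired(u[perm], v[perm])
  expect_equal(r2$statistic, r$statistic)
  # equal pairs; incomplete pairs dropped with a message
  expect_equal(t_paired(u, u)$p, 1)
  expect_message(r3 <- t_paired(c(u, NA), c(v, 1)), "1 incomplete")
  expect_equal(r3$p, r$p)
  expect_error(t_paired(1, 2), "pairs")
})

test_that("one-way ANOVA reduces to the pooled t-test for two groups", {
  set.seed(13)
  x <- rnorm(8); y <- rnorm(6, 1)
  a <- anova_oneway(list(x, y))
  t2 <- t_unpaired(x, y, "student")
  expect_equal(a$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(a$p, t2$p, tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  a0 <- anova_oneway(g)
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p, 1)
  expect_error(anova_oneway(list(c(1, 2), c(3))), "n >= 2")
})

test_that("Tukey HSD matches the studentized-range distribution", {
  # k = 2: adjusted p equals the pooled t-test p (q = t * sqrt(2))
  set.seed(17)
  x <- rnorm(7); y <- rnorm(9, 0.8)
  tk <- tukey_hsd(list(a = x, b = y))
  tt <- t_unpaired(x, y, "student")
  expect_equal(tk$p, tt$p, tolerance = 1e-8)
  expect_equal(tk$statistic, abs(tt$statistic) * sqrt(2), tolerance = 1e-9)
  # identical groups: all adjusted p = 1
  same <- tukey_hsd(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_true(all(same$p == 1))
  # k = 3 balanced: agrees with the independent stats::TukeyHSD /
  # stats::ptukey implementation (accurate to ~1e-4) to 3 decimals
  g <- list(a = c(2.1, 2.9, 3.4, 2.5), b = c(3.8, 4.1, 3.3, 4.4),
            c = c(5.0, 4.2, 4.8, 5.5))
  tk3 <- tukey_hsd(g)
  vals <- unlist(g); fac <- factor(rep(names(g), each = 4))
  ref <- stats::TukeyHSD(stats::aov(vals ~ fac))$fac
  expect_lt(max(abs(sort(tk3$p) - sort(unname(ref[, "p adj"])))), 5e-4)
  # adjusted p never falls below the unadjusted p of the same MSE-based
  # statistic (t = q / sqrt(2) on the error df)
  for (j in seq_len(nrow(tk3))) {
    pair_p <- 2 * stats::pt(-tk3$statistic[j] / sqrt(2), tk3$df2[j])
    expect_gte(tk3$p[j] + 1e-9, pair_p)
  }
})

test_that("pooled summaries equal the summary of the concatenated sample", {
  # construct raw samples with exactly the printed dysplasia summaries
  make_sample <- function(m, s, n) {
    z <- scale(rnorm(n))[, 1]
    m + s * z
  }
  set.seed(23)
  x <- make_sample(2.67, 1.00, 9)
  y <- make_sample(2.25, 1.04, 8)
  pooled <- pooled_group_summary(list(summarize_group(x), summarize_group(y)))
  expect_equal(pooled$mean, mean(c(x, y)), tolerance = 1e-10)
  expect_equal(pooled$sd, sd(c(x, y)), tolerance = 1e-10)
  expect_equal(pooled$n, 17L)
  # single part unchanged
  one <- pooled_group_summary(list(group_summary(1.5, 0.2, 5)))
  expect_equal(one$mean, 1.5)
  # equal means: combined variance is the weighted within-variance
  p <- pooled_group_summary(list(group_summary(3, 1, 5),
                                 group_summary(3, 2, 7)))
  expect_equal(p$sd^2, (4 * 1 + 6 * 4) / 11)
})

test_that("count ratios and organoid normalization follow their contracts", {
  expect_equal(positive_ratio(36, 100), 0.36)
  expect_equal(positive_ratio(0, 10), 0)
  expect_equal(positive_ratio(7, 7), 1)
  expect_error(positive_ratio(3, 0), "n_negative")
  expect_equal(organoid_norm(50, 75), 150)
  expect_equal(organoid_norm(100, 100), 100)
  expect_equal(organoid_norm(20, 10), 50)
  expect_error(organoid_norm(0, 10), "start_count")
})

test_that("tests are invariant to affine transformation of the data", {
  set.seed(29)
  x <- rnorm(6); y <- rnorm(7, 1); z <- rnorm(5, 2)
  tr <- function(v) 3.2 * v - 1.7
  a1 <- t_unpaired(x, y, "welch"); a2 <- t_unpaired(tr(x), tr(y), "welch")
  expect_equal(a1$p, a2$p, tolerance = 1e-12)
  b1 <- anova_oneway(list(x, y, z))
  b2 <- anova_oneway(list(tr(x), tr(y), tr(z)))
  expect_equal(b1$p, b2$p, tolerance = 1e-12)
  c1 <- tukey_hsd(list(x, y, z)); c2 <- tukey_hsd(list(tr(x), tr(y), tr(z)))
  expect_equal(c1$p, c2$p, tolerance = 1e-10)
})
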