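test_that("bootstrap of a constant sample is degenerate at the constant", {
  b <- bootstrap_parameter(rep(3.5, 20), "mean", n_boot = 200, seed = 1)
  expect_equal(b$estimate, 3.5)
  expect_equal(unique(b$replicates), 3.5)
  expect_equal(c(b$ci_lower, b$ci_upper), c(3.5, 3.5))
})

test_that("bootstrap is seed-reproducible and centred on the sample statistic", {
  x <- c(1.2, 5.4, 2.2, 9.1, 3.3, 7.7, 0.4, 4.8)
  b1 <- bootstrap_parameter(x, "mean", n_boot = 4000, seed = 42)
  b2 <- bootstrap_parameter(x, "mean", n_boot = 4000, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(b1$estimate, mean(x))
  # E[resample mean] = sample mean; Monte Carlo error ~ sd/sqrt(n * n_boot)
  se <- sd(x) / sqrt(length(x)) / sqrt(4000)
  expect_lt(abs(mean(b1$replicates) - mean(x)), 5 * se)
  expect_lte(b1$ci_lower, b1$estimate)
  expect_gte(b1$ci_upper, b1$estimate)
  # explicit replicate size
  b3 <- bootstrap_parameter(x, "median", n_boot = 50, replicate_size = 3,
                            seed = 7)
  expect_equal(b3$replicate_size, 3)
  expect_true(all(b3$replicates %in% x))
  expect_error(bootstrap_parameter(numeric(0)), "non-empty")
})

test_that("bootstrap replicate distribution matches exhaustive enumeration", {
  # n = 5 values: all 5^5 = 3125 equally likely resamples enumerated exactly
  x <- c(0, 1, 3, 7, 20)
  idx <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  exact_means <- sort(rowMeans(matrix(x[idx], ncol = 5)))
  b <- bootstrap_parameter(x, "mean", n_boot = 50000, seed = 99)
  # Kolmogorov-Smirnov distance between the empirical replicate CDF and the
  # exact resampling CDF, evaluated on the exact support
  sup <- unique(exact_means)
  F_exact <- ecdf(exact_means)(sup)
  F_emp <- ecdf(b$replicates)(sup)
  expect_lt(max(abs(F_exact - F_emp)), 0.015)
})

test_that("Kruskal-Wallis path matches the direct rank formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  h <- kw_h_oracle(g)
  expect_equal(h, 7.2)
  kt <- kruskal.test(unlist(g), factor(rep(1:3, each = 3)))
  expect_equal(unname(kt$statistic), h, tolerance = 1e-12)
})

test_that("Dunn z statistics follow the rank-sum formula and Bonferroni scaling", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_test(v, g)
  expect_equal(nrow(d), 3)
  # no ties: se = sqrt(N(N+1)/12 * (1/n1 + 1/n2)), mean ranks 2, 5, 8
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], (2 - 8) / se,
               tolerance = 1e-12)
  expect_equal(d$p_adjusted, pmin(1, d$p_value * 3))
  # adjusted p never below raw p
  expect_true(all(d$p_adjusted >= d$p_value))
})

test_that("Dunn tie correction reduces the standard error term", {
  # heavy ties: correction = sum(t^3 - t) / (12 (N - 1)) enters the SE
  v <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  g <- rep(c("a", "b", "c"), times = 3)
  d <- dunn_test(v, g)
  n <- 9
  tie_corr <- 3 * (27 - 3) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - tie_corr) * (2 / 3))
  # groups are identical up to permutation -> equal mean ranks, z = 0
  expect_equal(d$z, rep(0, 3))
  # perturb one value to get a nonzero z and check the SE scale
  v2 <- c(1, 1, 1, 2, 2, 2, 3, 3, 10)
  d2 <- dunn_test(v2, g)
  expect_true(all(is.finite(d2$z)))
})

test_that("identical two-group data gives t = 0, p = 1", {
  df <- data.frame(value = rep(c(1, 2, 3, 4, 5), 2),
                   group = rep(c("a", "b"), each = 5))
  cg <- compare_groups(df, design = "two_group")
  expect_equal(cg$statistic, 0, tolerance = 1e-12)
  expect_equal(cg$p_value, 1, tolerance = 1e-12)
  expect_match(cg$test, "student t")
})

test_that("the decision tree routes skewed data to Kruskal-Wallis plus Dunn", {
  set.seed(12)
  df <- data.frame(value = rexp(60)^2,
                   group = rep(c("a", "b", "c"), each = 20))
  cg <- compare_groups(df, design = "one_way")
  expect_equal(cg$test, "kruskal-wallis")
  kt <- kruskal.test(df$value, factor(df$group))
  expect_equal(unname(cg$statistic), unname(kt$statistic), tolerance = 1e-12)
  expect_false(is.null(cg$posthoc))
  expect_equal(nrow(cg$posthoc), 3)
})

test_that("the decision tree routes normal data to one-way ANOVA", {
  set.seed(13)
  df <- data.frame(value = rnorm(30), group = rep(c("a", "b", "c"), each = 10))
  cg <- compare_groups(df, design = "one_way")
  expect_equal(cg$test, "one-way anova")
  fit <- summary(aov(value ~ factor(group), data = df))[[1]]
  expect_equal(cg$statistic, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(cg$p_value, fit$`Pr(>F)`[1], tolerance = 1e-12)
  expect_null(cg$posthoc)
})

test_that("two-way design reports main effects and interaction", {
  set.seed(14)
  df <- expand.grid(group = c("wt", "mut"), treatment = c("veh", "drug"),
                    rep = 1:8)
  df$value <- rnorm(nrow(df)) + 3 * (df$group == "mut") +
    2 * (df$group == "mut" & df$treatment == "drug")
  cg <- compare_groups(df, design = "two_way", treatment = "treatment")
  expect_equal(length(cg$p_value), 3)
  expect_named(cg$p_value, c("group", "treatment", "group:treatment"))
  expect_lt(cg$p_value[["group"]], 0.01)
  expect_lt(cg$p_value[["group:treatment"]], 0.05)
  expect_error(compare_groups(df, design = "two_way"), "treatment")
})

test_that("type-I error of the one-way route is calibrated near alpha", {
  set.seed(15)
  rej <- vapply(1:200, function(i) {
    df <- data.frame(value = rnorm(24), group = rep(c("a", "b", "c"), each = 8))
    compare_groups(df, design = "one_way")$p_value[1] < 0.05
  }, logical(1))
  # binomial 99% band around 0.05 at 200 sims
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})

test_that("comparisons are invariant to row order", {
  set.seed(16)
  df <- data.frame(value = rexp(45), group = rep(c("a", "b", "c"), each = 15))
  shuf <- df[sample.int(nrow(df)), ]
  c1 <- compare_groups(df, design = "one_way")
  c2 <- compare_groups(shuf, design = "one_way")
  expect_equal(c1$statistic, c2$statistic, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  if (!is.null(c1$posthoc)) {
    expect_equal(c1$posthoc$z, c2$posthoc$z, tolerance = 1e-12)
  }
})

test_that("groups smaller than 3 are rejected", {
  df <- data.frame(value = c(1, 2, 3, 4, 5), group = c("a", "a", "a", "b", "b"))
  expect_error(compare_groups(df, design = "two_group"), "n >= 3")
})

test_that("rose histogram bins are left-closed, equal width and exhaustive", {
  a <- c(0, 22.4, 22.5, 45, 180, 359.999)
  r <- rose_histogram(a, n_bins = 16)
  expect_equal(nrow(r), 16)
  expect_equal(r$start_deg, seq(0, 337.5, by = 22.5))
  # 0 and 22.4 in bin 1; 22.5 and 45-eps boundary: 22.5 -> bin 2, 45 -> bin 3
  expect_equal(r$count[1], 2L)
  expect_equal(r$count[2], 1L)
  expect_equal(r$count[3], 1L)
  expect_equal(r$count[16], 1L)
  expect_equal(sum(r$count), length(a))
  expect_error(rose_histogram(c(10, 360)))
  expect_error(rose_histogram(c(-1, 10)))
})

test_that("raincloud box table matches type-7 quantile and Tukey oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 100)   # one high outlier
  df <- data.frame(value = x, group = "a")
  rs <- raincloud_summary(df)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  expect_equal(rs$box$q1, q[1])
  expect_equal(rs$box$median, q[2])
  expect_equal(rs$box$q3, q[3])
  iqr <- q[3] - q[1]
  expect_equal(rs$box$whisker_low, min(x[x >= q[1] - 1.5 * iqr]))
  expect_equal(rs$box$whisker_high, max(x[x <= q[3] + 1.5 * iqr]))
  expect_lt(rs$box$whisker_high, 100)   # outlier excluded from the whisker
  expect_equal(rs$box$mean, mean(x))
  # density integrates to ~1 over its grid
  d <- rs$density
  expect_equal(sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2),
               1, tolerance = 0.01)
})

test_that("raincloud handles degenerate single-value groups", {
  df <- data.frame(value = c(2, 2, 2, 1, 3, 5), group = rep(c("a", "b"), each = 3))
  rs <- raincloud_summary(df)
  expect_equal(nrow(rs$box), 2)
  expect_equal(rs$box$median[rs$box$group == "a"], 2)
  da <- rs$density[rs$density$group == "a", ]
  expect_equal(nrow(da), 1)   # constant group collapses to a point mass
})
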