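#' Bootstrap a location parameter
#'
#' Draws `n_boot` resamples with replacement of size `replicate_size`
#' (default: the original sample size) and computes the chosen statistic per
#' replicate; the percentile interval spans the 2.5 and 97.5 centiles
#' (type-7 quantiles). Fixed seed gives bit-reproducible output.
#'
#' @param values Non-empty numeric vector.
#' @param stat `"mean"` or `"median"`.
#' @param n_boot Number of replicates (default 1000).
#' @param replicate_size Resample size, or `"same"` for the original n.
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return A `boot_result` list: `estimate` (statistic on the original
#'   data), `replicates`, `ci_lower`, `ci_upper`, `n_boot`, `stat`, `seed`.
#' @export
bootstrap_parameter <- function(values, stat = c("mean", "median"),
                                n_boot = 1000, replicate_size = "same",
                                seed = NULL, conf = 0.95) {
  stat <- match.arg(stat)
  if (length(values) == 0) abort("`values` must be non-empty")
  stopifnot(all(is.finite(values)))
  n_boot <- assert_count(n_boot, "n_boot")
  m <- if (identical(replicate_size, "same")) length(values)
       else assert_count(replicate_size, "replicate_size")
  statfun <- switch(stat, mean = mean, median = median)
  reps <- with_seed_or_stream(seed, {
    idx <- matrix(sample.int(length(values), m * n_boot, replace = TRUE),
                  m, n_boot)
    draws <- matrix(values[idx], m, n_boot)
    if (stat == "mean") .colMeans(draws, m, n_boot)
    else apply(draws, 2, median)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(list(estimate = statfun(values), replicates = reps,
                 ci_lower = ci[1], ci_upper = ci[2], n_boot = n_boot,
                 replicate_size = m, stat = stat, conf = conf, seed = seed),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("<boot_result> %s = %.5g, %g%% percentile CI [%.5g, %.5g] (%d replicates of %d)\n",
              x$stat, x$estimate, 100 * x$conf, x$ci_lower, x$ci_upper,
              x$n_boot, x$replicate_size))
  invisible(x)
}

#' Dunn's rank-based post-hoc test
#'
#' All-pairs z tests on mean ranks after a Kruskal-Wallis comparison, with
#' tie correction, and Bonferroni adjustment by default.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param p_adjust Adjustment method (default `"bonferroni"`).
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- pmin(1, p.adjust(out$p_value, method = p_adjust))
  out
}

#' Compare grouped measurements with the protocol's decision tree
#'
#' Normality is checked per group (Shapiro-Wilk for n < `normality_n_cutoff`,
#' otherwise a Kolmogorov-Smirnov test against a normal with the sample's
#' moments). Designs: `two_group` uses an unpaired two-tailed Student's t
#' test; `one_way` uses ordinary one-way ANOVA when all groups pass
#' normality, otherwise Kruskal-Wallis followed by Dunn's test with
#' Bonferroni correction; `two_way` fits a two-way ANOVA with interaction on
#' `group` and `treatment` (e.g. a genotype-by-drug layout).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor.
#' @param design `"two_group"`, `"one_way"` or `"two_way"`.
#' @param treatment Second factor column for the two-way design.
#' @param alpha Normality-test significance level.
#' @param normality_n_cutoff Group size at which the normality test switches
#'   from Shapiro-Wilk to Kolmogorov-Smirnov (default 50).
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           design = c("one_way", "two_group", "two_way"),
                           treatment = NULL, alpha = 0.05,
                           normality_n_cutoff = 50) {
  design <- match.arg(design)
  v <- data[[value]]; g <- as.factor(data[[group]])
  if (is.null(v) || is.null(g)) abort("`value`/`group` columns not found")
  stopifnot(all(is.finite(v)))
  k <- nlevels(g)
  if (k < 2) abort("need >= 2 groups")
  if (design == "two_group" && k != 2) abort("two_group design needs exactly 2 groups")
  if (design == "two_way") {
    if (is.null(treatment)) abort("`treatment` required for two_way design")
    tr <- as.factor(data[[treatment]])
  }
  ns <- tapply(v, g, length)
  if (any(ns < 3)) abort("every group needs n >= 3 for normality testing")
  normality <- purrr::map(levels(g), function(l) {
    xs <- v[g == l]
    if (length(xs) < normality_n_cutoff) {
      tst <- shapiro.test(xs)
      meth <- "shapiro-wilk"
    } else {
      tst <- suppressWarnings(ks.test(xs, "pnorm", mean(xs), sd(xs)))
      meth <- "kolmogorov-smirnov"
    }
    tibble::tibble(group = l, n = length(xs), method = meth,
                   p_value = tst$p.value, normal = tst$p.value >= alpha)
  }) |> dplyr::bind_rows()
  all_normal <- all(normality$normal)
  posthoc <- NULL
  if (design == "two_group") {
    tst <- t.test(v ~ g, var.equal = TRUE)
    test_name <- "student t (unpaired, two-tailed)"
    statistic <- unname(tst$statistic); p <- tst$p.value
  } else if (design == "one_way") {
    if (all_normal) {
      fit <- aov(v ~ g)
      an <- summary(fit)[[1]]
      test_name <- "one-way anova"
      statistic <- an$`F value`[1]; p <- an$`Pr(>F)`[1]
    } else {
      tst <- kruskal.test(v, g)
      test_name <- "kruskal-wallis"
      statistic <- unname(tst$statistic); p <- tst$p.value
      posthoc <- dunn_test(v, g, p_adjust = "bonferroni")
    }
  } else {
    fit <- aov(v ~ g * tr)
    an <- summary(fit)[[1]]
    test_name <- "two-way anova"
    statistic <- an$`F value`[seq_len(3)]
    p <- an$`Pr(>F)`[seq_len(3)]
    names(statistic) <- names(p) <- c(group, treatment,
                                      paste(group, treatment, sep = ":"))
  }
  structure(list(test = test_name, statistic = statistic, p_value = p,
                 posthoc = posthoc, normality = normality, design = design,
                 alpha = alpha, groups = levels(g)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %s, p %s\n", x$test,
              paste(signif(x$statistic, 5), collapse = "/"),
              paste(signif(x$p_value, 4), collapse = "/")))
  if (!is.null(x$posthoc)) {
    cat("post hoc (dunn + bonferroni):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Circular histogram (rose-plot bins) of displacement angles
#'
#' Equal-width, left-closed bins starting at 0 degrees.
#'
#' @param angles Angles in degrees, in \[0, 360).
#' @param n_bins Number of bins (>= 2), default 16.
#' @return Tibble: `bin`, `start_deg`, `end_deg`, `count`.
#' @export
rose_histogram <- function(angles, n_bins = 16) {
  n_bins <- assert_count(n_bins, "n_bins", lower = 2)
  stopifnot(all(angles >= 0 & angles < 360))
  width <- 360 / n_bins
  bin <- pmin(floor(angles / width), n_bins - 1) + 1
  counts <- tabulate(bin, nbins = n_bins)
  tibble::tibble(bin = seq_len(n_bins),
                 start_deg = (seq_len(n_bins) - 1) * width,
                 end_deg = seq_len(n_bins) * width,
                 count = counts)
}

#' Raincloud summary tables
#'
#' Deterministic per-group tables sufficient to re-draw a raincloud plot:
#' quartiles (type-7), Tukey whiskers, mean and n (`box`), and a Gaussian
#' KDE with Silverman's bandwidth sampled on a regular grid (`density`).
#'
#' @param data A data frame.
#' @param value,group Column names (strings).
#' @param n_grid Number of density grid points per group.
#' @return A `raincloud_summary` list of tibbles `box` and `density`.
#' @export
raincloud_summary <- function(data, value = "value", group = "group",
                              n_grid = 128) {
  v <- data[[value]]; g <- as.factor(data[[group]])
  stopifnot(!is.null(v), !is.null(g), all(tapply(v, g, length) >= 1))
  box <- purrr::map(levels(g), function(l) {
    xs <- v[g == l]
    q <- unname(quantile(xs, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    tibble::tibble(group = l, n = length(xs), mean = mean(xs),
                   q1 = q[1], median = q[2], q3 = q[3],
                   whisker_low = min(xs[xs >= q[1] - 1.5 * iqr]),
                   whisker_high = max(xs[xs <= q[3] + 1.5 * iqr]))
  }) |> dplyr::bind_rows()
  dens <- purrr::map(levels(g), function(l) {
    xs <- v[g == l]
    if (length(xs) < 2 || sd(xs) == 0) {
      return(tibble::tibble(group = l, x = xs[1], density = 1))
    }
    d <- density(xs, bw = "nrd0", n = n_grid)
    tibble::tibble(group = l, x = d$x, density = d$y)
  }) |> dplyr::bind_rows()
  structure(list(box = box, density = dens), class = "raincloud_summary")
}
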