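#' Log2 intensity matrix with sample groups
#'
#' Container for a proteins x samples matrix of log2 intensities (missing
#' values allowed) and a sample-to-group map.
#'
#' @param mat Numeric matrix with unique rownames (protein ids) and colnames
#'   (sample ids); values on log2 scale, `NA` for missing.
#' @param groups Named character vector mapping sample id to group label.
#' @param log2_transformed Marker that `mat` is already log2.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(mat, groups, log2_transformed = TRUE) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat))) abort("duplicate protein ids")
  if (!all(colnames(mat) %in% names(groups))) {
    abort("every sample needs a group label")
  }
  groups <- groups[colnames(mat)]
  structure(list(mat = mat, groups = groups,
                 log2_transformed = isTRUE(log2_transformed)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples; groups: %s\n",
              nrow(x$mat), ncol(x$mat),
              paste(sprintf("%s (n=%d)", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Build a log2 intensity matrix from raw intensities
#'
#' Raw (linear-scale) intensities are log2-transformed; zero or negative
#' entries become missing. Proteins observed fewer than `min_obs_per_group`
#' times in any group are dropped; the number dropped is recorded in the
#' `n_dropped` attribute (and the ids in `dropped_proteins`).
#'
#' @param raw Numeric matrix of raw intensities (proteins x samples, unique
#'   rownames).
#' @param groups Named character vector: sample id -> group.
#' @param min_obs_per_group Minimum observed values per group (default 2).
#' @return An [intensity_matrix()].
#' @export
build_matrix <- function(raw, groups, min_obs_per_group = 2) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)))
  if (anyDuplicated(rownames(raw))) abort("duplicate protein ids")
  m <- raw
  m[!is.na(m) & m <= 0] <- NA
  m <- log2(m)
  groups <- groups[colnames(m)]
  keep <- vapply(seq_len(nrow(m)), function(i) {
    obs <- tapply(!is.na(m[i, ]), groups, sum)
    all(obs >= min_obs_per_group)
  }, logical(1))
  out <- intensity_matrix(m[keep, , drop = FALSE], groups)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_proteins") <- rownames(m)[!keep]
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0)
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

#' Estimate the variance-prior hyperparameters (d0, s0^2)
#'
#' Moment matching on `log(s^2)`: with `e = log(s^2) - digamma(d/2) +
#' log(d/2)`, the model implies `E[e] = log(s0^2) + digamma(d0/2) -
#' log(d0/2)` and `var(e) = mean(trigamma(d/2)) + trigamma(d0/2)`;
#' `trigamma(d0/2)` is recovered by Newton inversion. When the empirical
#' variance of `e` does not exceed the sampling contribution, `d0 = Inf`
#' (complete shrinkage to `s0^2`).
#'
#' @param s2 Per-protein residual variances (> 0 entries used).
#' @param df Residual degrees of freedom (scalar or per-protein).
#' @return List `df_prior`, `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) abort("need >= 2 positive variances")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s0_sq <- exp(emean)
  }
  list(df_prior = df_prior, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per protein, the group-mean difference `b = mean(case) - mean(control)`
#' and pooled residual variance `s^2` (df `d = n1 + n2 - 2`, observed values
#' only) are combined with a scaled inverse chi-square variance prior
#' `(d0, s0^2)` estimated across proteins ([estimate_variance_prior()]):
#' the posterior variance is `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, the
#' moderated t is `b / (s~ sqrt(1/n1 + 1/n2))` on `d0 + d` degrees of
#' freedom, and p values are BH-adjusted across proteins. Proteins with zero
#' residual df are excluded (count in attribute `n_excluded`). Forcing
#' `df_prior = 0` recovers the ordinary pooled t-test.
#'
#' @param im An [intensity_matrix()].
#' @param case,control Group labels to contrast (log2FC = case - control).
#' @param df_prior,s0_sq Optional fixed hyperparameters (both or neither).
#' @return A `de_result` tibble: `protein`, `log2fc`, `avg_intensity`,
#'   `s2`, `df_residual`, `s2_post`, `t`, `df_total`, `p_value`,
#'   `adj_p_value`; attributes `df_prior`, `s0_sq`, `n_excluded`.
#' @export
moderated_ttest <- function(im, case, control, df_prior = NULL, s0_sq = NULL) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (!all(c(case, control) %in% im$groups)) abort("unknown group label")
  m1 <- im$mat[, im$groups == case, drop = FALSE]
  m0 <- im$mat[, im$groups == control, drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n0 <- rowSums(!is.na(m0))
  if (any(n1 < 2 | n0 < 2)) {
    abort("every protein needs >= 2 observed values per contrasted group")
  }
  mu1 <- rowMeans(m1, na.rm = TRUE); mu0 <- rowMeans(m0, na.rm = TRUE)
  b <- mu1 - mu0
  ss <- rowSums((m1 - mu1)^2, na.rm = TRUE) + rowSums((m0 - mu0)^2, na.rm = TRUE)
  d <- n1 + n0 - 2
  excl <- d <= 0
  s2 <- ss / d
  if (is.null(df_prior) != is.null(s0_sq)) {
    abort("supply both `df_prior` and `s0_sq`, or neither")
  }
  if (is.null(df_prior)) {
    pri <- estimate_variance_prior(s2[!excl], d[!excl])
    df_prior <- pri$df_prior; s0_sq <- pri$s0_sq
  }
  if (is.finite(df_prior)) {
    s2_post <- (df_prior * s0_sq + d * s2) / (df_prior + d)
  } else {
    s2_post <- rep(s0_sq, length(s2))
  }
  tval <- b / sqrt(s2_post * (1 / n1 + 1 / n0))
  df_total <- df_prior + d
  p <- 2 * pt(-abs(tval), df = df_total)
  out <- tibble::tibble(
    protein = rownames(im$mat), log2fc = unname(b),
    avg_intensity = unname(rowMeans(cbind(m1, m0), na.rm = TRUE)),
    s2 = unname(s2), df_residual = unname(d), s2_post = unname(s2_post),
    t = unname(tval), df_total = unname(df_total), p_value = unname(p)
  )[!excl, ]
  out$adj_p_value <- bh_adjust(out$p_value)
  attr(out, "df_prior") <- df_prior
  attr(out, "s0_sq") <- s0_sq
  attr(out, "n_excluded") <- sum(excl)
  class(out) <- c("de_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' capped at 1.
#'
#' @param p Raw p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression cutoff regime
#'
#' The stringent regime is p < 0.05 with |log2FC| >= 1, the lenient
#' (discovery) regime p < 0.05 with |log2FC| >= 0.5. `p_basis` selects raw
#' p values (default, matching the printed cutoff convention) or
#' BH-adjusted p values for a more conservative sensitivity analysis.
#'
#' @param p_cutoff P-value cutoff in (0, 1].
#' @param lfc_cutoff Absolute log2 fold-change cutoff (>= 0).
#' @param p_basis `"raw"` or `"adjusted"`.
#' @return A `cutoff_regime` list.
#' @export
cutoff_regime <- function(p_cutoff = 0.05, lfc_cutoff = 1,
                          p_basis = c("raw", "adjusted")) {
  assert_number(p_cutoff, "p_cutoff", lower = 1e-300, upper = 1)
  assert_number(lfc_cutoff, "lfc_cutoff", lower = 0)
  structure(list(p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
                 p_basis = match.arg(p_basis)),
            class = "cutoff_regime")
}

#' @rdname cutoff_regime
#' @export
stringent_regime <- function(p_basis = "raw") {
  cutoff_regime(0.05, 1, p_basis)
}

#' @rdname cutoff_regime
#' @export
lenient_regime <- function(p_basis = "raw") {
  cutoff_regime(0.05, 0.5, p_basis)
}

#' Split a DE result into up/down protein sets under a cutoff regime
#'
#' Up-regulated: p (on the regime's basis) below `p_cutoff` and
#' `log2fc >= lfc_cutoff`; down-regulated analogously with
#' `log2fc <= -lfc_cutoff`. With `lfc_cutoff = 0`, proteins with log2FC
#' exactly 0 belong to neither set.
#'
#' @param de A `de_result` from [moderated_ttest()].
#' @param regime A [cutoff_regime()].
#' @return List of character vectors `up` and `down`.
#' @export
apply_cutoffs <- function(de, regime = stringent_regime()) {
  stopifnot(inherits(regime, "cutoff_regime"))
  p <- if (regime$p_basis == "raw") de$p_value else de$adj_p_value
  sig <- p < regime$p_cutoff
  up <- sig & de$log2fc >= regime$lfc_cutoff & de$log2fc > 0
  down <- sig & de$log2fc <= -regime$lfc_cutoff & de$log2fc < 0
  list(up = de$protein[up], down = de$protein[down])
}
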