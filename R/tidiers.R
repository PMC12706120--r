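#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a group comparison
#'
#' One row per test term: the omnibus statistic(s) and p value(s) for the
#' chosen design.
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble with `term`, `test`, `statistic`, `p_value`.
#' @export
tidy.group_comparison <- function(x, ...) {
  nm <- names(x$statistic) %||% rep(x$test, length(x$statistic))
  if (is.null(names(x$statistic))) nm <- rep("omnibus", length(x$statistic))
  tibble::tibble(term = nm, test = x$test,
                 statistic = unname(x$statistic), p_value = unname(x$p_value))
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, n_groups = length(x$groups),
                 all_normal = all(x$normality$normal),
                 p_value = x$p_value[1],
                 has_posthoc = !is.null(x$posthoc))
}

#' Tidy a bootstrap result
#'
#' @param x A `boot_result` from [bootstrap_parameter()].
#' @param ... Unused.
#' @return One-row tibble: `stat`, `estimate`, `ci_lower`, `ci_upper`,
#'   `n_boot`.
#' @export
tidy.boot_result <- function(x, ...) {
  tibble::tibble(stat = x$stat, estimate = x$estimate,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 n_boot = x$n_boot)
}

#' @rdname tidy.boot_result
#' @export
glance.boot_result <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, replicate_size = x$replicate_size,
                 conf = x$conf,
                 se_boot = sd(x$replicates))
}

#' Tidy / summarise a differential-expression result
#'
#' `tidy()` returns the per-protein table (it already is tidy); `glance()`
#' summarises the fit: protein count, the estimated variance-prior
#' hyperparameters and discovery counts at the stringent and lenient
#' regimes.
#'
#' @param x A `de_result` from [moderated_ttest()].
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  s <- apply_cutoffs(x, stringent_regime())
  l <- apply_cutoffs(x, lenient_regime())
  tibble::tibble(
    n_proteins = nrow(x),
    df_prior = attr(x, "df_prior"), s0_sq = attr(x, "s0_sq"),
    n_up_stringent = length(s$up), n_down_stringent = length(s$down),
    n_up_lenient = length(l$up), n_down_lenient = length(l$down)
  )
}

#' Tidy a tracking evaluation
#'
#' @param x A `tracking_eval` from [evaluate_tracking()].
#' @param ... Unused.
#' @export
tidy.tracking_eval <- function(x, ...) {
  tibble::tibble(recall = x$recall, precision = x$precision,
                 identity_accuracy = x$identity_accuracy,
                 n_truth_spots = x$n_truth_spots,
                 n_detected_spots = x$n_detected_spots,
                 n_truth_links = x$n_truth_links,
                 n_correct_links = x$n_correct_links)
}
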