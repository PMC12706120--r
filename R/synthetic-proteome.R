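#' Parameters for simulated lysosome-enriched proteome matrices
#'
#' The generator emulates the statistical structure of a log2-transformed
#' protein intensity matrix: per-protein true variances drawn from a scaled
#' inverse chi-square prior with `df_prior_true` degrees of freedom and scale
#' `s0_true` (the empirical-Bayes model the moderated t-test assumes), and
#' a fraction `frac_de` of proteins shifted by `+/- effect_log2fc` between
#' the case and control groups.
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Samples per group (>= 2).
#' @param frac_de Fraction of truly differential proteins, in \[0, 1\].
#' @param effect_log2fc Planted absolute log2 fold change.
#' @param sigma_protein SD of baseline log2 abundances across proteins.
#' @param df_prior_true,s0_true Variance-prior hyperparameters: degrees of
#'   freedom and prior scale (an SD, so the prior variance is `s0_true^2`)
#'   of the scaled inverse chi-square.
#' @param mean_log2 Grand mean log2 abundance.
#' @return A `de_sim_params` list.
#' @export
de_sim_params <- function(n_proteins = 2000, n_per_group = 4, frac_de = 0.1,
                          effect_log2fc = 1, sigma_protein = 2,
                          df_prior_true = 4, s0_true = 0.25,
                          mean_log2 = 25) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_per_group <- assert_count(n_per_group, "n_per_group", lower = 2)
  assert_number(frac_de, "frac_de", 0, 1)
  assert_number(effect_log2fc, "effect_log2fc", lower = 0)
  assert_number(sigma_protein, "sigma_protein", lower = 0)
  assert_number(df_prior_true, "df_prior_true", lower = .Machine$double.eps)
  assert_number(s0_true, "s0_true", lower = 0)
  structure(
    list(n_proteins = n_proteins, n_per_group = n_per_group, frac_de = frac_de,
         effect_log2fc = effect_log2fc, sigma_protein = sigma_protein,
         df_prior_true = df_prior_true, s0_true = s0_true,
         mean_log2 = mean_log2),
    class = "de_sim_params"
  )
}

#' Simulate a grouped log2 intensity matrix with planted fold changes
#'
#' @param params A [de_sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `matrix` (an [intensity_matrix()]: proteins x samples,
#'   log2 scale, groups `control`/`case`) and `truth` (tibble: `protein`,
#'   `is_de`, `true_log2fc`, `true_var`).
#' @export
simulate_intensity_matrix <- function(params, seed = NULL) {
  stopifnot(inherits(params, "de_sim_params"))
  with_seed_or_stream(seed, {
    p <- params
    ids <- sprintf("P%04d", seq_len(p$n_proteins))
    n_de <- round(p$frac_de * p$n_proteins)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, p$n_proteins - n_de))
    sign_de <- ifelse(runif(p$n_proteins) < 0.5, 1, -1)
    lfc <- ifelse(is_de, sign_de * p$effect_log2fc, 0)
    # scaled inverse chi-square: var = df0 * s0^2 / chisq_df0
    true_var <- if (p$s0_true > 0) {
      p$df_prior_true * p$s0_true^2 / rchisq(p$n_proteins, p$df_prior_true)
    } else rep(0, p$n_proteins)
    base <- rnorm(p$n_proteins, p$mean_log2, p$sigma_protein)
    n <- p$n_per_group
    noise <- matrix(rnorm(p$n_proteins * 2 * n), p$n_proteins, 2 * n) * sqrt(true_var)
    mat <- base + cbind(matrix(0, p$n_proteins, n),
                        matrix(lfc, p$n_proteins, n)) + noise
    rownames(mat) <- ids
    colnames(mat) <- c(sprintf("ctrl_%d", seq_len(n)), sprintf("case_%d", seq_len(n)))
    groups <- setNames(rep(c("control", "case"), each = n), colnames(mat))
    truth <- tibble::tibble(protein = ids, is_de = is_de,
                            true_log2fc = lfc, true_var = true_var)
    list(matrix = intensity_matrix(mat, groups, log2_transformed = TRUE),
         truth = truth)
  })
}

#' Simulate a cathepsin-style plate-reader fluorescence table
#'
#' Each of `n_wells` samples gets duplicate substrate wells with final
#' fluorescence `blank_level + rate_rfu_per_min * minutes` (+ noise),
#' duplicate inhibited-control wells at
#' `blank_level + inhibited_fraction * rate_rfu_per_min * minutes`, plus
#' duplicate blank wells.
#'
#' @param n_wells Number of samples.
#' @param rate_rfu_per_min True uninhibited fluorescence accumulation rate
#'   (RFU/min, >= 0).
#' @param blank_level Blank fluorescence (RFU).
#' @param inhibited_fraction Residual activity fraction in inhibited wells.
#' @param minutes Incubation time (min, > 0); 120 min matches the standard
#'   endpoint assay.
#' @param mg_protein Protein loaded per well (mg, > 0).
#' @param noise_sd Gaussian well noise SD (RFU).
#' @param seed Integer seed.
#' @return Tibble with columns `well`, `sample`, `condition`
#'   (`sample`/`inhibited`/`blank`), `rfu`, `minutes`, `mg`.
#' @export
simulate_platereader <- function(n_wells, rate_rfu_per_min, blank_level,
                                 inhibited_fraction = 0, minutes = 120,
                                 mg_protein = 0.1, noise_sd = 0, seed = NULL) {
  n_wells <- assert_count(n_wells, "n_wells")
  assert_number(rate_rfu_per_min, "rate_rfu_per_min", lower = 0)
  assert_number(blank_level, "blank_level", lower = 0)
  assert_number(inhibited_fraction, "inhibited_fraction", 0, 1)
  assert_number(minutes, "minutes", lower = .Machine$double.eps)
  assert_number(mg_protein, "mg_protein", lower = .Machine$double.eps)
  assert_number(noise_sd, "noise_sd", lower = 0)
  with_seed_or_stream(seed, {
    per <- function(cond, level, sample_id) {
      tibble::tibble(sample = sample_id, condition = cond,
                     rfu = level + rnorm(2, 0, noise_sd),
                     minutes = minutes,
                     mg = if (cond == "blank") NA_real_ else mg_protein)
    }
    f_samp <- blank_level + rate_rfu_per_min * minutes
    f_inh <- blank_level + inhibited_fraction * rate_rfu_per_min * minutes
    rows <- purrr::map(seq_len(n_wells), function(i) {
      dplyr::bind_rows(per("sample", f_samp, sprintf("S%02d", i)),
                       per("inhibited", f_inh, sprintf("S%02d", i)))
    })
    out <- dplyr::bind_rows(c(rows, list(per("blank", blank_level, NA_character_))))
    out$well <- sprintf("W%03d", seq_len(nrow(out)))
    dplyr::relocate(out, "well")
  })
}
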