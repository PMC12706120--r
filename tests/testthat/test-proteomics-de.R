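make_im <- function(ctrl, case) {
  # ctrl/case: proteins x replicates matrices
  mat <- cbind(ctrl, case)
  rownames(mat) <- sprintf("P%d", seq_len(nrow(mat)))
  colnames(mat) <- c(sprintf("c%d", seq_len(ncol(ctrl))),
                     sprintf("t%d", seq_len(ncol(case))))
  groups <- setNames(rep(c("control", "case"), c(ncol(ctrl), ncol(case))),
                     colnames(mat))
  intensity_matrix(mat, groups)
}

test_that("build_matrix log2-transforms, masks non-positives and applies the drop rule", {
  raw <- rbind(P1 = c(4, 8, 16, 32),
               P2 = c(2, 0, -1, 8),     # two non-positives -> 1 obs in group a
               P3 = c(1, 1, 0, 4))      # one missing in group b: still >= 2? no: 1 obs
  colnames(raw) <- c("a1", "a2", "b1", "b2")
  groups <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  im <- build_matrix(raw, groups, min_obs_per_group = 2)
  expect_equal(rownames(im$mat), "P1")
  expect_equal(im$mat["P1", ], c(a1 = 2, a2 = 3, b1 = 4, b2 = 5))
  expect_equal(attr(im, "n_dropped"), 2)
  expect_setequal(attr(im, "dropped_proteins"), c("P2", "P3"))
  raw2 <- raw; rownames(raw2) <- c("P1", "P1", "P3")
  expect_error(build_matrix(raw2, groups), "duplicate")
})

test_that("with df_prior = 0 the moderated t equals the classic pooled t-test", {
  set.seed(8)
  ctrl <- matrix(rnorm(5 * 4, 10, 1), 5, 4)
  case <- matrix(rnorm(5 * 4, 11, 1), 5, 4)
  im <- make_im(ctrl, case)
  de <- moderated_ttest(im, "case", "control", df_prior = 0, s0_sq = 1)
  for (i in 1:5) {
    tt <- t.test(case[i, ], ctrl[i, ], var.equal = TRUE)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$log2fc[i], mean(case[i, ]) - mean(ctrl[i, ]),
                 tolerance = 1e-12)
  }
  expect_equal(de$df_total, rep(6, 5))
})

test_that("a hand-computable toy gives the expected pooled t", {
  im <- make_im(rbind(c(1, 2, 3)), rbind(c(4, 5, 6)))
  de <- moderated_ttest(im, "case", "control", df_prior = 0, s0_sq = 1)
  # b = 3, pooled s2 = (2 + 2) / 4 = 1, t = 3 / sqrt(2/3)
  expect_equal(de$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$s2, 1)
})

test_that("with fixed hyperparameters the moderated t matches limma exactly", {
  skip_if_not_installed("limma")
  set.seed(81)
  sim <- simulate_intensity_matrix(de_sim_params(n_proteins = 300), seed = 82)
  im <- sim$matrix
  design <- cbind(intercept = 1, case = as.numeric(im$groups == "case"))
  fit <- limma::eBayes(limma::lmFit(im$mat, design))
  de <- moderated_ttest(im, "case", "control",
                        df_prior = fit$df.prior, s0_sq = fit$s2.prior)
  expect_equal(de$t, unname(fit$t[, "case"]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, "case"]), tolerance = 1e-8)
  expect_equal(de$log2fc, unname(fit$coefficients[, "case"]), tolerance = 1e-10)
  expect_equal(de$s2_post, unname(fit$s2.post), tolerance = 1e-8)
})

test_that("self-estimated hyperparameters are close to limma's", {
  skip_if_not_installed("limma")
  sim <- simulate_intensity_matrix(de_sim_params(), seed = 83)
  im <- sim$matrix
  design <- cbind(intercept = 1, case = as.numeric(im$groups == "case"))
  fit <- limma::eBayes(limma::lmFit(im$mat, design))
  de <- moderated_ttest(im, "case", "control")
  expect_lt(abs(attr(de, "df_prior") - fit$df.prior) / fit$df.prior, 0.25)
  expect_lt(abs(attr(de, "s0_sq") - fit$s2.prior) / fit$s2.prior, 0.1)
})

test_that("infinite prior df collapses all posterior variances to s0^2", {
  set.seed(9)
  im <- make_im(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4))
  de <- moderated_ttest(im, "case", "control", df_prior = Inf, s0_sq = 0.5)
  expect_equal(de$s2_post, rep(0.5, 3))
  expect_equal(de$t, de$log2fc / sqrt(0.5 * 0.5), tolerance = 1e-12)
})

test_that("hyperparameters are recovered from a large simulated cohort", {
  p <- de_sim_params(n_proteins = 2000, frac_de = 0)
  sim <- simulate_intensity_matrix(p, seed = 84)
  de <- moderated_ttest(sim$matrix, "case", "control")
  expect_lt(abs(attr(de, "df_prior") - p$df_prior_true) / p$df_prior_true, 0.5)
  expect_lt(abs(attr(de, "s0_sq") - p$s0_true^2) / p$s0_true^2, 0.25)
})

test_that("planted effects are detected with high recall and controlled FDR", {
  p <- de_sim_params()   # 2000 proteins, 10% DE at |log2FC| = 1, n = 4
  sim <- simulate_intensity_matrix(p, seed = 85)
  de <- moderated_ttest(sim$matrix, "case", "control")
  called <- de$protein[de$adj_p_value < 0.05]
  truth <- sim$truth$protein[sim$truth$is_de]
  recall <- length(intersect(called, truth)) / length(truth)
  fdr <- if (length(called)) 1 - length(intersect(called, truth)) / length(called) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.10)
})

test_that("swapping case and control negates effects and preserves p values", {
  sim <- simulate_intensity_matrix(de_sim_params(n_proteins = 100), seed = 86)
  a <- moderated_ttest(sim$matrix, "case", "control")
  b <- moderated_ttest(sim$matrix, "control", "case")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  set.seed(10)
  pr <- runif(50)
  got <- bh_adjust(pr)
  # hand step-up: adj_(i) = min_{j >= i} p_(j) * m / j (on sorted p)
  o <- order(pr)
  m <- length(pr)
  sorted_adj <- rev(cummin(rev(pr[o] * m / seq_len(m))))
  want <- numeric(m); want[o] <- pmin(1, sorted_adj)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= pr - 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cutoff regimes split up and down sets correctly", {
  de <- tibble::tibble(
    protein = c("A", "B", "C", "D", "E", "F"),
    log2fc = c(1.2, 0.7, -1.5, 2.0, -0.5, 0),
    p_value = c(0.04, 0.04, 0.01, 0.06, 0.03, 0.001),
    adj_p_value = c(0.08, 0.08, 0.03, 0.09, 0.06, 0.004))
  s <- apply_cutoffs(de, stringent_regime())
  expect_equal(s$up, "A")          # B fails |lfc| >= 1, D fails p < 0.05
  expect_equal(s$down, "C")        # E fails |lfc| >= 1
  l <- apply_cutoffs(de, lenient_regime())
  expect_setequal(l$up, c("A", "B"))
  expect_setequal(l$down, c("C", "E"))
  # adjusted-p basis is stricter here
  sa <- apply_cutoffs(de, cutoff_regime(0.05, 1, p_basis = "adjusted"))
  expect_equal(sa$up, character(0))
  expect_equal(sa$down, "C")
  # lfc_cutoff = 0 never claims zero-fold-change proteins
  z <- apply_cutoffs(de, cutoff_regime(0.05, 0))
  expect_false("F" %in% c(z$up, z$down))
})

test_that("exclusive overlaps match a bitmask oracle on random sets", {
  set.seed(11)
  universe <- sprintf("G%02d", 1:40)
  sets <- list(a = sample(universe, 15), b = sample(universe, 20),
               c = sample(universe, 10))
  ov <- overlap_sets(sets)
  # oracle: classify every universe element by its exact membership pattern
  pat <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  want <- table(pat[nzchar(pat)])
  for (i in seq_len(nrow(ov$exclusive))) {
    expect_equal(ov$exclusive$count[i],
                 unname(as.integer(want[ov$exclusive$combination[i]])))
  }
  expect_equal(sum(ov$exclusive$count), sum(nzchar(pat)))
  # pairwise intersections
  ab <- ov$pairwise$count[ov$pairwise$set1 == "a" & ov$pairwise$set2 == "b"]
  expect_equal(ab, length(intersect(sets$a, sets$b)))
})

test_that("overlap edge cases: disjoint and identical sets", {
  d <- overlap_sets(list(x = c("a", "b"), y = c("c", "d")))
  expect_setequal(d$exclusive$combination, c("x", "y"))
  expect_equal(d$pairwise$count, 0L)
  s <- overlap_sets(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(s$exclusive$combination, "x&y")
  expect_equal(s$exclusive$count, 2L)
})

test_that("shared DE proteins use the union-intersect rule", {
  got <- shared_de_proteins(up_a = c("A", "B"), down_a = "C",
                            up_b = c("B", "D"), down_b = c("C", "E"))
  expect_setequal(got, c("B", "C"))
  expect_equal(shared_de_proteins("A", character(0), character(0), "B"),
               character(0))
})

test_that("curated cross-reference is case-insensitive and counts by direction", {
  cr <- crossref_curated(up = c("Lamp1", "GAPDH"), down = c("ctsd", "TUBB"),
                         curated = c("LAMP1", "CTSD", "MAP1LC3B"))
  expect_equal(cr$summary$n_altered_in_curated, 2)
  expect_equal(cr$summary$n_up_in_curated, 1)
  expect_equal(cr$summary$n_down_in_curated, 1)
  expect_equal(cr$summary$n_curated, 3)
  expect_equal(cr$table$in_curated, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(crossref_curated("A", "B", character(0)), "empty")
})

test_that("ORA p values are exactly hypergeometric", {
  universe <- sprintf("G%02d", 1:20)
  gs <- gene_set_collection(list(hit = universe[1:5], miss = universe[6:10]),
                            universe)
  res <- ora_hypergeometric(universe[1:5], gs)
  # full containment: P(all 5 draws land in the 5-element set) = 1/choose(20,5)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # zero overlap has upper-tail p = 1
  expect_equal(res$p_value[res$set == "miss"], 1, tolerance = 1e-12)
  expect_equal(res$overlap, c(5L, 0L))
  expect_equal(res$expected, c(5 * 5 / 20, 5 * 5 / 20))
})

test_that("ORA upper tail equals the direct probability sum", {
  set.seed(12)
  universe <- sprintf("G%03d", 1:100)
  gs <- gene_set_collection(list(s = sample(universe, 20)), universe)
  sel <- sample(universe, 15)
  res <- ora_hypergeometric(sel, gs)
  k <- res$overlap
  direct <- sum(dhyper(k:15, 20, 80, 15))
  expect_equal(res$p_value, direct, tolerance = 1e-12)
})

test_that("gene set collections harmonise case and restrict to the universe", {
  gs <- gene_set_collection(list(s = c("lamp1", "FOO", "Ctsd")),
                            universe = c("LAMP1", "CTSD", "TUBB"))
  expect_setequal(gs$sets$s, c("LAMP1", "CTSD"))
  expect_equal(length(gs$universe), 3)
})

test_that("GMT round-trips through write_gmt and read_gmt", {
  sets <- list(lyso = c("LAMP1", "CTSD"), auto = c("MAP1LC3B", "SQSTM1", "ATG5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
})
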