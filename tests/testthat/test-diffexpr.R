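# small tmt_norm built directly from a log2 matrix (2 conditions x n reps,
# single batch, no bridges involved in the statistics)
mock_norm <- function(x, cond) {
  key <- sprintf("b1.C%02d", seq_along(cond))
  colnames(x) <- key
  d <- data.frame(batch = "b1", channel = sub("^b1\\.", "", key), tag = key,
                  sample = key, condition = cond,
                  replicate = as.integer(stats::ave(seq_along(cond), cond, FUN = seq_along)),
                  is_bridge = FALSE, column_key = key, stringsAsFactors = FALSE)
  structure(list(log2 = x, design = d, conditions = unique(cond),
                 applied_steps = list(), dropped = character(0)), class = "tmt_norm")
}

test_that("one-way fit recovers replicate means, pooled variance and df", {
  x <- rbind(P1 = c(1, 2, 3, 5, 5, 5), P2 = c(2, 2, 2, 4, 4, 4))
  cond <- rep(c("A", "B"), each = 3)
  fit <- fit_condition_means(mock_norm(x, cond))
  expect_equal(unname(fit$means["P1", ]), c(2, 5))
  expect_equal(unname(fit$s2[["P2"]]), 0)
  expect_equal(unname(fit$s2[["P1"]]), (1 + 0) / 4 * 2)  # RSS 2 over df 4
  expect_identical(fit$df, 4L)

  # the full layout gives 18 - 6 = 12 residual df
  sd <- simulate_dataset(sim_config(n_proteins = 60, seed = 3))
  fit18 <- fit_condition_means(normalize_pipeline(sd$matrices, sd$design))
  expect_identical(fit18$df, 12L)

  one_rep <- mock_norm(x[, c(1, 4, 5, 6)], c("A", "B", "B", "B"))
  expect_error(fit_condition_means(one_rep), "'A' has fewer than 2 replicates")
})

test_that("prior estimation recovers known hyperparameters and handles the degenerate limit", {
  set.seed(2024)
  d0 <- 4; s0 <- 0.04; dg <- 12; n <- 5000
  s2 <- s0 * (rchisq(n, dg) / dg) / (rchisq(n, d0) / d0)
  pri <- estimate_priors(s2, dg)
  expect_lt(abs(pri$d0 - d0) / d0, 0.15)
  expect_lt(abs(pri$s0_sq - s0) / s0, 0.10)

  # identical variances: no excess spread, so the prior is degenerate; the
  # moment estimate of s0^2 is exp(mean(e)), i.e. the common value corrected
  # for the expected bias of a log chi-square with d_g df
  same <- rep(0.3, 50)
  pri2 <- estimate_priors(same, dg)
  expect_identical(pri2$d0, Inf)
  expect_equal(pri2$s0_sq, 0.3 * exp(log(dg / 2) - digamma(dg / 2)))

  expect_error(estimate_priors(rep(0.1, 5), dg), "at least 10")
})

test_that("trigamma inversion is exact on round trips and monotone", {
  for (x in c(0.05, 0.5, 2, 30, 4000))
    expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-8)
  ys <- c(0.01, 0.1, 1, 10)
  xs <- vapply(ys, trigamma_inverse, numeric(1))
  expect_true(all(diff(xs) < 0))  # trigamma decreasing => inverse decreasing
})

test_that("moderated t collapses to the ordinary t at d0 = 0 and under equal variances", {
  set.seed(5)
  x <- matrix(rnorm(50 * 6), 50, dimnames = list(sprintf("P%02d", 1:50), NULL))
  cond <- rep(c("A", "B"), each = 3)
  norm <- mock_norm(x, cond)
  fit <- fit_condition_means(norm)

  plain <- moderated_test(fit, list(d0 = 0, s0_sq = NA), "A", "B")
  ora <- oracle_ordinary_t(x, cond, "A", "B")
  expect_equal(plain$t, ora$t, tolerance = 1e-12)
  expect_equal(plain$p, ora$p, tolerance = 1e-12)

  # equal variances: shrinkage target equals every s_g^2, so t is unchanged
  xe <- rbind(x[1, ] + 0, x[1, ] + 1, x[1, ] + 2)
  rownames(xe) <- paste0("Q", 1:3)
  fe <- fit_condition_means(mock_norm(xe, cond))
  t_plain <- moderated_test(fe, list(d0 = 0, s0_sq = NA), "A", "B")$t
  t_mod <- moderated_test(fe, list(d0 = 7, s0_sq = fe$s2[[1]]), "A", "B")$t
  expect_equal(t_mod, t_plain, tolerance = 1e-12)
})

test_that("moderated statistics match a formula-by-formula oracle and limma", {
  set.seed(9)
  sig <- sqrt(0.05 * 4 / rchisq(200, 4))  # heteroscedastic rows, finite d0
  x <- matrix(rnorm(200 * 18, 20, rep(sig, 18)), 200,
              dimnames = list(sprintf("P%03d", 1:200), NULL))
  cond <- rep(paste0("G", 1:6), each = 3)
  norm <- mock_norm(x, cond)
  fit <- fit_condition_means(norm)
  pri <- estimate_priors(fit$s2, fit$df)
  got <- moderated_test(fit, pri, "G2", "G5")
  ora <- oracle_moderated(x, cond, "G2", "G5", pri$d0, pri$s0_sq)
  expect_equal(got$logFC, ora$logFC, tolerance = 1e-12)
  expect_equal(got$t, ora$t, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)

  skip_if_not_installed("limma")
  design <- model.matrix(~ 0 + factor(cond))
  colnames(design) <- paste0("G", 1:6)
  lfit <- limma::lmFit(x, design)
  cm <- limma::makeContrasts(G2 - G5, levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  expect_equal(unname(got$logFC), unname(eb$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(unname(got$t), unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(got$p), unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderation keeps t^2 between the ordinary and fully-shrunk statistics", {
  set.seed(14)
  x <- matrix(rnorm(100 * 6, 0, 1), 100, dimnames = list(sprintf("P%03d", 1:100), NULL))
  cond <- rep(c("A", "B"), each = 3)
  fit <- fit_condition_means(mock_norm(x, cond))
  pri <- estimate_priors(fit$s2, fit$df)
  t_mod <- moderated_test(fit, pri, "A", "B")$t^2
  t_ord <- moderated_test(fit, list(d0 = 0, s0_sq = NA), "A", "B")$t^2
  t_inf <- moderated_test(fit, list(d0 = Inf, s0_sq = pri$s0_sq), "A", "B")$t^2
  expect_true(all(t_mod >= pmin(t_ord, t_inf) - 1e-12))
  expect_true(all(t_mod <= pmax(t_ord, t_inf) + 1e-12))
})

test_that("BH adjustment reproduces the hand step-up and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(77)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p))
  }
})

test_that("all pairwise contrasts: 15 contrasts, antisymmetry, noiseless exactness", {
  cfg <- sim_config(n_proteins = 250, noise_sd_log2 = 0, channel_loading_sd_log2 = 0,
                    batch_effect_sd_log2 = 0, dropout_rate = 0, seed = 6)
  sd <- simulate_dataset(cfg)
  norm <- normalize_pipeline(sd$matrices, sd$design)
  ct <- all_pairwise_contrasts(norm, moderation = FALSE)
  expect_identical(length(unique(ct$table$contrast)), 15L)

  fit <- ct$fit
  fwd <- moderated_test(fit, list(d0 = 0, s0_sq = NA), "Py/Fu", "H2/Fu")
  rev <- moderated_test(fit, list(d0 = 0, s0_sq = NA), "H2/Fu", "Py/Fu")
  expect_equal(fwd$logFC, -rev$logFC)

  m <- merge(ct$table, truth_contrast_table(sd$truth), by = c("protein", "contrast"))
  expect_lt(max(abs(m$logFC - m$true_logfc)), 1e-9)
})

test_that("BH keeps the per-contrast false discovery fraction controlled under the null", {
  fractions <- c()
  for (s in 1:10) {
    sd <- simulate_dataset(sim_config(n_proteins = 600, fraction_regulated = 0,
                                      dropout_rate = 0, seed = 6000 + s))
    norm <- normalize_pipeline(sd$matrices, sd$design)
    tab <- all_pairwise_contrasts(norm)$table
    fractions <- c(fractions, vapply(split(tab$fdr, tab$contrast),
                                     function(q) mean(q < 0.05), numeric(1)))
  }
  expect_lte(mean(fractions), 0.05)
})
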