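mk <- function(v, batch = "b1") {
  dimnames(v) <- list(paste0("P", seq_len(nrow(v))), paste0("C", seq_len(ncol(v))))
  tmt_matrix(v, batch)
}

test_that("sample loading equalizes column sums to the grand mean", {
  m <- mk(matrix(c(4, 6, 16, 4, 9, 21), 2))  # column sums 10, 20, 30
  out <- sample_loading_normalize(m)
  expect_equal(unname(out$factors), c(2, 1, 2/3))
  expect_equal(unname(colSums(out$matrix)), rep(20, 3))

  eq <- mk(matrix(c(1, 9, 4, 6, 2, 8), 2))  # all column sums 10
  out2 <- sample_loading_normalize(eq)
  expect_equal(unclass(out2$matrix), unclass(eq))
  expect_equal(unname(out2$factors), rep(1, 3))

  single <- mk(matrix(c(3, 7), 2, 1))
  expect_equal(unclass(sample_loading_normalize(single)$matrix), unclass(single))

  zero <- mk(matrix(c(0, 0, 1, 2), 2))
  expect_error(sample_loading_normalize(zero), "zero column sum")
})

test_that("IRS equalizes per-protein bridge means across batches", {
  d <- tiny_design(n_bio = 2, n_bridge = 2)  # channels C1,C2 bio; C3,C4 bridges
  v1 <- matrix(c(50, 10, 70, 10, 90, 10, 110, 10), 2)   # P1 bridge mean 100
  v2 <- matrix(c(200, 10, 280, 10, 350, 10, 450, 10), 2) # P1 bridge mean 400
  mats <- tiny_batches(v1, v2)
  out <- irs_normalize(mats, d)
  # reference sqrt(100 * 400) = 200 -> factors 2.0 and 0.5 for P1
  expect_equal(unname(out$factors["P1", ]), c(2, 0.5))
  bm1 <- rowMeans(out$matrix[, c("b1.C3", "b1.C4")])
  bm2 <- rowMeans(out$matrix[, c("b2.C3", "b2.C4")])
  expect_equal(bm1, bm2, tolerance = 1e-14)
  expect_equal(unname(bm1["P1"]), 200)

  # equal bridge means -> identity (up to exp/log round-off in the reference)
  same <- tiny_batches(v1, v1)
  out2 <- irs_normalize(same, d)
  expect_equal(unname(out2$factors), matrix(1, 2, 2), tolerance = 1e-14)
  expect_equal(unname(unclass(out2$matrix)[, 1:4]), unname(v1), tolerance = 1e-14)

  # single batch -> no-op
  d1 <- d[d$batch == "b1", ]
  attr(d1, "conditions") <- attr(d, "conditions")
  out3 <- irs_normalize(mats[1], d1)
  expect_true(all(out3$factors == 1))

  # zero bridge mean -> protein dropped with warning
  v1z <- v1; v1z[2, 3:4] <- 0
  expect_warning(out4 <- irs_normalize(tiny_batches(v1z, v2), d), "zero bridge mean")
  expect_identical(out4$dropped, "P2")
  expect_identical(rownames(out4$matrix), "P1")
})

test_that("TMM factors reproduce hand-enumerated and compositional cases", {
  two_same <- mk(matrix(c(5, 7, 2, 5, 7, 2), 3))[, 1:2]
  expect_equal(unname(tmm_factors(two_same)$factors), c(1, 1))

  set.seed(2)
  a <- rlnorm(40, 8, 1)
  prop <- mk(cbind(a, 3 * a))
  expect_equal(unname(tmm_factors(prop)$factors), c(1, 1))

  hand <- mk(cbind(c(100, 100, 100, 100), c(100, 100, 100, 500)))
  f <- tmm_factors(hand)$factors
  expect_equal(unname(f), c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)

  # aggressive M-trim leaves a single survivor -> untrimmed fallback
  tiny <- mk(cbind(c(100, 100, 100), c(50, 100, 400)))
  expect_warning(tmm_factors(tiny, trim_M = 0.45), "fewer than 2 rows")
})

test_that("TMM factors match the brute-force oracle and edgeR, with geometric mean 1", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  for (r in 1:10) {
    x <- matrix(rlnorm(200 * 6, 9, 1.2), 200, 6,
                dimnames = list(sprintf("P%03d", 1:200), paste0("C", 1:6)))
    f <- tmm_factors(mk(x))$factors
    expect_lt(max(abs(f - oracle_tmm(x))), 1e-9)
    expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
    fe <- edgeR::calcNormFactors(x, method = "TMM")
    expect_lt(max(abs(f - fe)), 1e-8)
    # invariance under global rescaling (the precision weights scale uniformly)
    expect_lt(max(abs(tmm_factors(mk(x * 12.5))$factors - f)), 1e-9)
  }
})

test_that("full cascade: no nuisance means log2 output is signal plus one constant", {
  cfg <- sim_config(n_proteins = 400, noise_sd_log2 = 0, channel_loading_sd_log2 = 0,
                    batch_effect_sd_log2 = 0, dropout_rate = 0, seed = 8)
  sd <- simulate_dataset(cfg)
  norm <- normalize_pipeline(sd$matrices, sd$design)
  bio <- norm$design[!norm$design$is_bridge, ]
  expected <- sd$truth$baseline[rownames(norm$log2)] +
    sd$truth$effects[rownames(norm$log2), bio$condition]
  got <- norm$log2[, bio$column_key]
  delta <- got - expected
  expect_lt(max(delta) - min(delta), 1e-9)
})

test_that("cascade post-conditions: SL sums, IRS bridge agreement, QC positive control", {
  sd <- simulate_dataset(sim_config(n_proteins = 600, seed = 21))
  norm <- normalize_pipeline(sd$matrices, sd$design)
  expect_lt(norm$applied_steps$bridge_qc_max_rel, 1e-9)
  for (b in unique(sd$design$batch)) {
    s <- norm$applied_steps$SL[[b]]
    expect_true(all(is.finite(s) & s > 0))
  }
  f <- norm$applied_steps$TMM$factors
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)

  no_irs <- normalize_pipeline(sd$matrices, sd$design, skip_irs = TRUE)
  expect_gt(no_irs$applied_steps$bridge_qc_max_rel, 0.01)
})

test_that("cascade is equivariant under permutation of protein rows", {
  sd <- simulate_dataset(sim_config(n_proteins = 150, seed = 4))
  norm1 <- normalize_pipeline(sd$matrices, sd$design)
  set.seed(1)
  perm <- sample(nrow(sd$matrices[[1]]))
  mats <- lapply(sd$matrices, function(m) tmt_matrix(unclass(m)[perm, ], attr(m, "batch_id")))
  norm2 <- normalize_pipeline(mats, sd$design)
  common <- rownames(norm1$log2)
  expect_equal(norm2$log2[common, ], norm1$log2[common, ], tolerance = 1e-12)
})

test_that("IRS benefit grows with batch effect while staying bounded when enabled", {
  err <- function(batch_sd, skip_irs) {
    sd <- simulate_dataset(sim_config(n_proteins = 800, batch_effect_sd_log2 = batch_sd,
                                      dropout_rate = 0, seed = 77))
    norm <- normalize_pipeline(sd$matrices, sd$design, skip_irs = skip_irs)
    m <- merge(all_pairwise_contrasts(norm)$table, truth_contrast_table(sd$truth),
               by = c("protein", "contrast"))
    median(abs(m$logFC - m$true_logfc))
  }
  no_irs <- c(err(0, TRUE), err(0.75, TRUE), err(1.5, TRUE))
  expect_true(all(diff(no_irs) > 0))
  with_irs <- c(err(0, FALSE), err(1.5, FALSE))
  expect_lt(abs(with_irs[2] - with_irs[1]), 0.05)
})
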