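# Independent oracles, deliberately written in a different style from the
# package implementations (explicit loops, sort-based trimming) so that
# agreement is a genuine dual-route check.

# Brute-force TMM: proportions, M/A per row, sorted-window double trimming,
# inverse-variance weighted mean, geometric-mean-1 rescaling.
oracle_tmm <- function(x, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(x)
  q75 <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) q75[j] <- unname(quantile(x[, j], 0.75)) / lib[j]
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    M <- A <- v <- numeric(0)
    for (i in seq_len(nrow(x))) {
      po <- x[i, j] / lib[j]; pr <- x[i, ref] / lib[ref]
      if (po > 0 && pr > 0) {
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        v <- c(v, (lib[j] - x[i, j]) / (lib[j] * x[i, j]) +
                  (lib[ref] - x[i, ref]) / (lib[ref] * x[i, ref]))
      }
    }
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    lo_m <- floor(n * trim_M) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_A) + 1; hi_a <- n + 1 - lo_a
    rm <- rank(M); ra <- rank(A)
    keep <- which(rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a)
    if (length(keep) < 2) keep <- seq_len(n)
    num <- den <- 0
    for (i in keep) { num <- num + M[i] / v[i]; den <- den + 1 / v[i] }
    f[j] <- 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# Hand step-up BH: q_(i) = min_{j>=i} m p_(j)/j capped at 1, back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * p[o[i]] / i)
    q_sorted[i] <- min(1, run_min)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Formula-by-formula moderated test, independent of the package's vectorized
# path: per-protein loop over condition means, pooled variance, shrinkage.
oracle_moderated <- function(x, cond, a, b, d0, s0_sq) {
  conds <- unique(cond)
  out <- data.frame(logFC = numeric(nrow(x)), t = numeric(nrow(x)), p = numeric(nrow(x)))
  dg <- ncol(x) - length(conds)
  for (i in seq_len(nrow(x))) {
    mns <- sapply(conds, function(cc) mean(x[i, cond == cc]))
    rss <- 0
    for (j in seq_len(ncol(x))) rss <- rss + (x[i, j] - mns[cond[j]])^2
    s2 <- rss / dg
    s2p <- if (is.infinite(d0)) s0_sq else if (d0 == 0) s2 else (d0 * s0_sq + dg * s2) / (d0 + dg)
    na <- sum(cond == a); nb <- sum(cond == b)
    lfc <- mns[a] - mns[b]
    tt <- lfc / (sqrt(s2p) * sqrt(1 / na + 1 / nb))
    out$logFC[i] <- lfc; out$t[i] <- tt
    out$p[i] <- 2 * pt(-abs(tt), df = d0 + dg)
  }
  out
}

# classical two-sample pooled-variance t using the one-way pooled s2
oracle_ordinary_t <- function(x, cond, a, b) {
  oracle_moderated(x, cond, a, b, d0 = 0, s0_sq = NA_real_)
}

# small two-batch design + matrices built directly (bypassing the simulator)
tiny_batches <- function(values1, values2, proteins = paste0("P", seq_len(nrow(values1)))) {
  rownames(values1) <- rownames(values2) <- proteins
  if (is.null(colnames(values1))) colnames(values1) <- sprintf("C%d", seq_len(ncol(values1)))
  if (is.null(colnames(values2))) colnames(values2) <- sprintf("C%d", seq_len(ncol(values2)))
  list(tmt_matrix(values1, "b1"), tmt_matrix(values2, "b2"))
}

tiny_design <- function(n_bio = 2, n_bridge = 1) {
  rows <- list()
  for (b in c("b1", "b2")) {
    off <- if (b == "b2") n_bio else 0
    for (i in seq_len(n_bio))
      rows[[length(rows) + 1]] <- data.frame(batch = b, channel = sprintf("C%d", i),
                                             tag = sprintf("t%d", i),
                                             sample = sprintf("%s_s%d", b, i),
                                             condition = c("Py-only", "Py/Fu")[1 + (i %% 2)],
                                             replicate = i + off, is_bridge = FALSE)
    for (i in seq_len(n_bridge))
      rows[[length(rows) + 1]] <- data.frame(batch = b, channel = sprintf("C%d", n_bio + i),
                                             tag = sprintf("t%d", n_bio + i),
                                             sample = sprintf("%s_br%d", b, i),
                                             condition = "BRIDGE", replicate = i, is_bridge = TRUE)
  }
  as_tmt_design(do.call(rbind, rows))
}

# pooled end-to-end recovery metrics over seeds (criterion-level helper)
recovery_metrics <- function(seeds, skip_irs = FALSE, ...) {
  errs <- c(); n_sel <- 0; n_fp <- 0; n_reg <- 0; n_tp <- 0
  for (s in seeds) {
    sd <- simulate_dataset(sim_config(seed = s, ...))
    norm <- normalize_pipeline(sd$matrices, sd$design, skip_irs = skip_irs)
    ct <- all_pairwise_contrasts(norm)
    m <- merge(ct$table, truth_contrast_table(sd$truth), by = c("protein", "contrast"))
    errs <- c(errs, abs(m$logFC - m$true_logfc))
    sel <- abs(m$logFC) > 1 & m$fdr < 0.05
    n_sel <- n_sel + sum(sel); n_fp <- n_fp + sum(sel & !m$regulated)
    n_reg <- n_reg + sum(m$regulated); n_tp <- n_tp + sum(sel & m$regulated)
  }
  list(median_err = median(errs),
       fdr = if (n_sel == 0) 0 else n_fp / n_sel,
       sensitivity = n_tp / n_reg)
}
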