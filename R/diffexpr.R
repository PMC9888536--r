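# Per-protein one-way linear model over conditions, empirical-Bayes variance
# moderation, pairwise moderated t contrasts and Benjamini-Hochberg control.

#' Fit per-protein condition means and pooled residual variance
#'
#' Ordinary least squares with a one-way condition layout on the log2 matrix:
#' each condition mean is the replicate average, the residual variance s_g^2
#' is the pooled within-condition variance, and the residual degrees of
#' freedom are `n_samples - n_conditions` (12 for 18 samples in 6 conditions).
#' Bridge channels are excluded.
#'
#' @param norm a `tmt_norm` from [normalize_pipeline()].
#' @return list of class `tmt_fit`: `means` (protein x condition), `s2`
#'   (per-protein residual variance), `df` (residual df, scalar), `n`
#'   (replicates per condition, named).
#' @export
fit_condition_means <- function(norm) {
  stopifnot(inherits(norm, "tmt_norm"))
  d <- norm$design[!norm$design$is_bridge, , drop = FALSE]
  conds <- intersect(norm$conditions, unique(d$condition))
  n <- vapply(conds, function(cc) sum(d$condition == cc), integer(1))
  if (any(n < 2L))
    stop(sprintf("condition '%s' has fewer than 2 replicates", conds[which(n < 2L)[1L]]))
  x <- norm$log2[, d$column_key, drop = FALSE]
  means <- sapply(conds, function(cc) rowMeans(x[, d$condition == cc, drop = FALSE]))
  rss <- rowSums((x - means[, d$condition, drop = FALSE])^2)
  df <- ncol(x) - length(conds)
  structure(list(means = means, s2 = rss / df, df = df, n = n), class = "tmt_fit")
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for `x > 0`; the trigamma
#' function is strictly decreasing there, so the root is unique. Used by
#' [estimate_priors()] to turn the excess spread of log variances into prior
#' degrees of freedom.
#'
#' @param y positive target value (`y <= 0` returns `Inf`).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration bound; non-convergence is an error.
#' @return the unique `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y, tol = 1e-10, max_iter = 100L) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < tol) return(x)
  }
  stop(sprintf("trigamma inversion did not converge for y = %g", y))
}

#' Estimate empirical-Bayes variance prior by moment matching
#'
#' The per-protein log variances `e_g = ln s_g^2 - psi(d_g/2) + ln(d_g/2)`
#' have, under the scaled inverse-chi-square prior with hyperparameters
#' (d0, s0^2), mean `ln s0^2 + psi(d0/2) - ln(d0/2)` and excess variance
#' `psi'(d0/2)` beyond the sampling term `psi'(d_g/2)`. Matching moments gives
#' d0 by inverting the (strictly decreasing) trigamma function; when the
#' excess is <= 0 the prior is degenerate (d0 = Inf, all variances shrunk to
#' a common s0^2).
#'
#' @param s2 per-protein residual variances (>= 10 finite positive values).
#' @param df residual degrees of freedom d_g (scalar).
#' @return list of class `eb_priors`: `d0`, `s0_sq`.
#' @export
estimate_priors <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (any(!ok))
    warning(sprintf("dropping %d non-positive/non-finite variance(s)", sum(!ok)))
  s2 <- s2[ok]
  if (length(s2) < 10L) stop("need at least 10 positive finite variances")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  nvar <- mean((e - ebar)^2) * length(e) / (length(e) - 1)
  target <- nvar - trigamma(df / 2)
  if (target <= 0) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0), class = "eb_priors")
}

#' Moderated t-test for one pairwise contrast
#'
#' Posterior variance `s~^2 = (d0*s0^2 + d_g*s_g^2)/(d0 + d_g)` (the ordinary
#' s_g^2 at d0 = 0; the common s0^2 at d0 = Inf); `logFC = mean_a - mean_b`;
#' `t = logFC / (s~ * sqrt(1/n_a + 1/n_b))`; two-sided p from the t
#' distribution with `d0 + d_g` degrees of freedom (normal limit at Inf).
#'
#' @param fit a `tmt_fit` from [fit_condition_means()].
#' @param priors an `eb_priors` (use `list(d0 = 0)` for no moderation).
#' @param a,b condition labels; the contrast is a vs b.
#' @return data frame: `protein`, `contrast`, `logFC`, `t`, `df`, `p`.
#' @export
moderated_test <- function(fit, priors, a, b) {
  stopifnot(inherits(fit, "tmt_fit"))
  if (!all(c(a, b) %in% colnames(fit$means)))
    stop(sprintf("unknown condition in contrast: %s vs %s", a, b))
  d0 <- priors$d0
  s2_post <- if (is.infinite(d0)) rep(priors$s0_sq, length(fit$s2))
             else if (d0 == 0) fit$s2
             else (d0 * priors$s0_sq + fit$df * fit$s2) / (d0 + fit$df)
  lfc <- fit$means[, a] - fit$means[, b]
  se <- sqrt(s2_post) * sqrt(1 / fit$n[[a]] + 1 / fit$n[[b]])
  t <- lfc / se
  # degenerate zero-variance rows: any difference is exact, none is null
  t[se == 0] <- sign(lfc[se == 0]) * Inf
  t[se == 0 & lfc == 0] <- 0
  df_total <- d0 + fit$df
  p <- 2 * stats::pt(-abs(t), df = df_total)
  data.frame(protein = rownames(fit$means), contrast = contrast_id(a, b),
             logFC = unname(lfc), t = unname(t), df = df_total, p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1, mapped back to the
#' input order. Apply separately within each contrast.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' All pairwise moderated contrasts with per-contrast FDR
#'
#' Fits the one-way model, estimates the moderation prior from all proteins,
#' tests every unordered condition pair once (C(6,2) = 15 for six conditions;
#' `logFC(a,b) = -logFC(b,a)` by construction) and BH-adjusts p-values within
#' each contrast separately.
#'
#' @param norm a `tmt_norm`.
#' @param moderation `TRUE` (default) for empirical-Bayes moderation, `FALSE`
#'   for ordinary t-tests.
#' @return list of class `contrast_table`: `table` (data frame with `protein`,
#'   `contrast`, `logFC`, `t`, `df`, `p`, `fdr`), `priors`, `fit`.
#' @export
all_pairwise_contrasts <- function(norm, moderation = TRUE) {
  fit <- fit_condition_means(norm)
  priors <- if (moderation) estimate_priors(fit$s2, fit$df) else list(d0 = 0, s0_sq = NA_real_)
  conds <- colnames(fit$means)
  pairs <- utils::combn(conds, 2L)
  tabs <- lapply(seq_len(ncol(pairs)), function(k) {
    tt <- moderated_test(fit, priors, pairs[1L, k], pairs[2L, k])
    tt$fdr <- bh_adjust(tt$p)
    tt
  })
  structure(list(table = do.call(rbind, tabs), priors = priors, fit = fit),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("contrast_table: %d proteins x %d contrasts (d0 = %.3g, s0^2 = %.3g)\n",
              nrow(x$fit$means), length(unique(x$table$contrast)),
              x$priors$d0, x$priors$s0_sq))
  invisible(x)
}

#' Write a contrast table as TSV
#'
#' @param contrasts a `contrast_table` or its `table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(contrasts, path) {
  tab <- if (inherits(contrasts, "contrast_table")) contrasts$table else contrasts
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_comment(), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
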