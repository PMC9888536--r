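# The three-step normalization cascade: Sample Loading (per batch), Internal
# Reference Scaling (across batches, via bridge channels), and trimmed mean of
# M-values (across all channels), followed by a log2 transform.

#' Sample Loading normalization
#'
#' Equalizes total reporter signal across the channels of one batch: column j
#' is multiplied by `mean(column sums) / sum(column j)`, so afterwards every
#' column sum equals the grand mean of the original column sums. Corrects
#' pipetting/labeling differences under the assumption of equal total protein
#' load per channel.
#'
#' @param matrix a complete-case [tmt_matrix()] (all values > 0).
#' @return list: `matrix` (scaled), `factors` (named per-channel multipliers).
#' @export
sample_loading_normalize <- function(matrix) {
  if (anyNA(matrix)) stop("sample loading normalization needs a complete-case matrix")
  sums <- colSums(matrix)
  if (any(sums == 0)) stop(sprintf("zero column sum in channel '%s'",
                                   colnames(matrix)[which(sums == 0)[1L]]))
  f <- mean(sums) / sums
  out <- sweep(matrix, 2L, f, `*`)
  list(matrix = tmt_matrix(unclass(out), batch_id(matrix)), factors = f)
}

#' Internal Reference Scaling across batches
#'
#' The pooled bridge channels are identical material in every batch, so for
#' each protein the per-batch bridge mean measures that protein's batch
#' effect. Per protein p and batch b: `bridge_mean(p,b)` combines p's bridge
#' channels within b (arithmetic mean by default); the cross-batch reference
#' is the geometric mean over batches of those bridge means; all of p's
#' intensities in batch b are multiplied by `reference(p)/bridge_mean(p,b)`.
#' Afterwards every protein's bridge means are identical across batches.
#' Proteins with a zero bridge mean in any batch are dropped with a warning.
#'
#' @param matrices list of per-batch SL-normalized [tmt_matrix()] objects with
#'   identical protein sets (complete cases).
#' @param design the `tmt_design` identifying bridge channels.
#' @param bridge_combine within-batch bridge summary: `"arithmetic"` (default)
#'   or `"geometric"` mean.
#' @param reference cross-batch reference: `"geometric"` (default, symmetric in
#'   batch order) or `"arithmetic"` mean of the batch bridge means.
#' @return list: `matrix` (merged [tmt_matrix()], columns `"<batch>.<channel>"`
#'   in design order), `factors` (protein x batch multipliers), `dropped`
#'   (accessions removed for zero bridge means).
#' @export
irs_normalize <- function(matrices, design,
                          bridge_combine = c("arithmetic", "geometric"),
                          reference = c("geometric", "arithmetic")) {
  bridge_combine <- match.arg(bridge_combine)
  reference <- match.arg(reference)
  ids <- vapply(matrices, batch_id, character(1))
  names(matrices) <- ids
  prot <- rownames(matrices[[1L]])
  for (m in matrices)
    if (!identical(rownames(m), prot)) stop("batch matrices must share an identical protein set")

  bm <- sapply(ids, function(b) {
    br <- design$channel[design$batch == b & design$is_bridge]
    if (!length(br)) stop(sprintf("batch '%s' has no bridge channel", b))
    x <- matrices[[b]][, br, drop = FALSE]
    if (bridge_combine == "arithmetic") rowMeans(x) else exp(rowMeans(log(x)))
  })
  bm <- as.matrix(bm)
  rownames(bm) <- prot

  dropped <- prot[apply(bm, 1L, function(v) any(v == 0 | !is.finite(v)))]
  if (length(dropped)) {
    warning(sprintf("dropping %d protein(s) with zero bridge mean: %s",
                    length(dropped), paste(utils::head(dropped, 5L), collapse = ", ")))
    keepi <- !(prot %in% dropped)
    bm <- bm[keepi, , drop = FALSE]
    matrices <- lapply(matrices, function(m) tmt_matrix(unclass(m[keepi, , drop = FALSE]), batch_id(m)))
    prot <- prot[keepi]
  }

  ref <- if (length(ids) == 1L) bm[, 1L]
         else if (reference == "geometric") exp(rowMeans(log(bm)))
         else rowMeans(bm)
  factors <- ref / bm  # protein x batch
  scaled <- lapply(ids, function(b) {
    m <- matrices[[b]] * factors[, b]
    colnames(m) <- paste(b, colnames(matrices[[b]]), sep = ".")
    m
  })
  merged <- do.call(cbind, scaled)
  key <- channel_key(design)
  merged <- merged[, key[key %in% colnames(merged)], drop = FALSE]
  list(matrix = tmt_matrix(unclass(merged), "merged"),
       factors = factors, dropped = dropped)
}

#' Trimmed mean of M-values normalization factors
#'
#' The published TMM algorithm on column-sum-scaled proportions, assuming a
#' majority of non-differentially-abundant proteins. The reference column is
#' the one whose 75th-percentile proportion is closest to the mean of 75th
#' percentiles. For each column, per-protein `M` = log2 ratio of proportions
#' to the reference and `A` = average log2 proportion; rows in the top/bottom
#' `trim_M` quantiles of M or `trim_A` quantiles of A (midpoint-tied ranks)
#' are removed; the column factor is 2^(precision-weighted mean of surviving
#' M), with inverse binomial-approximation variances as weights. Factors are
#' rescaled to geometric mean 1.
#'
#' @param matrix merged, strictly positive intensity matrix.
#' @param trim_M fraction trimmed from each tail of the M distribution.
#' @param trim_A fraction trimmed from each tail of the A distribution.
#' @return list: `factors` (named, geometric mean 1), `ref_column`.
#' @export
tmm_factors <- function(matrix, trim_M = 0.30, trim_A = 0.05) {
  if (anyNA(matrix) || any(matrix < 0)) stop("TMM needs a complete non-negative matrix")
  lib <- colSums(matrix)
  f75 <- apply(matrix, 2L, stats::quantile, probs = 0.75, names = FALSE) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(matrix)), function(j)
    .tmm_pair(matrix[, j], matrix[, ref], lib[j], lib[ref], trim_M, trim_A),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(matrix)
  list(factors = f, ref_column = colnames(matrix)[ref])
}

# one-column TMM factor against the reference column
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < 2L) {
    warning("fewer than 2 rows survive TMM trimming; falling back to untrimmed weighted mean")
    keep <- rep(TRUE, n)
  }
  wt <- 1 / w[keep]
  fin2 <- is.finite(wt) & wt > 0
  2^(sum(M[keep][fin2] * wt[fin2]) / sum(wt[fin2]))
}

#' Apply TMM factors
#'
#' Divides each column by (column factor x column-sum scale), where the
#' column-sum scale is `colSums(matrix)/mean(colSums(matrix))`, preserving the
#' overall intensity magnitude.
#'
#' @param matrix the matrix given to [tmm_factors()].
#' @param tmm result of [tmm_factors()].
#' @return scaled [tmt_matrix()].
#' @export
tmm_normalize <- function(matrix, tmm) {
  lib <- colSums(matrix)
  scale <- tmm$factors * (lib / mean(lib))
  out <- sweep(matrix, 2L, scale, `/`)
  tmt_matrix(unclass(out), if (inherits(matrix, "tmt_matrix")) batch_id(matrix) else "merged")
}

#' Run the full normalization cascade
#'
#' Complete-case filter, Sample Loading per batch, Internal Reference Scaling
#' across batches, TMM across all channels, log2 transform. Bridge channels
#' are retained (flagged) for QC but are meant to be excluded from downstream
#' statistics.
#'
#' @param matrices list of per-batch [tmt_matrix()] objects (raw intensities).
#' @param design the `tmt_design`.
#' @param skip_irs,skip_tmm disable the respective step (factors of 1 recorded
#'   with `skipped = TRUE`).
#' @param trim_M,trim_A TMM trim fractions.
#' @param bridge_combine,reference passed to [irs_normalize()].
#' @return object of class `tmt_norm`: `log2` (protein x channel log2 matrix,
#'   columns `"<batch>.<channel>"`), `design` (rows aligned to columns, with
#'   `column_key`), `applied_steps` (ordered factor records incl. the
#'   complete-case report), `dropped`.
#' @export
normalize_pipeline <- function(matrices, design, skip_irs = FALSE, skip_tmm = FALSE,
                               trim_M = 0.30, trim_A = 0.05,
                               bridge_combine = "arithmetic", reference = "geometric") {
  cc <- complete_case_filter(matrices, design)
  steps <- list(complete_case = cc$report)
  ids <- vapply(matrices, batch_id, character(1))
  prot <- rownames(cc$matrix)
  per_batch <- lapply(ids, function(b) {
    ch <- design$channel[design$batch == b]
    sub <- cc$matrix[, paste(b, ch, sep = "."), drop = FALSE]
    colnames(sub) <- ch
    tmt_matrix(unclass(sub), b)
  })
  names(per_batch) <- ids

  sl <- lapply(per_batch, sample_loading_normalize)
  steps$SL <- lapply(sl, `[[`, "factors")
  sl_mats <- lapply(sl, `[[`, "matrix")

  if (skip_irs) {
    merged <- do.call(cbind, lapply(ids, function(b) {
      m <- sl_mats[[b]]
      colnames(m) <- paste(b, colnames(m), sep = ".")
      unclass(m)
    }))
    merged <- tmt_matrix(merged[, channel_key(design), drop = FALSE], "merged")
    steps$IRS <- list(skipped = TRUE)
    dropped <- character(0)
  } else {
    irs <- irs_normalize(sl_mats, design, bridge_combine = bridge_combine,
                         reference = reference)
    merged <- irs$matrix
    steps$IRS <- list(factors = irs$factors, bridge_combine = bridge_combine,
                      reference = reference)
    dropped <- irs$dropped
  }
  # QC on the merged matrix before TMM: with IRS applied the per-protein
  # bridge means must agree across batches to machine precision
  steps$bridge_qc_max_rel <- .bridge_disagreement(merged, design)

  if (skip_tmm) {
    steps$TMM <- list(skipped = TRUE)
    final <- merged
  } else {
    tmm <- tmm_factors(merged, trim_M = trim_M, trim_A = trim_A)
    steps$TMM <- tmm
    final <- tmm_normalize(merged, tmm)
  }

  d <- as.data.frame(design)
  d$column_key <- channel_key(design)
  d <- d[match(colnames(final), d$column_key), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(log2 = log2(unclass(final)), design = d,
                 conditions = design_conditions(design),
                 applied_steps = steps, dropped = dropped),
            class = "tmt_norm")
}

#' @export
print.tmt_norm <- function(x, ...) {
  cat(sprintf("tmt_norm: %d proteins x %d channels (%d bridge); steps: %s\n",
              nrow(x$log2), ncol(x$log2), sum(x$design$is_bridge),
              paste(setdiff(names(x$applied_steps), "bridge_qc_max_rel"), collapse = " -> ")))
  invisible(x)
}

# max relative cross-batch disagreement of per-protein bridge means on a
# merged linear-scale matrix with "<batch>.<channel>" columns
.bridge_disagreement <- function(merged, design) {
  batches <- unique(design$batch)
  if (length(batches) < 2L) return(0)
  key <- channel_key(design)
  bm <- sapply(batches, function(b) {
    cols <- key[design$batch == b & design$is_bridge]
    rowMeans(merged[, cols, drop = FALSE])
  })
  max(abs(bm / bm[, 1L] - 1))
}

#' Per-protein bridge means on the log2 matrix, per batch (QC helper)
#'
#' @param norm a `tmt_norm`.
#' @return protein x batch matrix of linear-scale bridge means.
#' @export
bridge_means <- function(norm) {
  d <- norm$design
  sapply(unique(d$batch), function(b) {
    cols <- d$column_key[d$batch == b & d$is_bridge]
    rowMeans(2^norm$log2[, cols, drop = FALSE])
  })
}
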