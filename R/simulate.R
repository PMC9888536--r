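# Synthetic two-batch TMT generator with known ground truth.
#
# Signal model (log2 scale) for biological channel (protein p, sample s in
# batch b, channel j):
#   log2 I = baseline_p + effect_{p,cond(s)} + batch_{p,b} + loading_j + noise
# Bridge channels measure the pooled mixture of all biological samples: the
# mixture is formed on the LINEAR scale from the noise-free true signals
# (a pooled sample mixes mass, not logs), then acquires the measuring batch's
# protein-specific batch effect plus its own loading and noise. Dropout is
# independent per (protein, channel).

.default_archetypes <- function(effect) {
  list(
    "constitutive"  = c(),
    "Py-only-up"    = c("Py-only" = effect),
    "H2-up"         = c("H2/Fu" = effect, "H2/ClOHPA" = effect),
    "lactate-up"    = c("La/Fu" = effect, "La/ClOHPA" = effect),
    "ClOHPA-up"     = c("H2/ClOHPA" = effect, "La/ClOHPA" = effect),
    "Py-only-down"  = c("Py-only" = -effect)
  )
}

#' Configuration for the synthetic two-batch TMT generator
#'
#' Defaults reproduce the study layout being emulated: 6 growth conditions x 3
#' replicates = 18 biological samples split over 2 batches of 9, plus 2 bridge
#' channels per batch (22 channels). Replicate `r` of condition number `c` is
#' assigned to batch `1 + ((c + r) mod 2)`, a balanced interleave that puts
#' every condition in both batches. Noise magnitudes are package choices (the
#' emulated study reports none); see the methods vignette.
#'
#' @param n_proteins number of proteins (default 2000; use 4851 for a
#'   proteome-scale run).
#' @param conditions condition labels, in display order.
#' @param n_replicates biological replicates per condition.
#' @param n_batches number of TMT batches.
#' @param bridges_per_batch pooled reference channels per batch.
#' @param fraction_regulated total fraction of proteins carrying a non-zero
#'   condition effect, split equally over the non-constitutive archetypes.
#' @param effect_size_log2 magnitude of planted log2 effects.
#' @param baseline_mean_log2,baseline_sd_log2 normal distribution of the
#'   protein log2 baseline abundance.
#' @param noise_sd_log2 multiplicative log-normal measurement noise (log2 sd),
#'   applied to every channel including bridges.
#' @param channel_loading_sd_log2 per-channel loading factor (log2 sd).
#' @param batch_effect_sd_log2 protein-specific batch effect of batch 2+
#'   relative to batch 1 (log2 sd); identical for all channels within a batch.
#' @param dropout_rate probability that a (protein, channel) measurement is
#'   missing, independent per cell.
#' @param archetypes named list mapping archetype name to a named vector of
#'   condition effects (log2); `NULL` uses the six built-in patterns.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       conditions = c("Py-only", "Py/Fu", "La/Fu",
                                      "H2/Fu", "H2/ClOHPA", "La/ClOHPA"),
                       n_replicates = 3,
                       n_batches = 2,
                       bridges_per_batch = 2,
                       fraction_regulated = 0.10,
                       effect_size_log2 = 1.5,
                       baseline_mean_log2 = 20,
                       baseline_sd_log2 = 2,
                       noise_sd_log2 = 0.25,
                       channel_loading_sd_log2 = 0.3,
                       batch_effect_sd_log2 = 0.5,
                       dropout_rate = 0.05,
                       archetypes = NULL,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), conditions = conditions,
              n_replicates = as.integer(n_replicates), n_batches = as.integer(n_batches),
              bridges_per_batch = as.integer(bridges_per_batch),
              fraction_regulated = fraction_regulated,
              effect_size_log2 = effect_size_log2,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              noise_sd_log2 = noise_sd_log2,
              channel_loading_sd_log2 = channel_loading_sd_log2,
              batch_effect_sd_log2 = batch_effect_sd_log2,
              dropout_rate = dropout_rate,
              archetypes = archetypes, seed = as.integer(seed))
  sds <- c(cfg$baseline_sd_log2, cfg$noise_sd_log2, cfg$channel_loading_sd_log2,
           cfg$batch_effect_sd_log2)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) stop("dropout_rate must be in [0,1]")
  if (cfg$fraction_regulated < 0 || cfg$fraction_regulated > 1)
    stop("fraction_regulated must be in [0,1]")
  if (cfg$n_batches < 1 || cfg$bridges_per_batch < 1)
    stop("need >=1 batch and >=1 bridge channel per batch")
  n_samp <- length(cfg$conditions) * cfg$n_replicates
  if (n_samp %% cfg$n_batches != 0L)
    stop("sample count must divide evenly over batches")
  if (is.null(cfg$archetypes)) {
    cfg$archetypes <- .default_archetypes(cfg$effect_size_log2)
    if (!all(unlist(lapply(cfg$archetypes, names)) %in% cfg$conditions))
      stop("built-in archetypes need the default condition labels; supply `archetypes`")
  }
  bad <- setdiff(unlist(lapply(cfg$archetypes, names)), cfg$conditions)
  if (length(bad)) stop(sprintf("archetype effect on unknown condition: %s", paste(bad, collapse = ", ")))
  class(cfg) <- "sim_config"
  cfg
}

# TMT 11-plex tag labels, recycled if a batch needs more channels
.tmt_tags <- c("126", "127N", "127C", "128N", "128C", "129N",
               "129C", "130N", "130C", "131N", "131C")

#' Study design implied by a simulation configuration
#'
#' Deterministic (no RNG): lays out samples `<condition>_r<replicate>` over
#' batches by the balanced interleave described in [sim_config()], appends the
#' per-batch bridge channels last, and assigns TMT tag labels in channel order.
#'
#' @param config a [sim_config()].
#' @return a `tmt_design`.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- length(config$conditions)
  rows <- list()
  for (ci in seq_len(nc)) for (r in seq_len(config$n_replicates)) {
    b <- 1L + ((ci + r) %% config$n_batches)
    rows[[length(rows) + 1L]] <- data.frame(
      batch = sprintf("batch%d", b),
      sample = sprintf("%s_r%d", config$conditions[ci], r),
      condition = config$conditions[ci], replicate = r,
      is_bridge = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  batches <- sprintf("batch%d", seq_len(config$n_batches))
  per_b <- table(factor(df$batch, levels = batches))
  if (length(unique(as.integer(per_b))) != 1L)
    stop("layout inconsistent with batch assignment: unequal batch sizes")
  out <- list()
  for (b in batches) {
    bio <- df[df$batch == b, , drop = FALSE]
    br <- data.frame(batch = b,
                     sample = sprintf("%s_bridge%d", b, seq_len(config$bridges_per_batch)),
                     condition = BRIDGE, replicate = seq_len(config$bridges_per_batch),
                     is_bridge = TRUE, stringsAsFactors = FALSE)
    blk <- rbind(bio, br)
    blk$channel <- sprintf("C%02d", seq_len(nrow(blk)))
    blk$tag <- rep_len(.tmt_tags, nrow(blk))
    out[[b]] <- blk
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  as_tmt_design(df[, c("batch", "channel", "tag", "sample", "condition",
                       "replicate", "is_bridge")],
                conditions = config$conditions)
}

#' Simulate a multi-batch TMT dataset with known truth
#'
#' @param config a [sim_config()].
#' @return list with `matrices` (per-batch [tmt_matrix()], dropout as `NA`),
#'   `design` (a `tmt_design`) and `truth` (class `sim_truth`): per-protein
#'   `archetype`, `baseline`, `effects` (protein x condition log2 matrix),
#'   `batch_effect` (protein x batch, batch 1 = 0), `channel_loading` (named
#'   by `"<batch>.<channel>"`), and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- sim_design(config)
  conds <- config$conditions
  n <- config$n_proteins
  prot <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
  set.seed(config$seed)

  arche_names <- names(config$archetypes)
  reg_names <- arche_names[vapply(config$archetypes, length, integer(1)) > 0L]
  n_reg <- round(n * config$fraction_regulated)
  per <- n_reg %/% length(reg_names)
  counts <- stats::setNames(rep(per, length(reg_names)), reg_names)
  extra <- n_reg - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  labels <- c(rep(names(counts), counts), rep("constitutive", n - sum(counts)))
  archetype <- sample(labels)  # random placement among proteins

  effects <- matrix(0, n, length(conds), dimnames = list(prot, conds))
  for (a in reg_names) {
    eff <- config$archetypes[[a]]
    effects[archetype == a, names(eff)] <- matrix(rep(eff, each = sum(archetype == a)),
                                                  ncol = length(eff))
  }

  baseline <- stats::rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2)
  names(baseline) <- prot

  batches <- unique(design$batch)
  batch_effect <- matrix(0, n, length(batches), dimnames = list(prot, batches))
  if (length(batches) > 1L)
    for (b in batches[-1L])
      batch_effect[, b] <- stats::rnorm(n, 0, config$batch_effect_sd_log2)

  key <- channel_key(design)
  loading <- stats::rnorm(nrow(design), 0, config$channel_loading_sd_log2)
  names(loading) <- key

  bio <- design[!design$is_bridge, , drop = FALSE]
  # noise-free true linear signal per biological sample (pre batch/loading)
  true_lin <- 2^(baseline + effects[, bio$condition, drop = FALSE])
  colnames(true_lin) <- bio$sample
  bridge_lin <- rowMeans(true_lin)  # mixture of all biological samples

  matrices <- list()
  for (b in batches) {
    rows_b <- design[design$batch == b, , drop = FALSE]
    kb <- paste(b, rows_b$channel, sep = ".")
    noise <- matrix(stats::rnorm(n * nrow(rows_b), 0, config$noise_sd_log2), n, nrow(rows_b))
    m <- matrix(NA_real_, n, nrow(rows_b), dimnames = list(prot, rows_b$channel))
    for (j in seq_len(nrow(rows_b))) {
      base_lin <- if (rows_b$is_bridge[j]) bridge_lin else true_lin[, rows_b$sample[j]]
      m[, j] <- base_lin * 2^(batch_effect[, b] + loading[kb[j]] + noise[, j])
    }
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * ncol(m)) < config$dropout_rate, n, ncol(m))
      m[drop] <- NA_real_
    }
    matrices[[b]] <- tmt_matrix(m, b)
  }

  truth <- structure(list(archetype = stats::setNames(archetype, prot),
                          baseline = baseline, effects = effects,
                          batch_effect = batch_effect, channel_loading = loading,
                          config = config),
                     class = "sim_truth")
  list(matrices = matrices, design = design, truth = truth)
}

#' True pairwise log2 fold-changes implied by simulation truth
#'
#' For conditions a, b (a before b in the configured order),
#' `true_logfc(a vs b) = effect_a - effect_b`; 15 contrasts for 6 conditions.
#' The `regulated` flag marks `|true_logfc| > 0`.
#'
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @return data frame: `protein`, `contrast` (`"a_vs_b"`), `true_logfc`,
#'   `regulated`.
#' @export
truth_contrast_table <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  conds <- truth$config$conditions
  pairs <- utils::combn(conds, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    lfc <- truth$effects[, a] - truth$effects[, b]
    data.frame(protein = rownames(truth$effects),
               contrast = contrast_id(a, b),
               true_logfc = unname(lfc),
               regulated = abs(lfc) > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contrast identifier
#'
#' @param a,b condition labels (slashes preserved).
#' @return `"a_vs_b"`.
#' @export
contrast_id <- function(a, b) paste(a, b, sep = "_vs_")
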