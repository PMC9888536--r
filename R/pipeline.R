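# Orchestration: one configuration drives simulate/read -> filter -> normalize
# -> test -> select -> cluster -> PCA, writing every intermediate TSV and a
# run report whose numbers are all recomputable from the emitted artifacts.

#' Run configuration
#'
#' Either `sim` (a [sim_config()]) for synthetic input or `batch_paths` +
#' `design_path` for TSV input. Selection analyses default to the two-batch
#' study layout: any-vs-all around the fermentative condition, the
#' electron-donor quadrant, and the strict electron-acceptor group rule.
#'
#' @param sim optional [sim_config()].
#' @param batch_paths named character vector (names = batch ids) of intensity
#'   TSVs; ignored when `sim` is given.
#' @param design_path design TSV; ignored when `sim` is given.
#' @param outdir output directory.
#' @param rule a [selection_rule()].
#' @param skip_irs,skip_tmm normalization switches.
#' @param focal any-vs-all focal condition (`NULL` for first condition).
#' @param quadrant list of two contrast pairs `list(c(a,b), c(c,d))` or `NULL`
#'   for the default donor comparison.
#' @param strict_groups list of two disjoint condition groups or `NULL` for
#'   the default acceptor comparison.
#' @param k number of heatmap clusters.
#' @param database_size optional proteome size for the coverage figure.
#' @param seed seed forwarded to the simulator when `sim` lacks one.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, batch_paths = NULL, design_path = NULL,
                       outdir = tempfile("tmtbridge_run_"),
                       rule = selection_rule(),
                       skip_irs = FALSE, skip_tmm = FALSE,
                       focal = NULL, quadrant = NULL, strict_groups = NULL,
                       k = 9, database_size = NULL, seed = NULL) {
  if (is.null(sim) && (is.null(batch_paths) || is.null(design_path)))
    stop("config error: need either `sim` or `batch_paths` + `design_path`")
  if (!is.null(sim) && !inherits(sim, "sim_config")) stop("config error: `sim` must be a sim_config")
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, batch_paths = batch_paths, design_path = design_path,
                 outdir = outdir, rule = rule, skip_irs = skip_irs,
                 skip_tmm = skip_tmm, focal = focal, quadrant = quadrant,
                 strict_groups = strict_groups, k = k,
                 database_size = database_size), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected. The `sim:` block takes [sim_config()] arguments;
#' top-level keys mirror [run_config()] arguments with `rule:` as a block of
#' [selection_rule()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("sim", "batch_paths", "design_path", "outdir", "rule", "skip_irs",
             "skip_tmm", "focal", "quadrant", "strict_groups", "k",
             "database_size", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop(sprintf("config error: unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  if (!is.null(y$sim)) {
    bad <- setdiff(names(y$sim), names(formals(sim_config)))
    if (length(bad)) stop(sprintf("config error: unknown sim key(s): %s",
                                  paste(bad, collapse = ", ")))
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$rule)) y$rule <- do.call(selection_rule, y$rule)
  if (!is.null(y$batch_paths)) y$batch_paths <- unlist(y$batch_paths)
  do.call(run_config, y)
}

#' Percentage of a protein database covered by the quantified set
#'
#' The headline figure is rounded to the nearest integer; the exact value is
#' kept alongside.
#'
#' @param quantified number of quantified proteins (0 <= quantified <= size).
#' @param database_size number of sequences in the database (> 0).
#' @return list: `percent` (rounded), `exact`.
#' @export
proteome_coverage <- function(quantified, database_size) {
  if (database_size <= 0) stop("database size must be > 0")
  if (quantified < 0 || quantified > database_size)
    stop("quantified count must lie in [0, database size]")
  exact <- 100 * quantified / database_size
  list(percent = round(exact), exact = exact)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate/read, complete-case filtering, the normalization cascade,
#' all pairwise moderated contrasts, the configured selection analyses,
#' Z-score clustering of the regulated subset (proteins passing the rule in
#' either direction in at least one contrast) and sample PCA. Every
#' intermediate table is written under `config$outdir`; the returned report's
#' numbers are recomputable from those files. Fully reproducible from
#' (config, seed).
#'
#' @param config a [run_config()].
#' @return list of class `run_report`; see its fields.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$sim)) {
    simd <- .stage("simulate", simulate_dataset(config$sim))
    matrices <- simd$matrices; design <- simd$design; truth <- simd$truth
    for (b in names(matrices))
      write_intensity_table(matrices[[b]], file.path(config$outdir, sprintf("intensities_%s.tsv", b)))
    write_design(design, file.path(config$outdir, "design.tsv"))
  } else {
    design <- .stage("read", read_design(config$design_path))
    matrices <- .stage("read", lapply(stats::setNames(names(config$batch_paths), names(config$batch_paths)),
                                      function(b) read_intensity_table(config$batch_paths[[b]], b)))
  }

  cc <- .stage("filter", complete_case_filter(matrices, design))
  norm <- .stage("normalize",
                 normalize_pipeline(matrices, design, skip_irs = config$skip_irs,
                                    skip_tmm = config$skip_tmm))
  norm_out <- data.frame(protein = rownames(norm$log2), norm$log2,
                         check.names = FALSE)
  con <- file(file.path(config$outdir, "normalized_log2.tsv"), "wt", encoding = "UTF-8")
  writeLines(.provenance_comment(), con)
  utils::write.table(norm_out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  # QC: after IRS (pre-TMM) per-protein bridge means must agree across batches
  bridge_qc <- norm$applied_steps$bridge_qc_max_rel
  bridge_qc_pass <- bridge_qc < 1e-6

  contrasts <- .stage("test", all_pairwise_contrasts(norm))
  write_contrasts(contrasts, file.path(config$outdir, "contrasts.tsv"))

  conds <- norm$conditions
  focal <- if (is.null(config$focal)) conds[1L] else config$focal
  sets <- list()
  av <- .stage("select", any_vs_all_partition(contrasts, focal, setdiff(conds, focal), config$rule))
  sets[[sprintf("%s_any_up_union", focal)]] <- av$union
  sets[[sprintf("%s_all_up_intersection", focal)]] <- av$intersection

  quadrant <- config$quadrant
  if (is.null(quadrant) && all(c("H2/Fu", "La/Fu", "H2/ClOHPA", "La/ClOHPA") %in% conds))
    quadrant <- list(c("H2/Fu", "La/Fu"), c("H2/ClOHPA", "La/ClOHPA"))
  quad <- NULL
  if (!is.null(quadrant)) {
    quad <- .stage("select", quadrant_select(contrasts,
                                             contrast_id(quadrant[[1L]][1L], quadrant[[1L]][2L]),
                                             contrast_id(quadrant[[2L]][1L], quadrant[[2L]][2L]),
                                             config$rule))
    sets$quadrant_both_up <- quad$both_up
    sets$quadrant_both_down <- quad$both_down
  }

  strict_groups <- config$strict_groups
  if (is.null(strict_groups) && all(c("H2/ClOHPA", "La/ClOHPA") %in% conds))
    strict_groups <- list(c("H2/ClOHPA", "La/ClOHPA"),
                          setdiff(conds, c("H2/ClOHPA", "La/ClOHPA")))
  strict <- NULL
  if (!is.null(strict_groups)) {
    strict <- .stage("select", strict_group_select(contrasts, strict_groups[[1L]],
                                                   strict_groups[[2L]], config$rule))
    sets$strict_group_up <- strict
  }
  write_selection_sets(sets, file.path(config$outdir, "sets"))

  both_rule <- selection_rule(config$rule$logfc_threshold, config$rule$fdr_threshold, "both")
  regulated <- sort(unique(unlist(lapply(unique(contrasts$table$contrast),
                                         function(id) select_proteins(contrasts, id, both_rule)))))
  clustering <- NULL
  z <- NULL
  if (length(regulated) >= config$k) {
    z <- zscore_rows(structure(list(log2 = norm$log2[regulated, , drop = FALSE],
                                    design = norm$design), class = "tmt_norm"))
    clustering <- .stage("cluster", hcluster_cut(z, k = config$k))
    heatmap_export(z, clustering, file.path(config$outdir, "heatmap_zscores.tsv"))
  }

  pca <- .stage("pca", pca_samples(norm))
  pca_df <- data.frame(sample = rownames(pca$scores),
                       pca$scores[, seq_len(min(4L, ncol(pca$scores))), drop = FALSE],
                       check.names = FALSE)
  con <- file(file.path(config$outdir, "pca_scores.tsv"), "wt", encoding = "UTF-8")
  writeLines(.provenance_comment(), con)
  utils::write.table(pca_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  report <- list(
    detected = cc$report$detected,
    quantified = cc$report$quantified,
    coverage = if (!is.null(config$database_size))
      proteome_coverage(cc$report$quantified, config$database_size) else NULL,
    applied_steps = setdiff(names(norm$applied_steps), "bridge_qc_max_rel"),
    bridge_qc_max_rel_disagreement = bridge_qc,
    bridge_qc_pass = bridge_qc_pass,
    priors = contrasts$priors[c("d0", "s0_sq")],
    n_regulated = length(regulated),
    set_sizes = vapply(sets, length, integer(1)),
    cluster_sizes = if (is.null(clustering)) integer(0) else clustering$sizes,
    pca_explained = pca$explained,
    pca_pc12_percent = round(100 * sum(pca$explained[1:2])),
    outdir = config$outdir)
  out <- list(report = report, norm = norm, contrasts = contrasts,
              sets = sets, any_vs_all = av, quadrant = quad, strict = strict,
              clustering = clustering, zscores = z, pca = pca, truth = truth)
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("run_report: %d detected, %d quantified complete-case", r$detected, r$quantified))
  if (!is.null(r$coverage)) cat(sprintf(" (%d%% of database)", r$coverage$percent))
  cat(sprintf("\n  steps: %s | bridge QC %s\n", paste(r$applied_steps, collapse = " -> "),
              if (r$bridge_qc_pass) "pass" else "FAIL"))
  cat(sprintf("  regulated proteins: %d; PCA PC1+PC2: %d%%\n", r$n_regulated, r$pca_pc12_percent))
  if (length(r$set_sizes))
    cat(sprintf("  sets: %s\n", paste(sprintf("%s=%d", names(r$set_sizes), r$set_sizes), collapse = ", ")))
  invisible(x)
}
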