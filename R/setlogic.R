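# Regulated-protein set constructions: thresholding, any-vs-all union and
# intersection, quadrant classification over two parallel contrasts, strict
# group selection, and fold-change display formatting.

#' Selection rule for regulated proteins
#'
#' Strict inequalities at both thresholds: a protein passes "up" when
#' `logFC > logfc_threshold` and `fdr < fdr_threshold` (two-fold at the
#' default 1.0 on the log2 scale), "down" when `logFC < -logfc_threshold`
#' and `fdr < fdr_threshold`, "both" when either holds.
#'
#' @param logfc_threshold positive log2 threshold (default 1).
#' @param fdr_threshold FDR cutoff in (0, 1) (default 0.05).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return list of class `selection_rule`.
#' @export
selection_rule <- function(logfc_threshold = 1.0, fdr_threshold = 0.05,
                           direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (logfc_threshold <= 0) stop("logfc_threshold must be > 0")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) stop("fdr_threshold must be in (0, 1)")
  structure(list(logfc_threshold = logfc_threshold, fdr_threshold = fdr_threshold,
                 direction = direction), class = "selection_rule")
}

.contrast_df <- function(contrasts) {
  if (inherits(contrasts, "contrast_table")) contrasts$table else contrasts
}

.rule_pass <- function(logfc, fdr, rule) {
  sig <- fdr < rule$fdr_threshold
  up <- logfc > rule$logfc_threshold
  dn <- logfc < -rule$logfc_threshold
  switch(rule$direction, up = sig & up, down = sig & dn, both = sig & (up | dn))
}

#' Select regulated proteins in one contrast
#'
#' @param contrasts a `contrast_table` (or its data frame).
#' @param contrast contrast id, e.g. `contrast_id("Py-only", "Py/Fu")`.
#' @param rule a [selection_rule()].
#' @return sorted character vector of member accessions.
#' @export
select_proteins <- function(contrasts, contrast, rule = selection_rule()) {
  tab <- .contrast_df(contrasts)
  sub <- tab[tab$contrast == contrast, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("unknown contrast '%s'", contrast))
  sort(sub$protein[.rule_pass(sub$logFC, sub$fdr, rule)])
}

# orient a stored contrast so that `focal` is on the left
.oriented_pass <- function(tab, focal, other, rule) {
  id1 <- contrast_id(focal, other)
  id2 <- contrast_id(other, focal)
  if (any(tab$contrast == id1)) {
    sub <- tab[tab$contrast == id1, , drop = FALSE]
    lfc <- sub$logFC
  } else if (any(tab$contrast == id2)) {
    sub <- tab[tab$contrast == id2, , drop = FALSE]
    lfc <- -sub$logFC
  } else stop(sprintf("no contrast between '%s' and '%s'", focal, other))
  sub$protein[.rule_pass(lfc, sub$fdr, rule)]
}

# split "a_vs_b" into its two condition labels; the table itself is the
# authority on which ids exist, so we match against it (condition labels may
# contain slashes but never the literal "_vs_" separator)
.parse_contrast <- function(tab, id) {
  if (any(tab$contrast == id)) {
    parts <- strsplit(id, "_vs_", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) return(parts)
  }
  # id may be stated in the opposite orientation to the stored table
  parts <- strsplit(id, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) == 2L &&
      any(tab$contrast == contrast_id(parts[2L], parts[1L]))) return(parts)
  stop(sprintf("unknown contrast '%s'", id))
}

#' Any-vs-all partition for one focal condition
#'
#' Union = proteins passing the rule against at least one other condition
#' (a Venn union over the per-comparison sets); intersection = proteins
#' passing against every other condition. Contrasts are oriented so the focal
#' condition is on the left regardless of stored order.
#'
#' @param contrasts a `contrast_table`.
#' @param focal focal condition label.
#' @param others other condition labels (must exclude `focal`).
#' @param rule a [selection_rule()].
#' @return list: `union`, `per_comparison` (named by other condition),
#'   `intersection` — sorted accession vectors.
#' @export
any_vs_all_partition <- function(contrasts, focal, others, rule = selection_rule()) {
  if (!length(others)) stop("`others` must be non-empty")
  if (focal %in% others) stop("`focal` must not appear in `others`")
  tab <- .contrast_df(contrasts)
  per <- lapply(others, function(o) sort(.oriented_pass(tab, focal, o, rule)))
  names(per) <- others
  list(union = sort(Reduce(union, per)),
       per_comparison = per,
       intersection = sort(Reduce(intersect, per)))
}

#' Quadrant selection over two parallel contrasts
#'
#' Classifies proteins by joint direction in two contrasts sharing an
#' orientation (e.g. H2 vs lactate under each of two electron acceptors):
#' `both_up` passes the up rule in both, `both_down` the down rule in both,
#' and `mixed` collects proteins significant and beyond threshold in both but
#' with opposite directions (the off-diagonal scatter-plot corners).
#'
#' @param contrasts a `contrast_table`.
#' @param pair1,pair2 contrast ids (distinct).
#' @param rule a [selection_rule()]; its `direction` is overridden per corner.
#' @return list: `both_up`, `both_down`, `mixed`.
#' @export
quadrant_select <- function(contrasts, pair1, pair2, rule = selection_rule()) {
  if (identical(pair1, pair2)) stop("the two contrasts must differ")
  tab <- .contrast_df(contrasts)
  up_rule <- selection_rule(rule$logfc_threshold, rule$fdr_threshold, "up")
  dn_rule <- selection_rule(rule$logfc_threshold, rule$fdr_threshold, "down")
  c1 <- .parse_contrast(tab, pair1); c2 <- .parse_contrast(tab, pair2)
  up1 <- .oriented_pass(tab, c1[1], c1[2], up_rule)
  dn1 <- .oriented_pass(tab, c1[1], c1[2], dn_rule)
  up2 <- .oriented_pass(tab, c2[1], c2[2], up_rule)
  dn2 <- .oriented_pass(tab, c2[1], c2[2], dn_rule)
  list(both_up = sort(intersect(up1, up2)),
       both_down = sort(intersect(dn1, dn2)),
       mixed = sort(union(intersect(up1, dn2), intersect(dn1, up2))))
}

#' Strict group-vs-group selection
#'
#' Proteins passing the rule in every A x B contrast (with A on the left), e.g.
#' both electron-acceptor conditions against all four others (2 x 4 = 8
#' comparisons).
#'
#' @param contrasts a `contrast_table`.
#' @param group_a,group_b disjoint non-empty condition groups.
#' @param rule a [selection_rule()].
#' @return sorted accession vector.
#' @export
strict_group_select <- function(contrasts, group_a, group_b, rule = selection_rule()) {
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  tab <- .contrast_df(contrasts)
  sets <- list()
  for (a in group_a) for (b in group_b)
    sets[[length(sets) + 1L]] <- .oriented_pass(tab, a, b, rule)
  sort(Reduce(intersect, sets))
}

#' Format a log2 fold-change as a display ratio
#'
#' `ratio = 2^|logFC|`, rendered to the nearest integer when >= 2 and to one
#' decimal (decimal point, never comma) when < 2. Down-regulation (negative
#' logFC) is flagged and displayed as the reciprocal magnitude.
#'
#' @param logfc finite log2 fold-changes.
#' @return data frame: `logfc`, `display` (character ratio of the magnitude),
#'   `direction` (`"up"`/`"down"`).
#' @export
fold_change_format <- function(logfc) {
  if (any(!is.finite(logfc))) stop("logFC must be finite")
  ratio <- 2^abs(logfc)
  display <- ifelse(ratio >= 2, sprintf("%.0f", ratio), sprintf("%.1f", ratio))
  data.frame(logfc = logfc, display = display,
             direction = ifelse(logfc < 0, "down", "up"),
             stringsAsFactors = FALSE)
}

#' Write selection sets as TSVs plus a membership matrix
#'
#' One `<name>.tsv` per set (accession per line) and `membership.tsv`, a
#' protein x set 0/1 table over the union of members.
#'
#' @param sets named list of accession vectors.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_selection_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9._-]", "_", names(sets))
  for (i in seq_along(sets))
    writeLines(c(.provenance_comment(), sets[[i]]), file.path(dir, paste0(safe[i], ".tsv")))
  all_p <- sort(unique(unlist(sets)))
  memb <- sapply(sets, function(s) as.integer(all_p %in% s))
  if (length(all_p) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  df <- data.frame(protein = all_p, memb, check.names = FALSE)
  con <- file(file.path(dir, "membership.tsv"), open = "wt", encoding = "UTF-8")
  writeLines(.provenance_comment(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(dir)
}
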