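# Z-scoring, Euclidean hierarchical clustering with a k-cluster cut, PCA of
# samples, and heatmap-order export.

#' Row-wise Z-scores
#'
#' Each row is centered by its mean and scaled by its sample standard
#' deviation (n-1 denominator), so non-constant rows have mean 0 and sd 1.
#' Positive scores mark channels where the protein is more abundant than its
#' own average. Constant rows become all-zero, with a warning listing them.
#'
#' @param x numeric matrix with >= 2 columns (proteins in rows); a `tmt_norm`
#'   is accepted, in which case its biological (non-bridge) log2 columns are
#'   used.
#' @return Z-score matrix with attribute `constant_rows`.
#' @export
zscore_rows <- function(x) {
  if (inherits(x, "tmt_norm")) {
    keep <- !x$design$is_bridge
    x <- x$log2[, x$design$column_key[keep], drop = FALSE]
  }
  if (ncol(x) < 2L) stop("Z-scoring needs at least 2 columns")
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  if (any(const))
    warning(sprintf("%d constant row(s) set to zero Z-scores: %s", sum(const),
                    paste(utils::head(rownames(x)[const], 5L), collapse = ", ")))
  sd[const] <- 1
  z <- (x - mu) / sd
  attr(z, "constant_rows") <- rownames(x)[const]
  z
}

#' Hierarchical clustering with a k-group cut
#'
#' Agglomerative clustering of rows on Euclidean distances. Rows are first
#' ordered lexicographically by id so the partition does not depend on input
#' row order; the tree is cut into exactly `k` groups and cluster indices are
#' relabelled by decreasing size (ties broken by the smallest member id).
#'
#' @param z numeric matrix (typically row Z-scores) with rownames.
#' @param k number of clusters (`<= nrow(z)`).
#' @param linkage `hclust` agglomeration method (default `"complete"`).
#' @return list of class `cluster_assignment`: `cluster` (named 1..k vector),
#'   `tree` (the `hclust` object), `k`, `sizes`.
#' @export
hcluster_cut <- function(z, k = 9, linkage = "complete") {
  if (is.null(rownames(z))) stop("rows must be named")
  if (k > nrow(z)) stop(sprintf("k = %d exceeds the %d rows", k, nrow(z)))
  z <- z[order(rownames(z)), , drop = FALSE]
  tree <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first_id <- vapply(names(sizes), function(g) min(names(raw)[raw == g]), character(1))
  ord <- order(-as.integer(sizes), first_id)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes)[ord])] <- seq_along(ord)
  cl <- stats::setNames(relabel[raw], names(raw))
  structure(list(cluster = cl, tree = tree, k = k,
                 sizes = as.integer(table(cl))), class = "cluster_assignment")
}

#' PCA of samples in protein space
#'
#' Samples are observations, proteins variables; columns (proteins) are
#' centered, not scaled. Explained-variance fractions sum to 1.
#'
#' @param x numeric matrix (proteins x samples) or a `tmt_norm`.
#' @param include_bridges for a `tmt_norm`, keep the bridge channels (useful
#'   to check that the pooled mixtures sit centrally); default `TRUE`.
#' @return list: `scores` (samples x components), `explained` (fractions),
#'   `prcomp` (the full fit).
#' @export
pca_samples <- function(x, include_bridges = TRUE) {
  if (inherits(x, "tmt_norm")) {
    keep <- if (include_bridges) rep(TRUE, nrow(x$design)) else !x$design$is_bridge
    x <- x$log2[, x$design$column_key[keep], drop = FALSE]
  }
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  list(scores = fit$x, explained = ev / sum(ev), prcomp = fit)
}

#' Export a clustered heatmap matrix
#'
#' Writes a TSV mirror of the plotted matrix with rows in dendrogram leaf
#' order and a `cluster` annotation column, and optionally renders a PNG
#' (rows in leaf order, one tick per cluster boundary). The TSV is
#' deterministic: re-running with the same inputs is byte-identical.
#'
#' @param z the Z-score matrix given to [hcluster_cut()].
#' @param assignment the corresponding `cluster_assignment`.
#' @param tsv_path output TSV path.
#' @param fig_path optional PNG path (`NULL` to skip rendering).
#' @return the leaf-ordered matrix, invisibly.
#' @export
heatmap_export <- function(z, assignment, tsv_path, fig_path = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  leaf <- assignment$tree$labels[assignment$tree$order]
  zo <- z[leaf, , drop = FALSE]
  cl <- assignment$cluster[leaf]
  df <- data.frame(protein = leaf, cluster = unname(cl),
                   zo, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(tsv_path, open = "wt", encoding = "UTF-8")
  writeLines(.provenance_comment(), con)
  num <- vapply(df[-(1:2)], function(col) sprintf("%.10g", col), character(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  writeLines(paste(c("protein", "cluster", colnames(zo)), collapse = "\t"), con)
  writeLines(paste(df$protein, df$cluster, apply(num, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  close(con)
  if (!is.null(fig_path)) {
    grDevices::png(fig_path, width = 900, height = 1200)
    on.exit(grDevices::dev.off(), add = TRUE)
    pal <- grDevices::hcl.colors(51, "Blue-Red 3")
    graphics::image(t(zo[rev(seq_len(nrow(zo))), , drop = FALSE]),
                    col = pal, axes = FALSE,
                    main = sprintf("Row Z-scores, %d clusters", assignment$k))
    bnd <- cumsum(rev(rle(unname(cl))$lengths)) / nrow(zo)
    graphics::abline(h = bnd[-length(bnd)], col = "black", lwd = 0.5)
  }
  invisible(zo)
}
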