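# Domain containers and TSV plumbing: intensity matrices, study designs and
# the complete-case filter that defines the analyzable protein set.

#' Construct a per-batch intensity matrix
#'
#' A thin S3 wrapper around a numeric matrix of non-negative reporter-ion
#' intensities (rows = protein accessions, columns = channel labels) tagged
#' with its batch identifier. Missing quantifications are `NA`; a stored 0 is
#' treated as "not quantified" on input (see [read_intensity_table()]).
#'
#' @param values numeric matrix with unique rownames (accessions) and unique
#'   colnames (channel labels); values must be `NA` or >= 0.
#' @param batch_id scalar batch identifier.
#' @return an object of class `tmt_matrix` (a matrix with a `batch_id`
#'   attribute).
#' @export
tmt_matrix <- function(values, batch_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("protein accessions (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("channel labels (colnames) must be present and unique")
  if (any(values < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (length(batch_id) != 1L) stop("`batch_id` must be a scalar")
  structure(values, batch_id = as.character(batch_id), class = c("tmt_matrix", class(values)))
}

#' @export
print.tmt_matrix <- function(x, ...) {
  cat(sprintf("tmt_matrix: batch '%s', %d proteins x %d channels, %d missing\n",
              attr(x, "batch_id"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

batch_id <- function(x) attr(x, "batch_id")

#' Read a protein-level reporter intensity table
#'
#' Tab-separated, UTF-8, '.' decimal file with a header row of channel labels
#' and protein accessions in the first column. Empty cells and zeros are both
#' recorded as missing (`NA`): a reporter intensity of 0 is not a usable
#' measurement. Lines starting with `#` are treated as comments.
#'
#' @param path file path.
#' @param batch_id batch identifier attached to the matrix.
#' @return a [tmt_matrix()].
#' @export
read_intensity_table <- function(path, batch_id) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed intensity table: need accession column plus >=1 channel")
  acc <- as.character(df[[1L]])
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    stop(sprintf("duplicate protein accession(s): %s", paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("malformed intensity table: non-numeric values")
  bad <- which(vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative intensity at row '%s', column '%s'",
                 acc[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  vals[!is.na(vals) & vals == 0] <- NA_real_
  rownames(vals) <- acc
  tmt_matrix(vals, batch_id)
}

#' Write an intensity table
#'
#' Inverse of [read_intensity_table()]: values are printed with the `%.17g`
#' format so a write/read round trip reproduces doubles exactly; `NA` becomes
#' an empty cell. A `#` comment line records the package version (and an
#' optional configuration hash) for provenance.
#'
#' @param x a [tmt_matrix()] or plain numeric matrix with dimnames.
#' @param path output file path.
#' @param config_hash optional string recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_comment(config_hash), con)
  writeLines(paste(c("accession", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(ifelse(is.na(r), "", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

.provenance_comment <- function(config_hash = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("tmtbridge")), error = function(e) "dev")
  h <- if (is.null(config_hash)) "" else sprintf(" config=%s", config_hash)
  sprintf("# tmtbridge %s%s", v, h)
}

.known_conditions <- c("Py-only", "Py/Fu", "La/Fu", "H2/Fu", "H2/ClOHPA", "La/ClOHPA")
BRIDGE <- "BRIDGE"

#' Validate and construct a study design
#'
#' One row per channel with columns `batch`, `channel`, `tag`, `sample`,
#' `condition`, `replicate`, `is_bridge`. Bridge channels carry condition
#' `"BRIDGE"`. Enforced invariants: unique (batch, channel); at least one
#' bridge channel in every batch; unique (batch, sample) for non-bridge
#' channels; every replicate of every condition present exactly once across
#' batches.
#'
#' @param df data frame of channel annotations.
#' @param conditions allowed condition labels (besides `"BRIDGE"`). Defaults
#'   to the six growth conditions of the two-batch layout.
#' @return `df` with class `tmt_design`.
#' @export
as_tmt_design <- function(df, conditions = NULL) {
  need <- c("batch", "channel", "tag", "sample", "condition", "replicate", "is_bridge")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("design lacks column(s): %s", paste(miss, collapse = ", ")))
  df$batch <- as.character(df$batch)
  df$channel <- as.character(df$channel)
  df$sample <- as.character(df$sample)
  df$condition <- as.character(df$condition)
  df$is_bridge <- as.logical(df$is_bridge)
  df$replicate <- as.integer(df$replicate)
  if (is.null(conditions)) {
    conditions <- setdiff(unique(df$condition), BRIDGE)
    known_first <- intersect(.known_conditions, conditions)
    conditions <- c(known_first, setdiff(conditions, known_first))
  }
  unknown <- setdiff(df$condition, c(conditions, BRIDGE))
  if (length(unknown))
    stop(sprintf("unknown condition label(s): %s", paste(unique(unknown), collapse = ", ")))
  if (any(df$is_bridge & df$condition != BRIDGE) || any(!df$is_bridge & df$condition == BRIDGE))
    stop("bridge flag and 'BRIDGE' condition label must agree")
  if (anyDuplicated(df[c("batch", "channel")]))
    stop("duplicate (batch, channel) pair in design")
  for (b in unique(df$batch))
    if (!any(df$is_bridge[df$batch == b]))
      stop(sprintf("batch '%s' has no bridge channel", b))
  bio <- df[!df$is_bridge, ]
  if (anyDuplicated(bio[c("batch", "sample")]))
    stop("duplicate (batch, sample) pair among biological channels")
  if (anyDuplicated(bio[c("condition", "replicate")]))
    stop("duplicate (condition, replicate) among biological channels")
  attr(df, "conditions") <- conditions
  class(df) <- c("tmt_design", "data.frame")
  df
}

#' Read a study design table
#'
#' @param path tab-separated file with the columns documented in
#'   [as_tmt_design()].
#' @param conditions allowed condition labels; `NULL` takes them from the file.
#' @return a `tmt_design` data frame.
#' @export
read_design <- function(path, conditions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  as_tmt_design(df, conditions = conditions)
}

#' Write a study design table
#'
#' @param design a `tmt_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_comment(), con)
  utils::write.table(as.data.frame(design), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

design_conditions <- function(design) attr(design, "conditions")

# channel key used for merged matrices: "<batch>.<channel>"
channel_key <- function(design) paste(design$batch, design$channel, sep = ".")

#' Complete-case filter across batches
#'
#' Keeps only proteins with a positive quantification in every channel of
#' every batch — the analyzable set for bridge-based cross-batch scaling —
#' and merges the batches into one matrix with `"<batch>.<channel>"` column
#' labels. The retained set does not depend on channel or batch order, and the
#' filter is idempotent.
#'
#' @param matrices list of per-batch [tmt_matrix()] objects.
#' @param design a `tmt_design` covering those batches' channels.
#' @return list with elements `matrix` (merged complete-case [tmt_matrix()],
#'   batch id `"merged"`) and `report` (`detected` = union of accessions over
#'   batches, `quantified` = retained count, `per_batch` rows/channels).
#' @export
complete_case_filter <- function(matrices, design) {
  if (!length(matrices)) stop("need at least one batch matrix")
  ids <- vapply(matrices, batch_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate batch ids among matrices")
  names(matrices) <- ids
  if (!setequal(ids, unique(design$batch)))
    stop("matrices and design disagree on batch ids")
  for (b in ids) {
    want <- design$channel[design$batch == b]
    if (!setequal(colnames(matrices[[b]]), want))
      stop(sprintf("batch '%s': matrix channels do not match design", b))
    # canonical channel order = design order
    matrices[[b]] <- matrices[[b]][, want, drop = FALSE]
  }
  all_prot <- sort(unique(unlist(lapply(matrices, rownames))))
  common <- Reduce(intersect, lapply(matrices, rownames))
  keep <- common[vapply(common, function(p) {
    all(vapply(matrices, function(m) {
      v <- m[p, ]
      !anyNA(v) && all(v > 0)
    }, logical(1)))
  }, logical(1))]
  keep <- sort(keep)
  if (!length(keep)) stop("no complete cases: no protein is quantified in every channel of every batch")
  # design row order defines column order of the merge
  merged <- do.call(cbind, lapply(ids, function(b) {
    m <- matrices[[b]][keep, , drop = FALSE]
    colnames(m) <- paste(b, colnames(m), sep = ".")
    m
  }))
  merged <- merged[, channel_key(design), drop = FALSE]
  out <- tmt_matrix(unclass(merged), "merged")
  report <- list(detected = length(all_prot), quantified = length(keep),
                 per_batch = lapply(matrices, dim))
  list(matrix = out, report = report)
}
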