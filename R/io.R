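# On-disk formats: tab-separated expression matrices with an optional group
# header row, FASTA sequence files, GMT gene-set files. Readers are strict:
# they never silently drop records, and every format violation is reported
# with the offending identifier or coordinate.

#' Construct an expression dataset
#'
#' A cohort's log2 expression matrix together with tumor/normal sample labels
#' and a platform tag. This is the unit of input to differential expression.
#'
#' @param dataset_id short identifier for the cohort.
#' @param values numeric matrix, features x samples, log2 expression. Row and
#'   column names are taken as feature and sample ids when `feature_ids` /
#'   `sample_ids` are not given.
#' @param group_labels character vector, one of `"tumor"`/`"normal"` per
#'   sample.
#' @param platform `"array"` or `"rnaseq"`.
#' @param feature_ids,sample_ids optional explicit ids (override dimnames).
#' @return an object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, values, group_labels,
                               platform = c("array", "rnaseq"),
                               feature_ids = rownames(values),
                               sample_ids = colnames(values)) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(feature_ids) || is.null(sample_ids))
    format_error("dataset '%s': feature and sample ids are required", dataset_id)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(feature_ids))
    format_error("dataset '%s': duplicate feature id '%s'",
                 dataset_id, feature_ids[duplicated(feature_ids)][1])
  if (anyDuplicated(sample_ids))
    format_error("dataset '%s': duplicate sample id '%s'",
                 dataset_id, sample_ids[duplicated(sample_ids)][1])
  if (length(sample_ids) != ncol(values) || length(feature_ids) != nrow(values))
    format_error("dataset '%s': id lengths do not match matrix dimensions",
                 dataset_id)
  if (length(group_labels) != length(sample_ids))
    format_error("dataset '%s': one group label per sample required", dataset_id)
  if (!all(group_labels %in% c("tumor", "normal")))
    format_error("dataset '%s': group labels must be 'tumor' or 'normal'",
                 dataset_id)
  if (!all(is.finite(values)))
    format_error("dataset '%s': non-finite expression values", dataset_id)
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(dataset_id = dataset_id, platform = platform,
         feature_ids = feature_ids, sample_ids = sample_ids,
         group_labels = setNames(group_labels, sample_ids),
         values = values),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s): %d features x %d samples (%d tumor / %d normal)\n",
              x$dataset_id, x$platform, nrow(x$values), ncol(x$values),
              sum(x$group_labels == "tumor"), sum(x$group_labels == "normal")))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected dialect: row 1 is `feature_id` followed by sample ids; an optional
#' row 2 is `group` followed by `tumor`/`normal` per sample; remaining rows
#' are a feature id followed by numeric log2 values.
#'
#' @param path file path.
#' @param group_line_present whether the second row carries group labels. If
#'   `NA` (default) it is auto-detected from the first field of row 2.
#' @param dataset_id id for the returned dataset; defaults to the file stem.
#' @param platform platform tag for the returned dataset.
#' @param group_labels labels supplied externally when the file has no group
#'   row.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, group_line_present = NA,
                                dataset_id = sub("\\.tsv$", "", basename(path)),
                                platform = "array", group_labels = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) format_error("%s: too few rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "feature_id")
    format_error("%s: first header field must be 'feature_id', got '%s'",
                 path, header[1L])
  sample_ids <- header[-1L]
  width <- length(header)
  if (is.na(group_line_present))
    group_line_present <- identical(fields[[2L]][1L], "group")
  body_start <- 2L
  if (group_line_present) {
    grp <- fields[[2L]]
    if (grp[1L] != "group")
      format_error("%s: expected 'group' row at line 2, got '%s'", path, grp[1L])
    if (length(grp) != width) format_error("%s: ragged group row", path)
    group_labels <- grp[-1L]
    body_start <- 3L
  }
  if (is.null(group_labels))
    format_error("%s: no group row present and no group_labels supplied", path)
  body <- fields[seq(body_start, length(fields))]
  ragged <- which(lengths(body) != width)
  if (length(ragged))
    format_error("%s: ragged row at line %d", path, body_start + ragged[1L] - 1L)
  feature_ids <- vapply(body, `[`, character(1), 1L)
  cells <- vapply(body, function(f) suppressWarnings(as.numeric(f[-1L])),
                  numeric(width - 1L))
  # cells is samples x features (vapply stacks columns); transpose to features x samples
  values <- if (width - 1L == 1L) matrix(cells, ncol = 1L) else t(cells)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    format_error("%s: non-numeric cell at data row %d, column %d",
                 path, bad[1L, 1L], bad[1L, 2L])
  rownames(values) <- feature_ids
  colnames(values) <- sample_ids
  expression_dataset(dataset_id, values, group_labels, platform)
}

#' Write an expression dataset to TSV
#'
#' Values are printed with 6 decimals; [read_expression_tsv()] on the output
#' reproduces the dataset up to that printed precision.
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @param write_group_line include the `group` label row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, write_group_line = TRUE) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  out <- c(
    paste(c("feature_id", dataset$sample_ids), collapse = "\t"),
    if (write_group_line)
      paste(c("group", unname(dataset$group_labels)), collapse = "\t"),
    vapply(seq_along(dataset$feature_ids), function(i) {
      paste(c(dataset$feature_ids[i], fmt_num(dataset$values[i, ])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(out, con)
  invisible(path)
}

#' Read a FASTA file as a named character vector of RNA sequences
#'
#' Sequences are uppercased and T is converted to U so that one alphabet
#' serves all downstream sequence arithmetic. Ids are the header token before
#' the first whitespace. Duplicate ids and empty records are errors.
#'
#' @param path FASTA file path.
#' @return named character vector, id -> RNA sequence (5' to 3').
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as_rna(as.character(set))
  if (any(!nzchar(ids))) format_error("%s: record with empty id", path)
  if (anyDuplicated(ids))
    format_error("%s: duplicate sequence id '%s'", path, ids[duplicated(ids)][1])
  empty <- which(!nzchar(seqs))
  if (length(empty)) format_error("%s: empty record '%s'", path, ids[empty[1]])
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    format_error("%s: non-nucleotide characters in record '%s'",
                 path, ids[bad][1])
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(as_rna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `term_id TAB description TAB member1 TAB member2 ...`.
#' Members are deduplicated preserving first occurrence.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`: named list of gene-id vectors with a
#'   `term_names` attribute mapping term_id -> description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    format_error("%s: line %d has fewer than 3 fields", path, short[1L])
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    format_error("%s: duplicate term id '%s'", path, ids[duplicated(ids)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "term_names") <- setNames(vapply(fields, `[`, character(1), 2L), ids)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets a `GeneSetCollection` (or plain named list of gene vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  nms <- attr(sets, "term_names")
  if (is.null(nms)) nms <- setNames(names(sets), names(sets))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, nms[[id]], sets[[id]]), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

# Generic table writers with the package-wide numeric dialect (6 decimals).
write_table_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(cols, sep = "\t"))), con)
  invisible(path)
}

read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
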