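#' Construct a timed sample matrix
#'
#' Binds a feature-by-sample abundance matrix to its sample annotation
#' (group, zeitgeber time in hours, replicate). This is the container every
#' downstream stage (filtering, normalisation, rhythm detection,
#' differential comparison, differential expression) operates on.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with columns `sample`, `group`, `time`,
#'   `replicate`; one row per column of `values`, in column order.
#' @param value_kind `"counts"` (non-negative integers) or `"continuous"`.
#' @return an object of class `timed_matrix`.
#' @export
timed_matrix <- function(values, meta, value_kind = c("counts", "continuous")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop_field("values", "must have feature ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop_field("values", paste("duplicated feature id:",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  req <- c("sample", "group", "time", "replicate")
  if (!all(req %in% names(meta)))
    stop_field("meta", paste("missing columns:",
      paste(setdiff(req, names(meta)), collapse = ", ")))
  if (nrow(meta) != ncol(values))
    stop_field("meta", "row count must equal the number of sample columns")
  if (anyDuplicated(meta$sample))
    stop_field("meta", "sample ids must be unique")
  if (!is.null(colnames(values)) && !identical(colnames(values), as.character(meta$sample)))
    stop_field("meta", "sample order must match matrix columns")
  if (any(!is.finite(meta$time)) || any(meta$time < 0 | meta$time >= 24))
    stop_field("time", "zeitgeber times must lie in [0, 24)")
  if (value_kind == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop_field("values", "counts must be non-negative integers")
  } else if (any(!is.finite(values))) {
    stop_field("values", "continuous values must be finite")
  }
  colnames(values) <- as.character(meta$sample)
  meta$group <- as.character(meta$group)
  structure(list(values = values, meta = meta, value_kind = value_kind),
            class = "timed_matrix")
}

#' @export
print.timed_matrix <- function(x, ...) {
  cat(sprintf("timed_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  tab <- table(x$meta$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("times:", paste(sort(unique(x$meta$time)), collapse = ", "), "h\n")
  invisible(x)
}

#' @export
dim.timed_matrix <- function(x) dim(x$values)

#' Read an abundance matrix and its sample sheet
#'
#' Reads a features-by-samples TSV (first column feature id, header row of
#' sample ids) together with a sample-sheet TSV (columns `sample`, `group`,
#' `time`, `replicate`), checks that the two agree, and reorders the matrix
#' columns to the sheet order.
#'
#' @param matrix_path path to the abundance TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @param value_kind `"counts"` or `"continuous"`.
#' @return a [timed_matrix].
#' @export
read_timed_matrix <- function(matrix_path, sample_sheet_path,
                              value_kind = c("counts", "continuous")) {
  value_kind <- match.arg(value_kind)
  raw <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated feature id in %s: %s", matrix_path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                   ids[bad], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  only_mat <- setdiff(colnames(m), meta$sample)
  only_sheet <- setdiff(meta$sample, colnames(m))
  if (length(only_mat) || length(only_sheet))
    stop(sprintf(
      "sample ids disagree; only in matrix: {%s}; only in sheet: {%s}",
      paste(only_mat, collapse = ", "), paste(only_sheet, collapse = ", ")),
      call. = FALSE)
  m <- m[, as.character(meta$sample), drop = FALSE]
  timed_matrix(m, meta, value_kind)
}

#' Write a timed matrix and its sample sheet to TSV
#'
#' @param x a [timed_matrix].
#' @param matrix_path,sample_sheet_path output paths.
#' @return invisibly, `x`.
#' @export
write_timed_matrix <- function(x, matrix_path, sample_sheet_path) {
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, sample_sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Drop features with low total counts
#'
#' Removes features whose read total across all samples of both groups falls
#' below `min_total` (default 100, the conventional pre-filter for this
#' design). Feature order is preserved.
#'
#' @param x a [timed_matrix] of counts.
#' @param min_total minimum total count across all samples; features with
#'   total `>= min_total` are retained.
#' @return the filtered [timed_matrix].
#' @export
filter_low_counts <- function(x, min_total = 100) {
  stopifnot(inherits(x, "timed_matrix"))
  if (x$value_kind != "counts")
    stop("filter_low_counts() requires count data", call. = FALSE)
  keep <- rowSums(x$values) >= min_total
  timed_matrix(x$values[keep, , drop = FALSE], x$meta, "counts")
}

#' Normalise counts and move to log2 scale
#'
#' Computes median-of-ratios size factors (the median, over features with a
#' nonzero geometric mean, of each sample's count divided by the feature's
#' geometric mean) and returns `log2(count / size_factor + 1)`. This is an
#' approximate variance-stabilising transform: the mean-dispersion trend is
#' not modelled, so very low counts retain some extra variance. The
#' `"log2"` method skips size factors and applies `log2(x + 1)` directly.
#'
#' @param x a [timed_matrix] of counts.
#' @param method `"median-ratio"` (default) or `"log2"`.
#' @return a continuous [timed_matrix]; size factors are attached as
#'   attribute `"size_factors"` when the median-ratio method is used.
#' @export
normalize_log <- function(x, method = c("median-ratio", "log2")) {
  stopifnot(inherits(x, "timed_matrix"))
  method <- match.arg(method)
  if (x$value_kind != "counts")
    stop("normalize_log() requires count data", call. = FALSE)
  v <- x$values
  if (method == "median-ratio") {
    sf <- size_factors(v)
    v <- sweep(v, 2, sf, "/")
  }
  out <- timed_matrix(log2(v + 1), x$meta, "continuous")
  if (method == "median-ratio") attr(out, "size_factors") <- sf
  out
}

#' Median-of-ratios size factors
#'
#' @param counts integer matrix, features x samples.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  logs <- log(counts)
  geo <- rowMeans(logs)
  use <- is.finite(geo)                 # features with all-nonzero counts
  if (!any(use))
    stop("no feature has nonzero counts in every sample; cannot compute size factors",
         call. = FALSE)
  apply(logs[use, , drop = FALSE], 2, function(lc) exp(median(lc - geo[use])))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line (need >= 3 fields): '%s'",
                   substr(ln, 1, 60)), call. = FALSE)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2]
    out[[parts[1]]] <- members
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
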