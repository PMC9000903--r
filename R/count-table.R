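#' Construct a count table
#'
#' The central container of the pipeline: a non-negative features x samples
#' matrix together with per-sample library sizes and optional per-feature
#' metadata (e.g. the ncRNA class of each reference). Library sizes default
#' to the column sums; normalization replaces them with effective library
#' sizes (raw library size x TMM factor).
#'
#' @param counts numeric matrix, features in rows, samples in columns; must
#'   have row and column names and no negative entries.
#' @param lib_sizes numeric vector of per-sample totals, named by sample.
#'   Defaults to `colSums(counts)`.
#' @param feature_meta optional data.frame keyed by feature id (row names
#'   matching `rownames(counts)`), e.g. a `class` column.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, lib_sizes = NULL, feature_meta = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
  if (!all(colnames(counts) %in% names(lib_sizes)))
    stop("lib_sizes must cover every sample")
  lib_sizes <- lib_sizes[colnames(counts)]
  if (!is.null(feature_meta)) {
    if (!all(rownames(counts) %in% rownames(feature_meta)))
      stop("feature_meta must cover every feature")
    feature_meta <- feature_meta[rownames(counts), , drop = FALSE]
  }
  structure(
    list(counts = counts, lib_sizes = lib_sizes, feature_meta = feature_meta),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d features x %d samples (library sizes %s..%s)\n",
    nrow(x$counts), ncol(x$counts),
    format(min(x$lib_sizes), digits = 4), format(max(x$lib_sizes), digits = 4)
  ))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Write / read a count table as TSV
#'
#' The on-disk layout is one `feature` column, optional feature-metadata
#' columns, then one numeric column per sample. Library sizes travel in a
#' `#lib_sizes` comment header line so a round trip preserves effective
#' library sizes of normalized tables.
#'
#' @param ct a `count_table`.
#' @param path file path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns a `count_table`.
#' @export
write_count_table <- function(ct, path) {
  meta_cols <- if (!is.null(ct$feature_meta)) ct$feature_meta else NULL
  df <- data.frame(feature = rownames(ct$counts), stringsAsFactors = FALSE)
  if (!is.null(meta_cols)) df <- cbind(df, meta_cols)
  df <- cbind(df, as.data.frame(ct$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "#lib_sizes\t%s",
    paste(sprintf("%s=%.10g", names(ct$lib_sizes), ct$lib_sizes), collapse = "\t")
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param n_meta number of feature-metadata columns between `feature` and the
#'   sample columns.
#' @export
read_count_table <- function(path, n_meta = 0L) {
  first <- readLines(path, n = 1L)
  lib_sizes <- NULL
  skip <- 0L
  if (startsWith(first, "#lib_sizes")) {
    parts <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
    kv <- strsplit(parts, "=", fixed = TRUE)
    lib_sizes <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
    names(lib_sizes) <- vapply(kv, `[`, character(1), 1L)
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                          check.names = FALSE)
  feature <- df[[1]]
  meta <- NULL
  if (n_meta > 0) {
    meta <- df[, 1 + seq_len(n_meta), drop = FALSE]
    rownames(meta) <- feature
  }
  counts <- as.matrix(df[, -seq_len(1 + n_meta), drop = FALSE])
  rownames(counts) <- feature
  count_table(counts, lib_sizes = lib_sizes, feature_meta = meta)
}
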