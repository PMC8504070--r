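#' Read a feature-by-replicate measurement matrix from delimited text
#'
#' Expects a rectangular table with a header row, one feature-ID column
#' (default: the first), and numeric measurement columns. The delimiter is
#' inferred from the file extension (\code{.tsv} = tab, \code{.csv} =
#' comma) unless given explicitly. Negative values, missing values,
#' non-numeric cells and duplicated feature IDs are rejected with messages
#' naming the offending row and column.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator; \code{NULL} to infer from the
#'   extension.
#' @param idColumn name or index of the feature-ID column (default 1).
#' @return numeric matrix with feature IDs as rownames.
#' @export
readMeasurementMatrix <- function(path, delimiter = NULL, idColumn = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  delimiter <- delimiter %||% .inferDelimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) {
    stop("expected a feature-ID column plus at least one measurement column",
         call. = FALSE)
  }
  if (is.character(idColumn)) {
    idColumn <- match(idColumn, colnames(df))
    if (is.na(idColumn)) {
      stop("ID column not found in header", call. = FALSE)
    }
  }
  ids <- df[[idColumn]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop(sprintf("duplicate feature ID '%s'", dup), call. = FALSE)
  }
  vals <- df[, -idColumn, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric or missing value in column '%s', row %d (feature '%s')",
        colnames(vals)[j], bad[1L], ids[bad[1L]]), call. = FALSE)
    }
    mat[, j] <- v
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf(
      paste0("negative value at feature '%s', column '%s'; measurements ",
             "must be non-negative (shift or transform upstream)"),
      rownames(mat)[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]),
      call. = FALSE)
  }
  mat
}

.inferDelimiter <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a per-feature result table
#'
#' \code{writeResultTable} serializes a \linkS4class{ClipperResult} as a
#' tab-separated table (one row per feature: ID, contrast score, FDR
#' estimate, discovery flag) preceded by a \code{#}-prefixed metadata block
#' recording the resolved configuration (mode, score, procedure, h, seed,
#' cutoff, q, package version). \code{readResultTable} parses such a file
#' back into the table plus its metadata; a written table round-trips
#' losslessly.
#'
#' @param result a \linkS4class{ClipperResult}.
#' @param path output (or input) file path.
#' @return \code{writeResultTable}: \code{path}, invisibly.
#'   \code{readResultTable}: a data.frame with the metadata in
#'   \code{attr(, "metadata")}.
#' @export
writeResultTable <- function(result, path) {
  stopifnot(methods::is(result, "ClipperResult"))
  meta <- c(
    mode = result@mode, score = result@score, procedure = result@procedure,
    h = as.character(result@h), seed = as.character(result@seed),
    cutoff = formatC(result@cutoff, digits = 17, format = "g"),
    q = as.character(result@q),
    version = as.character(utils::packageVersion("clipfdr"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  tab <- resultTable(result)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (l in metaLines) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$feature_id <- as.character(tab$feature_id)
  attr(tab, "metadata") <- meta
  tab
}

#' Write a benchmark table as TSV
#'
#' @param table a \code{"BenchmarkTable"} from \code{\link{runBenchmark}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBenchmarkTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
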