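#' Construct a MeasurementPair from two measurement matrices
#'
#' Validates and bundles the experimental (d x m) and background (d x n)
#' measurement matrices of a two-condition analysis into a
#' \linkS4class{MeasurementPair}. Both matrices must be numeric, free of
#' missing values, non-negative, and have the same number of rows
#' (features). Feature identifiers are taken from \code{featureIds}, the
#' rownames of \code{experimental}, or generated as \code{feature_1, ...}.
#'
#' @param experimental numeric matrix (or vector, treated as one column) of
#'   measurements under the experimental condition; d features x m
#'   replicates.
#' @param background numeric matrix of measurements under the background
#'   condition; d features x n replicates.
#' @param featureIds optional character vector of d unique feature IDs.
#' @return a \linkS4class{MeasurementPair}.
#' @examples
#' x <- matrix(rpois(30, 5), nrow = 10)
#' y <- matrix(rpois(30, 5), nrow = 10)
#' mp <- MeasurementPair(x, y)
#' replicateCounts(mp)
#' @export
MeasurementPair <- function(experimental, background, featureIds = NULL) {
  x <- .asMeasurementMatrix(experimental, "experimental")
  y <- .asMeasurementMatrix(background, "background")
  if (nrow(x) != nrow(y)) {
    stop("'experimental' and 'background' must describe the same features ",
         "(", nrow(x), " vs ", nrow(y), " rows)", call. = FALSE)
  }
  d <- nrow(x)
  if (is.null(featureIds)) {
    featureIds <- rownames(x)
  }
  if (is.null(featureIds)) {
    featureIds <- paste0("feature_", seq_len(d))
  }
  featureIds <- as.character(featureIds)
  if (length(featureIds) != d) {
    stop("'featureIds' must have one entry per feature", call. = FALSE)
  }
  if (anyDuplicated(featureIds)) {
    stop("feature IDs must be unique", call. = FALSE)
  }
  m <- ncol(x)
  n <- ncol(y)
  w <- cbind(x, y)
  rownames(w) <- featureIds
  colnames(w) <- c(paste0("exp_", seq_len(m)), paste0("bg_", seq_len(n)))
  cond <- factor(rep(c("experimental", "background"), c(m, n)),
                 levels = c("experimental", "background"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(measurements = w),
    colData = S4Vectors::DataFrame(condition = cond,
                                   row.names = colnames(w))
  )
  methods::new("MeasurementPair", se)
}

.asMeasurementMatrix <- function(v, what) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.vector(v) && is.numeric(v)) v <- matrix(v, ncol = 1L)
  if (!is.matrix(v) || !is.numeric(v)) {
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  }
  if (ncol(v) < 1L || nrow(v) < 1L) {
    stop(sprintf("'%s' needs at least one feature and one replicate", what),
         call. = FALSE)
  }
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s' has a missing value at row %d, column %d",
                 what, bad[1L], bad[2L]), call. = FALSE)
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0(
      "'%s' has a negative value at row %d, column %d; measurements must ",
      "be non-negative (apply a shift or transformation upstream)"),
      what, bad[1L], bad[2L]), call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}

#' Accessors for MeasurementPair objects
#'
#' \code{experimentalMatrix} and \code{backgroundMatrix} return the d x m and
#' d x n measurement matrices; \code{replicateCounts} returns
#' \code{c(m = ..., n = ...)}; \code{featureIds} returns the feature
#' identifiers.
#'
#' @param x a \linkS4class{MeasurementPair}.
#' @return see Description.
#' @name experimentalMatrix
#' @aliases backgroundMatrix replicateCounts featureIds
NULL

#' @rdname experimentalMatrix
#' @export
setMethod("experimentalMatrix", "MeasurementPair", function(x) {
  w <- SummarizedExperiment::assay(x, "measurements")
  w[, SummarizedExperiment::colData(x)$condition == "experimental",
    drop = FALSE]
})

#' @rdname experimentalMatrix
#' @export
setMethod("backgroundMatrix", "MeasurementPair", function(x) {
  w <- SummarizedExperiment::assay(x, "measurements")
  w[, SummarizedExperiment::colData(x)$condition == "background",
    drop = FALSE]
})

#' @rdname experimentalMatrix
#' @export
setMethod("replicateCounts", "MeasurementPair", function(x) {
  cond <- SummarizedExperiment::colData(x)$condition
  c(m = sum(cond == "experimental"), n = sum(cond == "background"))
})

#' @rdname experimentalMatrix
#' @export
setMethod("featureIds", "MeasurementPair", function(x) rownames(x))

setMethod("show", "MeasurementPair", function(object) {
  rc <- replicateCounts(object)
  cat("MeasurementPair with", nrow(object), "features:",
      rc[["m"]], "experimental vs", rc[["n"]], "background replicates\n")
})
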