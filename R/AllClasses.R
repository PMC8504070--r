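#' @import methods
NULL

#' MeasurementPair: two-condition feature-by-replicate measurements
#'
#' An S4 container for the paired input of an enrichment or differential
#' analysis: a matrix of non-negative measurements for d features under an
#' experimental condition (m replicates) and under a background condition
#' (n replicates). The class extends
#' \linkS4class{SummarizedExperiment}: the two matrices are stored
#' column-bound as a single \code{"measurements"} assay of dimension
#' d x (m + n), and \code{colData(x)$condition} records which columns belong
#' to which condition.
#'
#' Measurements must be non-negative: the contrast-score construction assumes
#' measurements on a non-negative scale (counts, intensities, or transformed
#' versions thereof). Apply a shift or transformation upstream if your data
#' contain negative values.
#'
#' @seealso \code{\link{MeasurementPair}} (constructor),
#'   \code{\link{experimentalMatrix}}, \code{\link{backgroundMatrix}},
#'   \code{\link{runClipper}}
#' @name MeasurementPair-class
#' @aliases MeasurementPair-class
#' @exportClass MeasurementPair
setClass("MeasurementPair", contains = "SummarizedExperiment")

setValidity("MeasurementPair", function(object) {
  msg <- character(0)
  if (length(SummarizedExperiment::assayNames(object)) < 1L ||
      !("measurements" %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, "assay 'measurements' is required")
  } else {
    w <- SummarizedExperiment::assay(object, "measurements")
    if (!is.numeric(w)) {
      msg <- c(msg, "assay 'measurements' must be numeric")
    } else {
      if (anyNA(w)) msg <- c(msg, "assay 'measurements' contains NA values")
      if (!anyNA(w) && any(w < 0)) {
        msg <- c(msg, paste0(
          "assay 'measurements' contains negative values; ",
          "contrast scores require non-negative measurements ",
          "(shift or transform your data first)"
        ))
      }
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!("condition" %in% colnames(cd))) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else {
    cond <- cd$condition
    if (!is.factor(cond) ||
        !identical(levels(cond), c("experimental", "background"))) {
      msg <- c(msg, paste0(
        "'condition' must be a factor with levels ",
        "'experimental', 'background'"
      ))
    } else if (any(table(cond) < 1L)) {
      msg <- c(msg, "each condition needs at least one replicate")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "feature IDs (rownames) must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationPlan: equivalence classes of replicate permutations
#'
#' Describes which column partitions of the pooled d x (m + n) measurement
#' matrix are used to form permuted pseudo-experimental groups. Permutations
#' of the m + n replicate columns fall into equivalence classes: two
#' permutations are equivalent when they assign the same set of columns to
#' the pseudo-experimental group (for differential analysis with m = n, a
#' class and its complement are additionally identified). The plan stores one
#' m-subset of column indices per class, with the identity assignment
#' (columns 1..m) always first.
#'
#' @slot mode \code{"enrichment"} or \code{"differential"}.
#' @slot m,n replicate counts of the experimental and background condition.
#' @slot classes list of integer vectors; element 1 is the identity
#'   assignment \code{1:m}.
#' @slot h number of non-identity classes (\code{length(classes) - 1}).
#' @slot seed seed used for sampling, or \code{NA} for exhaustive plans.
#' @slot exhaustive \code{TRUE} when every equivalence class is included.
#' @seealso \code{\link{buildPermutationPlan}},
#'   \code{\link{countEquivalenceClasses}}
#' @name PermutationPlan-class
#' @aliases PermutationPlan-class
#' @exportClass PermutationPlan
setClass("PermutationPlan",
  representation(
    mode = "character",
    m = "integer",
    n = "integer",
    classes = "list",
    h = "integer",
    seed = "numeric",
    exhaustive = "logical"
  )
)

setValidity("PermutationPlan", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("enrichment", "differential")) {
    msg <- c(msg, "mode must be 'enrichment' or 'differential'")
  }
  if (object@m < 1L || object@n < 1L) {
    msg <- c(msg, "m and n must be >= 1")
  }
  if (length(object@classes) < 2L) {
    msg <- c(msg, "plan needs the identity class plus at least one other")
  } else {
    if (!identical(as.integer(object@classes[[1L]]), seq_len(object@m))) {
      msg <- c(msg, "first class must be the identity assignment 1:m")
    }
    keys <- vapply(
      object@classes,
      function(s) paste(sort(s), collapse = ","), character(1)
    )
    if (anyDuplicated(keys)) {
      msg <- c(msg, "equivalence classes must be pairwise distinct")
    }
    if (object@h != length(object@classes) - 1L) {
      msg <- c(msg, "h must equal length(classes) - 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DiscoveryResult: an FDR-controlled discovery set
#'
#' Output of the BC or GZ thresholding procedure applied to a vector of
#' contrast scores: the selected score cutoff, the indices of discovered
#' features (scores at or above the cutoff), and per-feature FDR estimates.
#'
#' @slot cutoff numeric(1); \code{Inf} when no threshold satisfies the
#'   target, in which case the discovery set is empty.
#' @slot discoveries integer indices of discovered features.
#' @slot fdrEstimates numeric vector in [0, 1], one value per feature;
#'   thresholding these at any q reproduces the procedure's discovery set.
#' @slot q target FDR used for the cutoff.
#' @slot procedure \code{"BC"} or \code{"GZ"}.
#' @slot h number of permutation classes (GZ), \code{NA} for BC.
#' @seealso \code{\link{bcThreshold}}, \code{\link{gzThreshold}}
#' @name DiscoveryResult-class
#' @aliases DiscoveryResult-class
#' @exportClass DiscoveryResult
setClass("DiscoveryResult",
  representation(
    cutoff = "numeric",
    discoveries = "integer",
    fdrEstimates = "numeric",
    q = "numeric",
    procedure = "character",
    h = "integer"
  )
)

setClassUnion("PermutationPlanOrNULL", c("PermutationPlan", "NULL"))

#' ClipperResult: full result of a contrast-score FDR analysis
#'
#' Returned by \code{\link{runClipper}}. Bundles the resolved configuration
#' (mode, contrast score, procedure, h, q, seed), the per-feature contrast
#' scores and FDR estimates, the score cutoff, the discovery set, and the
#' permutation plan if one was used.
#'
#' @slot featureIds character vector of feature identifiers.
#' @slot contrastScores signed per-feature contrast scores.
#' @slot cutoff selected score cutoff (\code{Inf} if no discoveries).
#' @slot discoveries integer indices of discovered features.
#' @slot fdrEstimates per-feature FDR estimates in [0, 1].
#' @slot mode,score,procedure resolved analysis choices.
#' @slot h number of non-identity permutation classes (\code{NA} for the
#'   direct BC path).
#' @slot q target FDR.
#' @slot seed seed used for permutation-class sampling (\code{NA} when no
#'   sampling happened).
#' @slot plan the \linkS4class{PermutationPlan} used, or \code{NULL}.
#' @seealso \code{\link{runClipper}}, \code{\link{resultTable}}
#' @name ClipperResult-class
#' @aliases ClipperResult-class
#' @exportClass ClipperResult
setClass("ClipperResult",
  representation(
    featureIds = "character",
    contrastScores = "numeric",
    cutoff = "numeric",
    discoveries = "integer",
    fdrEstimates = "numeric",
    mode = "character",
    score = "character",
    procedure = "character",
    h = "integer",
    q = "numeric",
    seed = "numeric",
    plan = "PermutationPlanOrNULL"
  )
)

setValidity("ClipperResult", function(object) {
  d <- length(object@featureIds)
  msg <- character(0)
  if (length(object@contrastScores) != d ||
      length(object@fdrEstimates) != d) {
    msg <- c(msg, "scores and FDR estimates must match featureIds in length")
  }
  if (length(object@discoveries) &&
      any(object@contrastScores[object@discoveries] < object@cutoff)) {
    msg <- c(msg, "all discoveries must have contrast score >= cutoff")
  }
  if (length(msg)) msg else TRUE
})
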