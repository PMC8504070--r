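#' Run a contrast-score FDR analysis
#'
#' The top-level entry point. Given two feature-by-replicate measurement
#' matrices (as a \linkS4class{MeasurementPair} or as separate matrices), a
#' target FDR \code{q}, and an analysis mode, computes per-feature contrast
#' scores, selects an FDR-controlling cutoff, and returns the discovery set
#' together with per-feature FDR estimates.
#'
#' With \code{score = "auto"} and \code{procedure = "auto"} the defaults
#' are:
#' \itemize{
#'   \item enrichment with m = n: direct minus contrast scores + BC
#'     procedure (no permutation machinery);
#'   \item enrichment with m != n: permutation statistics (minus statistic
#'     per class), maximum contrast score + GZ procedure;
#'   \item differential (any m, n with m + n >= 3): permutation statistics
#'     (absolute minus statistic), maximum contrast score + GZ procedure.
#' }
#' Explicit choices are honoured where they are defined: for equal-replicate
#' enrichment either direct score ("minus"/"max") may be combined with BC,
#' and the GZ path accepts either combining rule. The BC procedure is only
#' available for the direct equal-replicate enrichment construction.
#'
#' Features that are constant zero across all replicates are retained: they
#' receive contrast score 0, are never discoveries, and still count toward
#' d. Filtering features changes the procedures' false-discovery estimate
#' and is deliberately left to the caller. Likewise any between-sample
#' normalization (e.g., library-size scaling for sequencing counts) must
#' happen upstream.
#'
#' @param data a \linkS4class{MeasurementPair}, or the experimental matrix
#'   if \code{background} is given.
#' @param background optional background matrix (used with a matrix
#'   \code{data}).
#' @param mode \code{"enrichment"} or \code{"differential"}.
#' @param q target FDR in (0, 1); default 0.05.
#' @param score \code{"auto"}, \code{"minus"} or \code{"max"}.
#' @param procedure \code{"auto"}, \code{"BC"} or \code{"GZ"}.
#' @param h number of permutation classes for the GZ path: an integer,
#'   \code{"max"}, or \code{"default"} (exhaustive when at most 100 classes
#'   exist, otherwise 100 sampled).
#' @param seed seed for permutation-class sampling; irrelevant for
#'   exhaustive plans and the direct BC path.
#' @return a \linkS4class{ClipperResult}.
#' @examples
#' set.seed(7)
#' y <- matrix(rpois(3000, 5), ncol = 3)
#' x <- y
#' x[1:100, ] <- matrix(rpois(300, 15), ncol = 3) # enriched features
#' res <- runClipper(MeasurementPair(x, y), mode = "enrichment", q = 0.05)
#' res
#' @export
runClipper <- function(data, background = NULL,
                       mode = c("enrichment", "differential"),
                       q = 0.05,
                       score = c("auto", "minus", "max"),
                       procedure = c("auto", "BC", "GZ"),
                       h = "default", seed = 1L) {
  mode <- match.arg(mode)
  score <- match.arg(score)
  procedure <- match.arg(procedure)
  .checkFdrTarget(q)
  if (!methods::is(data, "MeasurementPair")) {
    data <- MeasurementPair(data, background)
  } else if (!is.null(background)) {
    stop("'background' must be NULL when 'data' is a MeasurementPair",
         call. = FALSE)
  }
  rc <- replicateCounts(data)
  m <- rc[["m"]]
  n <- rc[["n"]]
  if (mode == "differential" && m + n < 3L) {
    stop("differential analysis needs at least 3 replicates in total ",
         "(m + n >= 3)", call. = FALSE)
  }

  equalEnrich <- mode == "enrichment" && m == n
  if (procedure == "auto") {
    procedure <- if (equalEnrich) "BC" else "GZ"
  }
  if (procedure == "BC" && !equalEnrich) {
    stop("the BC procedure is only available for enrichment analysis with ",
         "equal replicate numbers (m = n); use procedure = 'GZ'",
         call. = FALSE)
  }
  if (score == "auto") {
    score <- if (procedure == "BC") "minus" else "max"
  }

  if (procedure == "BC") {
    scores <- directContrastScores(data, kind = score)
    disc <- bcThreshold(scores, q)
    plan <- NULL
    hUsed <- NA_integer_
    seedUsed <- NA_real_
  } else {
    plan <- buildPermutationPlan(m, n, mode, h = h, seed = seed)
    stats <- permutedStatistics(data, plan)
    scores <- contrastFromPermutations(stats, kind = score)
    disc <- gzThreshold(scores, q, h = plan@h)
    hUsed <- plan@h
    seedUsed <- if (plan@exhaustive) NA_real_ else as.numeric(seed)
  }

  methods::new("ClipperResult",
    featureIds = featureIds(data),
    contrastScores = unname(scores),
    cutoff = disc@cutoff,
    discoveries = disc@discoveries,
    fdrEstimates = unname(disc@fdrEstimates),
    mode = mode, score = score, procedure = procedure,
    h = hUsed, q = q, seed = seedUsed, plan = plan
  )
}

#' Enrichment rescoring of paired target/decoy q-values
#'
#' Add-on mode for target-decoy competition settings (e.g., peptide-spectrum
#' matches scored against a real and a decoy database). Each feature carries
#' one target q-value and one decoy q-value in (0, 1]; both are transformed
#' to -log10 scale so that larger means more significant, and the default
#' 1vs1 enrichment path (minus contrast score + BC procedure) is run on the
#' transformed pair.
#'
#' @param targetQ,decoyQ numeric vectors of equal length with values in
#'   (0, 1].
#' @param q target FDR in (0, 1).
#' @param ids optional feature identifiers.
#' @return a \linkS4class{ClipperResult}.
#' @export
rescorePairedQvalues <- function(targetQ, decoyQ, q = 0.05, ids = NULL) {
  .checkNumericVector(targetQ, "targetQ")
  .checkNumericVector(decoyQ, "decoyQ")
  if (length(targetQ) != length(decoyQ)) {
    stop("'targetQ' and 'decoyQ' must have the same length", call. = FALSE)
  }
  if (any(targetQ <= 0) || any(decoyQ <= 0) ||
      any(targetQ > 1) || any(decoyQ > 1)) {
    stop("q-values must lie in (0, 1]", call. = FALSE)
  }
  mp <- MeasurementPair(matrix(-log10(targetQ), ncol = 1L),
                        matrix(-log10(decoyQ), ncol = 1L),
                        featureIds = ids)
  runClipper(mp, mode = "enrichment", q = q)
}

#' Accessors for ClipperResult and DiscoveryResult objects
#'
#' \code{contrastScores} returns the per-feature signed scores;
#' \code{scoreCutoff} the selected cutoff (\code{Inf} when nothing is
#' discovered); \code{discoveries} the IDs of discovered features;
#' \code{discoveryIndices} their integer indices; \code{fdrEstimates} the
#' per-feature FDR estimates.
#'
#' @param x a \linkS4class{ClipperResult} or \linkS4class{DiscoveryResult}.
#' @return see Description.
#' @name ClipperResult-accessors
NULL

#' @rdname ClipperResult-accessors
#' @export
setMethod("contrastScores", "ClipperResult", function(x) {
  stats::setNames(x@contrastScores, x@featureIds)
})

#' @rdname ClipperResult-accessors
#' @export
setMethod("scoreCutoff", "ClipperResult", function(x) x@cutoff)

#' @rdname ClipperResult-accessors
#' @export
setMethod("discoveries", "ClipperResult", function(x) {
  x@featureIds[x@discoveries]
})

#' @rdname ClipperResult-accessors
#' @export
setMethod("discoveryIndices", "ClipperResult", function(x) x@discoveries)

#' @rdname ClipperResult-accessors
#' @export
setMethod("fdrEstimates", "ClipperResult", function(x) {
  stats::setNames(x@fdrEstimates, x@featureIds)
})

setMethod("show", "ClipperResult", function(object) {
  cat(sprintf(
    "ClipperResult: %s analysis, %s contrast score, %s procedure%s\n",
    object@mode, object@score, object@procedure,
    if (!is.na(object@h)) sprintf(" (h = %d)", object@h) else ""
  ))
  cat(sprintf(
    "  %d features, %d discoveries at q = %g (cutoff %s)\n",
    length(object@featureIds), length(object@discoveries), object@q,
    format(object@cutoff, digits = 4)
  ))
})

#' Per-feature result table
#'
#' Flattens a \linkS4class{ClipperResult} into a data.frame with one row per
#' feature: ID, contrast score, FDR estimate, and a logical discovery flag
#' at the run's q.
#'
#' @param x a \linkS4class{ClipperResult}.
#' @param ... unused.
#' @return a data.frame with columns \code{feature_id},
#'   \code{contrast_score}, \code{fdr_estimate}, \code{discovery}.
#' @export
setMethod("resultTable", "ClipperResult", function(x, ...) {
  data.frame(
    feature_id = x@featureIds,
    contrast_score = x@contrastScores,
    fdr_estimate = x@fdrEstimates,
    discovery = seq_along(x@featureIds) %in% x@discoveries,
    stringsAsFactors = FALSE
  )
})
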