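## FDR-controlling cutoffs on contrast scores.
##
## Both procedures scan the candidate set C = {|C_j| : C_j != 0} in
## increasing order and pick the smallest t whose estimated false discovery
## proportion falls below q:
##   BC:  ( #{C_j <= -t} + 1 )            / max(#{C_j >= t}, 1)  <= q
##   GZ:  ( 1/h + (1/h) #{C_j <= -t} )    / max(#{C_j >= t}, 1)  <= q
## Counts are obtained from one sorted copy of the scores (O(d log d)); an
## independent O(d^2) scan lives in the test suite as an oracle.

.checkScores <- function(C) {
  if (!is.numeric(C) || length(C) == 0L) {
    stop("'C' must be a non-empty numeric vector of contrast scores",
         call. = FALSE)
  }
  if (anyNA(C)) {
    stop("contrast scores contain NA/NaN; their ordering is undefined",
         call. = FALSE)
  }
  invisible(C)
}

## ratios of the procedure's FDP estimate at every candidate threshold,
## candidates returned in increasing order
.candidateRatios <- function(C, numeratorFun) {
  cand <- sort(unique(abs(C[C != 0])))
  if (length(cand) == 0L) {
    return(list(cand = numeric(0), ratio = numeric(0)))
  }
  sC <- sort(C)
  d <- length(C)
  nNeg <- findInterval(-cand, sC)                      # #{C_j <= -t}
  nPos <- d - findInterval(cand, sC, left.open = TRUE) # #{C_j >= t}
  list(cand = cand, ratio = numeratorFun(nNeg) / pmax(nPos, 1))
}

.thresholdResult <- function(C, q, procedure, h, numeratorFun) {
  .checkScores(C)
  .checkFdrTarget(q)
  cr <- .candidateRatios(C, numeratorFun)
  ok <- which(cr$ratio <= q)
  cutoff <- if (length(ok)) cr$cand[min(ok)] else Inf
  disc <- if (is.finite(cutoff)) which(C >= cutoff) else integer(0)
  ## per-feature estimate: best achievable ratio at any candidate <= C_j
  est <- rep(1, length(C))
  if (length(cr$cand)) {
    runmin <- cummin(cr$ratio)
    pos <- C > 0
    idx <- findInterval(C[pos], cr$cand)
    est[pos] <- pmin(1, ifelse(idx >= 1L, runmin[pmax(idx, 1L)], 1))
  }
  names(est) <- names(C)
  methods::new("DiscoveryResult",
    cutoff = cutoff, discoveries = as.integer(disc),
    fdrEstimates = est, q = q, procedure = procedure,
    h = as.integer(h)
  )
}

#' BC procedure: contrast-score cutoff with FDR control
#'
#' The Barber-Candes thresholding rule. Negative contrast scores act as an
#' internal estimate of the number of false discoveries among the positive
#' scores: the cutoff is the smallest candidate t (a nonzero absolute score)
#' at which \eqn{(\#\{C_j \le -t\} + 1) / \max(\#\{C_j \ge t\}, 1) \le q}.
#' Features with \eqn{C_j \ge t} are the discoveries. When no candidate
#' qualifies the cutoff is \code{Inf} and the discovery set is empty.
#'
#' @param C numeric vector of signed contrast scores (\code{Inf} allowed,
#'   \code{NA} rejected).
#' @param q target FDR in (0, 1).
#' @return a \linkS4class{DiscoveryResult}.
#' @examples
#' res <- bcThreshold(c(5, 4, 3, 2, -1), q = 0.5)
#' scoreCutoff(res)      # 1
#' discoveryIndices(res) # 1 2 3 4
#' @export
bcThreshold <- function(C, q) {
  .thresholdResult(C, q, "BC", NA_integer_, function(nNeg) nNeg + 1)
}

#' GZ procedure: contrast-score cutoff for permutation-based scores
#'
#' The Gimenez-Zou multiple-knockoff generalization of the BC rule, used
#' with contrast scores built from h permutation equivalence classes. A
#' negative score arises with probability at most 1/(h+1)-per-class
#' symmetry, so each negative score counts 1/h toward the false discovery
#' estimate, with an additive 1/h correction: the cutoff is the smallest
#' candidate t with
#' \eqn{(1/h + \#\{C_j \le -t\}/h) / \max(\#\{C_j \ge t\}, 1) \le q}.
#'
#' @param C numeric vector of signed contrast scores.
#' @param q target FDR in (0, 1).
#' @param h number of non-identity permutation classes used to build the
#'   scores (>= 1).
#' @return a \linkS4class{DiscoveryResult}.
#' @examples
#' scoreCutoff(gzThreshold(c(5, 4, 3, -2), q = 0.5, h = 1)) # 3
#' scoreCutoff(gzThreshold(c(5, 4, 3, -2), q = 0.5, h = 2)) # 2
#' @export
gzThreshold <- function(C, q, h) {
  h <- as.integer(h)
  if (is.na(h) || h < 1L) {
    stop("'h' must be an integer >= 1", call. = FALSE)
  }
  .thresholdResult(C, q, "GZ", h, function(nNeg) (1 + nNeg) / h)
}

#' Per-feature FDR estimates from contrast scores
#'
#' For each feature, the smallest FDP estimate (the BC or GZ ratio) over all
#' candidate thresholds at or below the feature's score, clipped to [0, 1];
#' features with non-positive scores get 1. These play the role of q-values:
#' thresholding them at any target q reproduces exactly the discovery set of
#' \code{\link{bcThreshold}} / \code{\link{gzThreshold}} at that q. They are
#' score-based estimates, not p-values.
#'
#' @param C numeric vector of signed contrast scores.
#' @param procedure \code{"BC"} or \code{"GZ"}.
#' @param h number of permutation classes (required for GZ).
#' @return numeric vector of estimates in [0, 1].
#' @export
featureFdrEstimates <- function(C, procedure = c("BC", "GZ"), h = NULL) {
  procedure <- match.arg(procedure)
  .checkScores(C)
  if (procedure == "BC") {
    numeratorFun <- function(nNeg) nNeg + 1
    h <- NA_integer_
  } else {
    if (is.null(h) || is.na(h) || h < 1) {
      stop("'h' is required for the GZ procedure", call. = FALSE)
    }
    numeratorFun <- function(nNeg) (1 + nNeg) / h
  }
  cr <- .candidateRatios(C, numeratorFun)
  est <- rep(1, length(C))
  if (length(cr$cand)) {
    runmin <- cummin(cr$ratio)
    pos <- C > 0
    idx <- findInterval(C[pos], cr$cand)
    est[pos] <- pmin(1, ifelse(idx >= 1L, runmin[pmax(idx, 1L)], 1))
  }
  names(est) <- names(C)
  est
}

setMethod("show", "DiscoveryResult", function(object) {
  cat(sprintf(
    "DiscoveryResult (%s procedure%s): %d discoveries at q = %g (cutoff %s)\n",
    object@procedure,
    if (!is.na(object@h)) sprintf(", h = %d", object@h) else "",
    length(object@discoveries), object@q,
    format(object@cutoff, digits = 4)
  ))
})

#' @rdname ClipperResult-accessors
#' @export
setMethod("scoreCutoff", "DiscoveryResult", function(x) x@cutoff)

#' @rdname ClipperResult-accessors
#' @export
setMethod("discoveryIndices", "DiscoveryResult", function(x) x@discoveries)

#' @rdname ClipperResult-accessors
#' @export
setMethod("fdrEstimates", "DiscoveryResult", function(x) x@fdrEstimates)
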