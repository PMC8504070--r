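#' Summary statistics comparing one feature's two measurement vectors
#'
#' Building blocks of the contrast-score construction. For a feature with
#' measurements \code{x} (m experimental replicates) and \code{y}
#' (n background replicates):
#' \describe{
#'   \item{\code{summarizeMinus}}{the difference of sample means,
#'     \eqn{\bar x - \bar y} ("minus" statistic).}
#'   \item{\code{summarizeMax}}{the larger sample mean signed by the
#'     direction of the difference,
#'     \eqn{\max(\bar x, \bar y)\,\mathrm{sign}(\bar x - \bar y)}
#'     ("max" statistic); 0 when the means tie.}
#'   \item{\code{summarizeTstat}}{the pooled-variance two-sample t
#'     statistic,
#'     \eqn{(\bar x - \bar y) / \sqrt{(SS_x + SS_y)/(m + n - 2)}}.}
#' }
#' All three are antisymmetric in their arguments. The minus and max
#' statistics scale linearly with the data; the t statistic is
#' scale-invariant.
#'
#' When the pooled variance is zero, \code{summarizeTstat} returns a signed
#' infinity if the means differ (with a warning, preserving the ranking
#' semantics of constant replicates) and raises an error when numerator and
#' denominator are both zero.
#'
#' @param x numeric vector of m >= 1 non-negative measurements.
#' @param y numeric vector of n >= 1 non-negative measurements
#'   (\code{summarizeTstat} additionally needs m + n >= 3).
#' @return a single numeric summary.
#' @examples
#' summarizeMinus(c(3, 5), c(2, 2)) # 2
#' summarizeMax(c(3, 5), c(2, 2))   # 4
#' summarizeTstat(c(1, 3), c(0, 2)) # 1/sqrt(2)
#' @name summaries
NULL

#' @rdname summaries
#' @export
summarizeMinus <- function(x, y) {
  .checkNumericVector(x, "x")
  .checkNumericVector(y, "y")
  mean(x) - mean(y)
}

#' @rdname summaries
#' @export
summarizeMax <- function(x, y) {
  .checkNumericVector(x, "x")
  .checkNumericVector(y, "y")
  mx <- mean(x)
  my <- mean(y)
  max(mx, my) * sign(mx - my)
}

#' @rdname summaries
#' @export
summarizeTstat <- function(x, y) {
  .checkNumericVector(x, "x")
  .checkNumericVector(y, "y")
  m <- length(x)
  n <- length(y)
  if (m + n < 3L) {
    stop("the two-sample t statistic needs m + n >= 3 replicates",
         call. = FALSE)
  }
  num <- mean(x) - mean(y)
  ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (ss == 0) {
    if (num == 0) {
      stop("t statistic undefined: zero pooled variance and equal means",
           call. = FALSE)
    }
    warning("zero pooled variance; returning signed infinity", call. = FALSE)
    return(sign(num) * Inf)
  }
  num / sqrt(ss / (m + n - 2))
}

#' Direct contrast scores for equal-replicate enrichment analysis
#'
#' When both conditions have the same number of replicates (m = n), the
#' background replicates act as natural negative controls and a contrast
#' score can be computed directly, feature by feature, without permutation:
#' the minus score \eqn{C_j = \bar X_j - \bar Y_j} or the max score
#' \eqn{C_j = \max(\bar X_j, \bar Y_j)\,\mathrm{sign}(\bar X_j - \bar Y_j)}.
#' For uninteresting features both scores are symmetrically distributed
#' around zero, which is what the BC thresholding procedure exploits.
#'
#' @param data a \linkS4class{MeasurementPair} with m = n.
#' @param kind \code{"minus"} (default) or \code{"max"}.
#' @return numeric vector of d contrast scores, named by feature ID.
#' @seealso \code{\link{bcThreshold}}, \code{\link{runClipper}}
#' @export
directContrastScores <- function(data, kind = c("minus", "max")) {
  stopifnot(methods::is(data, "MeasurementPair"))
  kind <- match.arg(kind)
  rc <- replicateCounts(data)
  if (rc[["m"]] != rc[["n"]]) {
    stop("direct contrast scores require equal replicate numbers (m = n); ",
         "use the permutation-based construction (buildPermutationPlan + ",
         "permutedStatistics) for unequal designs", call. = FALSE)
  }
  xbar <- rowMeans(experimentalMatrix(data))
  ybar <- rowMeans(backgroundMatrix(data))
  scores <- switch(kind,
    minus = xbar - ybar,
    max = pmax(xbar, ybar) * sign(xbar - ybar)
  )
  names(scores) <- featureIds(data)
  scores
}
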