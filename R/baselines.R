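## p-value-based comparator methods for the simulation benchmark.

#' Pooled empirical p-values
#'
#' The "pooled" p-value approach: the null distribution is the empirical
#' distribution of the d features' background-condition averages, and each
#' feature's p-value is the right-tail probability of its experimental
#' average under that pooled null, with an add-one correction to avoid
#' zeros:
#' \deqn{p_j = (1 + \#\{k : \bar Y_k \ge \bar X_j\}) / (d + 1).}
#' Valid when all features share one background distribution (homogeneous
#' background) and d is large; breaks down under feature-specific
#' backgrounds.
#'
#' @param data a \linkS4class{MeasurementPair} with d >= 2 features.
#' @return numeric vector of p-values in (0, 1], named by feature ID, with
#'   attribute \code{method = "pooled"}.
#' @export
pooledPvalues <- function(data) {
  stopifnot(methods::is(data, "MeasurementPair"))
  d <- nrow(data)
  if (d < 2L) stop("pooled p-values need at least 2 features", call. = FALSE)
  xbar <- rowMeans(experimentalMatrix(data))
  ybarSorted <- sort(rowMeans(backgroundMatrix(data)))
  ## #{ybar >= x} = d - #{ybar < x}
  nGE <- d - findInterval(xbar, ybarSorted, left.open = TRUE)
  p <- (1 + nGE) / (d + 1)
  names(p) <- featureIds(data)
  attr(p, "method") <- "pooled"
  p
}

#' Paired (per-feature) parametric p-values
#'
#' The "paired" p-value approach: one parametric test per feature using only
#' that feature's m + n measurements.
#' \describe{
#'   \item{gaussian, two-sample}{pooled-variance two-sample t test
#'     (df = m + n - 2); needs m + n >= 3.}
#'   \item{poisson, two-sample}{conditional binomial test: given the total
#'     count S, the experimental sum is Binomial(S, m/(m+n)) under the
#'     null.}
#'   \item{one-sample-2as1 formulation}{deliberately misformulated
#'     comparator that treats the background mean as a known constant and
#'     runs a one-sample t test of the experimental replicates against it
#'     (df = m - 1, needs m >= 2). Ignoring the background's sampling
#'     variability makes the test anti-conservative.}
#' }
#' \code{sided = "one"} gives right-tail (enrichment) p-values;
#' \code{"two"} gives two-sided ones (differential).
#'
#' Degenerate features are handled conservatively: a zero test statistic or
#' an undefined denominator with equal means yields p = 1; an infinite
#' statistic yields p = 0 (or 1 for a one-sided test in the wrong
#' direction).
#'
#' @param data a \linkS4class{MeasurementPair}.
#' @param family \code{"gaussian"} or \code{"poisson"} (apply the poisson
#'   test to negative-binomial counts to emulate a misspecified model).
#' @param sided \code{"two"} or \code{"one"}.
#' @param formulation \code{"two-sample"} or \code{"one-sample-2as1"}.
#' @return numeric vector of p-values in [0, 1] with a \code{method}
#'   attribute.
#' @export
pairedPvalues <- function(data, family = c("gaussian", "poisson"),
                          sided = c("two", "one"),
                          formulation = c("two-sample", "one-sample-2as1")) {
  stopifnot(methods::is(data, "MeasurementPair"))
  family <- match.arg(family)
  sided <- match.arg(sided)
  formulation <- match.arg(formulation)
  x <- experimentalMatrix(data)
  y <- backgroundMatrix(data)
  m <- ncol(x)
  n <- ncol(y)

  if (formulation == "one-sample-2as1") {
    if (m < 2L) {
      stop("the one-sample formulation needs m >= 2 experimental replicates",
           call. = FALSE)
    }
    xbar <- rowMeans(x)
    ybar <- rowMeans(y)
    sx <- sqrt(pmax(apply(x, 1L, stats::var), 0))
    tstat <- (xbar - ybar) / (sx / sqrt(m))
    tstat[sx == 0 & xbar == ybar] <- 0
    p <- .tTailP(tstat, df = m - 1, sided = sided)
    attr(p, "method") <- "paired-2as1"
  } else if (family == "gaussian") {
    if (m + n < 3L) {
      stop("the two-sample gaussian test needs m + n >= 3", call. = FALSE)
    }
    xbar <- rowMeans(x)
    ybar <- rowMeans(y)
    ss <- rowSums((x - xbar)^2) + rowSums((y - ybar)^2)
    denom <- sqrt(ss / (m + n - 2)) * sqrt(1 / m + 1 / n)
    tstat <- (xbar - ybar) / denom
    tstat[ss == 0 & xbar == ybar] <- 0
    p <- .tTailP(tstat, df = m + n - 2, sided = sided)
    attr(p, "method") <- "paired-gaussian"
  } else {
    sx <- round(rowSums(x))
    sy <- round(rowSums(y))
    s <- sx + sy
    prob <- m / (m + n)
    upper <- stats::pbinom(sx - 1, s, prob, lower.tail = FALSE)
    if (sided == "one") {
      p <- upper
    } else {
      lower <- stats::pbinom(sx, s, prob)
      p <- pmin(1, 2 * pmin(lower, upper))
    }
    p[s == 0] <- 1
    attr(p, "method") <- "paired-poisson"
  }
  names(p) <- featureIds(data)
  p
}

.tTailP <- function(tstat, df, sided) {
  if (sided == "one") {
    stats::pt(tstat, df = df, lower.tail = FALSE)
  } else {
    2 * stats::pt(-abs(tstat), df = df)
  }
}

#' Benjamini-Hochberg discoveries
#'
#' Thresholds a p-value vector with the BH step-up procedure (via
#' \code{stats::p.adjust}) and returns the indices of rejected features.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q target FDR in (0, 1).
#' @return integer vector of discovery indices.
#' @export
bhDiscoveries <- function(p, q) {
  .checkPvalues(p)
  .checkFdrTarget(q)
  which(stats::p.adjust(p, method = "BH") <= q)
}

#' Storey q-value discoveries
#'
#' Estimates the null proportion with a single tuning parameter lambda,
#' \eqn{\hat\pi_0 = \min(1, \#\{p_j > \lambda\} / (d (1 - \lambda)))},
#' multiplies the BH-adjusted p-values by it (with the usual step-down
#' minimum accumulation), and rejects features whose q-value is at most q.
#' With \code{lambda = 0} this reduces exactly to BH.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q target FDR in (0, 1).
#' @param lambda null-proportion tuning parameter in [0, 1); default 0.5.
#' @return integer vector of discovery indices, with the estimated
#'   \code{pi0} as an attribute.
#' @export
storeyDiscoveries <- function(p, q, lambda = 0.5) {
  .checkPvalues(p)
  .checkFdrTarget(q)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      lambda >= 1) {
    stop("'lambda' must be a single value in [0, 1)", call. = FALSE)
  }
  d <- length(p)
  pi0 <- min(1, sum(p > lambda) / (d * (1 - lambda)))
  qval <- pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
  out <- which(qval <= q)
  attr(out, "pi0") <- pi0
  out
}

.checkPvalues <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) ||
      any(p < 0 | p > 1)) {
    stop("'p' must be a vector of p-values in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
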