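#' Configuration for the synthetic two-condition generator
#'
#' Collects and validates the parameters of a simulated enrichment or
#' differential dataset. The generator emulates the benchmark conditions
#' used throughout the package's validation: a chosen replicate design
#' (e.g., 1vs1, 2vs1, 3vs3, 10vs10), one of three distributional families
#' for the per-replicate measurements, and a homogeneous background (all
#' features share one background mean) or a heterogeneous background
#' (feature-specific background means drawn from a positive distribution).
#'
#' Defaults: homogeneous background mean 5 for count families and 0 for
#' gaussian; heterogeneous background means ~ Gamma(shape 2, scale 5) for
#' count families and ~ Uniform(0, 10) for gaussian; gaussian noise sd 1;
#' negative-binomial size 2; 10\% interesting features with a 3-fold effect.
#' Gaussian draws are truncated at zero (measurements are non-negative);
#' the truncation is applied identically to every replicate, so uninteresting
#' features keep identically distributed measurements across all replicates
#' and conditions.
#'
#' @param d number of features.
#' @param m,n replicate counts for the experimental and background
#'   condition.
#' @param family \code{"gaussian"}, \code{"poisson"} or \code{"negbin"}.
#' @param background \code{"homogeneous"} or \code{"heterogeneous"}.
#' @param mode \code{"enrichment"} or \code{"differential"}.
#' @param pi1 proportion of interesting features in [0, 1).
#' @param effect effect size for interesting features: a fold change
#'   (\code{effectKind = "fold"}, default) applied as
#'   \eqn{\mu_X = \mathrm{effect} \cdot \mu_Y} (enrichment) or up/down with
#'   equal probability (differential), or an additive mean shift
#'   (\code{effectKind = "shift"}).
#' @param effectKind \code{"fold"} or \code{"shift"}. A fold change has no
#'   effect on a zero-mean background (the gaussian homogeneous default), so
#'   the shift variant exists for that corner.
#' @param dispersion negative-binomial size parameter (> 0).
#' @param noiseSd gaussian measurement sd (> 0).
#' @param mu0 homogeneous background mean; default 5 for count families, 0
#'   for gaussian.
#' @param outlierRate per-feature probability that one randomly chosen
#'   replicate is multiplied by \code{outlierFactor}.
#' @param outlierFactor multiplicative outlier magnitude.
#' @param correlation \code{NULL} for independent features, or a list with
#'   elements \code{blockSize} (default 50) and \code{rho} (default 0.5):
#'   features within a block share a latent gaussian factor per replicate,
#'   coupled through a gaussian copula so marginals are preserved.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param parameterSeed optional separate seed for the parameter layer of
#'   the model: the background means, the choice of interesting features,
#'   and the direction of differential effects. In the measurement model
#'   these are fixed feature properties, not random noise, so a
#'   Monte-Carlo estimate of the FDR should hold them fixed while the
#'   measurement noise (driven by \code{seed}) varies across replicate
#'   datasets; \code{\link{runBenchmark}} does exactly that. \code{NA}
#'   (default) draws everything from \code{seed}.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @seealso \code{\link{generateDataset}}, \code{\link{runBenchmark}}
#' @export
simulationConfig <- function(d = 10000, m = 3, n = 3,
                             family = c("gaussian", "poisson", "negbin"),
                             background = c("heterogeneous", "homogeneous"),
                             mode = c("enrichment", "differential"),
                             pi1 = 0.1, effect = 3,
                             effectKind = c("fold", "shift"),
                             dispersion = 2, noiseSd = 1, mu0 = NULL,
                             outlierRate = 0, outlierFactor = 10,
                             correlation = NULL, seed = 1L,
                             parameterSeed = NA) {
  family <- match.arg(family)
  background <- match.arg(background)
  mode <- match.arg(mode)
  effectKind <- match.arg(effectKind)
  stopifnot(d >= 1, m >= 1, n >= 1, pi1 >= 0, pi1 < 1,
            effect > 0, dispersion > 0, noiseSd > 0,
            outlierRate >= 0, outlierRate <= 1, outlierFactor > 0)
  if (is.null(mu0)) {
    mu0 <- if (family == "gaussian") 0 else 5
  }
  if (!is.null(correlation)) {
    correlation <- list(
      blockSize = if (is.null(correlation$blockSize)) 50L
                  else as.integer(correlation$blockSize),
      rho = if (is.null(correlation$rho)) 0.5 else correlation$rho
    )
    stopifnot(correlation$blockSize >= 2L,
              correlation$rho >= 0, correlation$rho < 1)
  }
  structure(
    list(d = as.integer(d), m = as.integer(m), n = as.integer(n),
         family = family, background = background, mode = mode,
         pi1 = pi1, effect = effect, effectKind = effectKind,
         dispersion = dispersion, noiseSd = noiseSd, mu0 = mu0,
         outlierRate = outlierRate, outlierFactor = outlierFactor,
         correlation = correlation, seed = as.integer(seed),
         parameterSeed = if (is.na(parameterSeed)) NA_integer_
                         else as.integer(parameterSeed)),
    class = "SimulationConfig"
  )
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: %d features, %dvs%d %s, %s %s background (seed %d)\n",
    x$d, x$m, x$n, x$mode, x$background, x$family, x$seed))
  cat(sprintf("  pi1 = %g, effect = %g (%s), outliers %g x%g\n",
              x$pi1, x$effect, x$effectKind, x$outlierRate, x$outlierFactor))
  invisible(x)
}

#' Generate a synthetic two-condition dataset with known ground truth
#'
#' Draws a \linkS4class{MeasurementPair} according to a
#' \code{\link{simulationConfig}}. Background means are one shared value
#' (homogeneous) or feature-specific draws (heterogeneous); interesting
#' features (a seeded random subset of size \code{round(pi1 * d)}) get their
#' experimental mean moved by the configured effect, while uninteresting
#' features have all m + n measurements drawn i.i.d. from one distribution
#' - the exchangeability assumption holds for them by construction.
#' Optional outliers multiply one randomly chosen replicate of a feature by
#' \code{outlierFactor} with probability \code{outlierRate}; optional block
#' correlation couples features through a gaussian copula that preserves the
#' marginals.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a list with elements \code{data} (a
#'   \linkS4class{MeasurementPair}) and \code{truth} (class
#'   \code{"GroundTruth"}: logical vector \code{interesting} plus the true
#'   mean vectors \code{muX}, \code{muY}).
#' @examples
#' sim <- generateDataset(simulationConfig(d = 500, seed = 11))
#' sum(sim$truth$interesting) # 50
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, .generateDatasetImpl(config))
}

.generateDatasetImpl <- function(config) {
  d <- config$d
  m <- config$m
  n <- config$n

  drawParameters <- function() {
    muY <- if (config$background == "homogeneous") {
      rep(config$mu0, d)
    } else if (config$family == "gaussian") {
      stats::runif(d, 0, 10)
    } else {
      stats::rgamma(d, shape = 2, scale = 5)
    }

    nInteresting <- round(config$pi1 * d)
    interesting <- rep(FALSE, d)
    if (nInteresting > 0) {
      interesting[sample.int(d, nInteresting)] <- TRUE
    }

    muX <- muY
    if (nInteresting > 0) {
      idx <- which(interesting)
      if (config$mode == "enrichment") {
        up <- rep(TRUE, nInteresting)
      } else {
        up <- stats::runif(nInteresting) < 0.5
      }
      if (config$effectKind == "fold") {
        muX[idx] <- ifelse(up, muY[idx] * config$effect,
                           muY[idx] / config$effect)
      } else {
        muX[idx] <- pmax(0, muY[idx] + ifelse(up, config$effect,
                                              -config$effect))
      }
    }
    list(muY = muY, muX = muX, interesting = interesting)
  }

  ## feature parameters (means, truth) are fixed model quantities; when a
  ## parameterSeed is given they come from their own stream so replicate
  ## datasets can share one parameter configuration
  pars <- if (is.na(config$parameterSeed)) {
    drawParameters()
  } else {
    .withSeed(config$parameterSeed, drawParameters())
  }
  muY <- pars$muY
  muX <- pars$muX
  interesting <- pars$interesting

  drawBlock <- function(mu, k) {
    ## k replicate columns with per-feature mean mu, family marginals
    if (is.null(config$correlation)) {
      vals <- switch(config$family,
        gaussian = stats::rnorm(d * k, mean = mu, sd = config$noiseSd),
        poisson = stats::rpois(d * k, lambda = mu),
        negbin = stats::rnbinom(d * k, size = config$dispersion, mu = mu)
      )
      matrix(vals, nrow = d, ncol = k)
    } else {
      rho <- config$correlation$rho
      bs <- config$correlation$blockSize
      block <- rep(seq_len(ceiling(d / bs)), each = bs)[seq_len(d)]
      out <- matrix(0, nrow = d, ncol = k)
      for (i in seq_len(k)) {
        g <- stats::rnorm(max(block))[block]
        z <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(d)
        u <- stats::pnorm(z)
        out[, i] <- switch(config$family,
          gaussian = stats::qnorm(u, mean = mu, sd = config$noiseSd),
          poisson = stats::qpois(u, lambda = mu),
          negbin = stats::qnbinom(u, size = config$dispersion, mu = mu)
        )
      }
      out
    }
  }

  x <- drawBlock(muX, m)
  y <- drawBlock(muY, n)
  if (config$family == "gaussian") {
    x <- pmax(x, 0)
    y <- pmax(y, 0)
  }

  if (config$outlierRate > 0) {
    w <- cbind(x, y)
    hit <- which(stats::runif(d) < config$outlierRate)
    if (length(hit)) {
      cols <- sample.int(m + n, length(hit), replace = TRUE)
      w[cbind(hit, cols)] <- w[cbind(hit, cols)] * config$outlierFactor
      x <- w[, seq_len(m), drop = FALSE]
      y <- w[, m + seq_len(n), drop = FALSE]
    }
  }

  data <- MeasurementPair(x, y)
  truth <- structure(
    list(interesting = interesting, muX = muX, muY = muY),
    class = "GroundTruth"
  )
  list(data = data, truth = truth)
}

#' False discovery proportion and power of a discovery set
#'
#' FDP = (false discoveries) / max(discoveries, 1); power = (true
#' discoveries) / max(interesting features, 1). An empty discovery set has
#' FDP 0 and power 0.
#'
#' @param discoveries integer indices of discovered features.
#' @param truth a \code{"GroundTruth"} object (or any list with a logical
#'   \code{interesting} element).
#' @return named numeric vector \code{c(fdp = ..., power = ...)}.
#' @export
evaluateFdpPower <- function(discoveries, truth) {
  interesting <- truth$interesting
  stopifnot(is.logical(interesting))
  discoveries <- as.integer(discoveries)
  if (length(discoveries) &&
      (min(discoveries) < 1L || max(discoveries) > length(interesting))) {
    stop("discovery indices out of range", call. = FALSE)
  }
  nTrue <- sum(interesting[discoveries])
  c(
    fdp = (length(discoveries) - nTrue) / max(length(discoveries), 1),
    power = nTrue / max(sum(interesting), 1)
  )
}
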