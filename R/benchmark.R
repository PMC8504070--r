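## Monte-Carlo benchmark: realized FDR (mean FDP) and power per method.

#' Methods available to the benchmark runner
#'
#' @return character vector of method names understood by
#'   \code{\link{runBenchmark}}.
#' @export
benchmarkMethods <- function() {
  c("clipper", "BH-pool", "qvalue-pool", "BH-pair", "qvalue-pair",
    "BH-pair-2as1", "qvalue-pair-2as1", "BH-pair-mis", "qvalue-pair-mis")
}

## per-method discovery function factory; returns indices or stops
.methodDiscoveries <- function(method, data, truth, config, q, seed) {
  sided <- if (config$mode == "enrichment") "one" else "two"
  pooledP <- function() {
    p <- pooledPvalues(data)
    if (sided == "one") return(p)
    ## two-sided pooled: combine right and left empirical tails
    xbar <- rowMeans(experimentalMatrix(data))
    ybarSorted <- sort(rowMeans(backgroundMatrix(data)))
    d <- length(p)
    nLE <- findInterval(xbar, ybarSorted) # #{ybar <= x}
    pLeft <- (1 + nLE) / (d + 1)
    pmin(1, 2 * pmin(p, pLeft))
  }
  pairedP <- function(formulation = "two-sample", family = NULL) {
    if (is.null(family)) {
      family <- if (config$family == "gaussian") "gaussian" else "poisson"
    }
    pairedPvalues(data, family = family, sided = sided,
                  formulation = formulation)
  }
  switch(method,
    "clipper" = discoveryIndices(
      runClipper(data, mode = config$mode, q = q, seed = seed)),
    "BH-pool" = bhDiscoveries(pooledP(), q),
    "qvalue-pool" = storeyDiscoveries(pooledP(), q),
    "BH-pair" = bhDiscoveries(pairedP(), q),
    "qvalue-pair" = storeyDiscoveries(pairedP(), q),
    "BH-pair-2as1" = bhDiscoveries(pairedP("one-sample-2as1"), q),
    "qvalue-pair-2as1" = storeyDiscoveries(pairedP("one-sample-2as1"), q),
    "BH-pair-mis" = bhDiscoveries(pairedP(family = "poisson"), q),
    "qvalue-pair-mis" = storeyDiscoveries(pairedP(family = "poisson"), q),
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

#' Monte-Carlo FDR/power benchmark over simulated datasets
#'
#' Repeatedly generates datasets from \code{config} (replicate r draws its
#' measurement noise with seed \code{config$seed + r}), runs every
#' requested method at every target FDR in \code{qGrid}, and averages the
#' realized false discovery proportions and power over replicates. The mean
#' FDP estimates the method's actual FDR at that target; an FDR-controlling
#' method should satisfy mean FDP <= q up to Monte-Carlo error (reported as
#' the standard error of the mean).
#'
#' The feature parameters - background means, which features are
#' interesting, effect directions - are fixed properties of the simulated
#' study, so all replicates share one parameter configuration (drawn with
#' \code{config$parameterSeed}, defaulting to \code{config$seed}); only the
#' measurement noise varies across replicates. This matches the FDR's
#' definition as an expectation over measurement randomness given the
#' underlying signal structure, and it is what exposes methods whose
#' validity silently requires feature parameters to be exchangeable.
#'
#' A method that errors on a given dataset (e.g., a test that needs more
#' replicates than the design provides) is recorded in the \code{n_fail}
#' column and excluded from that cell's averages rather than aborting the
#' benchmark.
#'
#' @param config a \code{\link{simulationConfig}} describing the data;
#'   \code{config$seed} is the base seed.
#' @param methods character vector of method names (see
#'   \code{\link{benchmarkMethods}}).
#' @param qGrid numeric vector of target FDR thresholds in (0, 1).
#' @param nReps number of simulated datasets (>= 1).
#' @return a data.frame of class \code{"BenchmarkTable"} with columns
#'   \code{method}, \code{q_target}, \code{mean_FDP}, \code{mc_se_FDP},
#'   \code{mean_power}, \code{mc_se_power}, \code{n_reps}, \code{n_fail}.
#' @examples
#' cfg <- simulationConfig(d = 300, m = 3, n = 3, seed = 5)
#' runBenchmark(cfg, methods = "clipper", qGrid = 0.05, nReps = 2)
#' @export
runBenchmark <- function(config, methods = c("clipper", "BH-pool", "BH-pair"),
                         qGrid = seq(0.01, 0.10, by = 0.01), nReps = 200) {
  stopifnot(inherits(config, "SimulationConfig"), nReps >= 1)
  methods <- match.arg(methods, benchmarkMethods(), several.ok = TRUE)
  vapply(qGrid, .checkFdrTarget, numeric(1))

  fdp <- array(NA_real_, dim = c(length(methods), length(qGrid), nReps))
  pow <- array(NA_real_, dim = c(length(methods), length(qGrid), nReps))
  if (is.na(config$parameterSeed)) {
    config$parameterSeed <- config$seed
  }
  for (r in seq_len(nReps)) {
    repSeed <- config$seed + r
    cfg <- config
    cfg$seed <- repSeed
    sim <- generateDataset(cfg)
    for (i in seq_along(methods)) {
      for (k in seq_along(qGrid)) {
        disc <- tryCatch(
          .methodDiscoveries(methods[i], sim$data, sim$truth, config,
                             qGrid[k], seed = repSeed),
          error = function(e) NULL
        )
        if (!is.null(disc)) {
          fp <- evaluateFdpPower(disc, sim$truth)
          fdp[i, k, r] <- fp[["fdp"]]
          pow[i, k, r] <- fp[["power"]]
        }
      }
    }
  }

  grid <- expand.grid(i = seq_along(methods), k = seq_along(qGrid))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    i <- grid$i[g]
    k <- grid$k[g]
    f <- fdp[i, k, ]
    p <- pow[i, k, ]
    ok <- !is.na(f)
    data.frame(
      method = methods[i],
      q_target = qGrid[k],
      mean_FDP = mean(f[ok]),
      mc_se_FDP = stats::sd(f[ok]) / sqrt(max(sum(ok), 1)),
      mean_power = mean(p[ok]),
      mc_se_power = stats::sd(p[ok]) / sqrt(max(sum(ok), 1)),
      n_reps = sum(ok),
      n_fail = sum(!ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$q_target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BenchmarkTable", "data.frame")
  out
}
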