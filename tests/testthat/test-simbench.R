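test_that("generated datasets have the configured shape and truth", {
  cfg <- simulationConfig(d = 1000, m = 3, n = 3, family = "gaussian",
                          background = "heterogeneous", pi1 = 0.1, seed = 1)
  sim <- generateDataset(cfg)
  expect_s4_class(sim$data, "MeasurementPair")
  expect_equal(dim(experimentalMatrix(sim$data)), c(1000L, 3L))
  expect_equal(dim(backgroundMatrix(sim$data)), c(1000L, 3L))
  expect_equal(sum(sim$truth$interesting), 100)
  # uninteresting features have identical means by construction
  nullIdx <- !sim$truth$interesting
  expect_equal(sim$truth$muX[nullIdx], sim$truth$muY[nullIdx])
  expect_true(all(sim$truth$muX[!nullIdx] != sim$truth$muY[!nullIdx]))

  # same config + seed => identical matrices
  sim2 <- generateDataset(cfg)
  expect_identical(experimentalMatrix(sim$data),
                   experimentalMatrix(sim2$data))

  # pi1 = 0: everything uninteresting
  sim0 <- generateDataset(simulationConfig(d = 50, pi1 = 0, seed = 2))
  expect_equal(sum(sim0$truth$interesting), 0)
})

test_that("every family produces valid non-negative measurements", {
  for (family in c("gaussian", "poisson", "negbin")) {
    for (background in c("homogeneous", "heterogeneous")) {
      sim <- generateDataset(simulationConfig(
        d = 200, m = 2, n = 1, family = family, background = background,
        mode = "differential", seed = 7
      ))
      w <- cbind(experimentalMatrix(sim$data), backgroundMatrix(sim$data))
      expect_true(all(w >= 0))
      expect_false(anyNA(w))
    }
  }
})

test_that("uninteresting features satisfy the exchangeability assumption", {
  # pooled X-half vs Y-half of null features must look like one
  # distribution: rank test at coarse tolerance
  set.seed(41)
  sim <- generateDataset(simulationConfig(
    d = 3000, m = 3, n = 3, family = "negbin",
    background = "heterogeneous", pi1 = 0, seed = 41
  ))
  x <- experimentalMatrix(sim$data)
  y <- backgroundMatrix(sim$data)
  # per-feature standardization so pooling across features is meaningful
  mu <- rowMeans(cbind(x, y))
  keep <- mu > 0
  p <- wilcox.test(as.vector(x[keep, ] / mu[keep]),
                   as.vector(y[keep, ] / mu[keep]))$p.value
  expect_gt(p, 0.001)
})

test_that("outliers and block correlation are applied as configured", {
  cfg <- simulationConfig(d = 2000, m = 2, n = 2, family = "poisson",
                          outlierRate = 0.5, outlierFactor = 100, seed = 3)
  sim <- generateDataset(cfg)
  base <- generateDataset(simulationConfig(
    d = 2000, m = 2, n = 2, family = "poisson", seed = 3))
  wOut <- cbind(experimentalMatrix(sim$data), backgroundMatrix(sim$data))
  wBase <- cbind(experimentalMatrix(base$data), backgroundMatrix(base$data))
  changed <- rowSums(wOut != wBase) > 0
  expect_gt(mean(changed), 0.3) # ~half the features get one outlier
  expect_true(max(wOut) > max(wBase))

  # shared within-block factors: residuals of two features from the same
  # block correlate across blocks, features from different blocks do not
  cfgCor <- simulationConfig(d = 5000, m = 1, n = 1, family = "gaussian",
                             background = "heterogeneous", pi1 = 0,
                             correlation = list(blockSize = 50, rho = 0.7),
                             seed = 4)
  simC <- generateDataset(cfgCor)
  resid <- experimentalMatrix(simC$data)[, 1] - simC$truth$muY
  byBlock <- matrix(resid, nrow = 50) # column b = block b
  sameBlock <- cor(byBlock[1, ], byBlock[2, ])
  expect_gt(sameBlock, 0.4) # population value rho = 0.7
  # block means have variance ~ rho, far above the 1/50 of independence
  expect_gt(var(colMeans(byBlock)), 0.3)

  indep <- generateDataset(simulationConfig(
    d = 5000, m = 1, n = 1, family = "gaussian",
    background = "heterogeneous", pi1 = 0, seed = 4))
  residI <- experimentalMatrix(indep$data)[, 1] - indep$truth$muY
  expect_lt(var(colMeans(matrix(residI, nrow = 50))), 0.1)
})

test_that("FDP and power follow the V/max(R,1) convention", {
  truth <- list(interesting = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(evaluateFdpPower(1:3, truth),
               c(fdp = 1 / 3, power = 1))
  expect_equal(evaluateFdpPower(integer(0), truth),
               c(fdp = 0, power = 0))
  expect_equal(evaluateFdpPower(1:2, truth),
               c(fdp = 0, power = 1))
  expect_error(evaluateFdpPower(9, truth), "out of range")
})

test_that("benchmark runner aggregates per-replicate metrics", {
  cfg <- simulationConfig(d = 300, m = 3, n = 3, family = "gaussian",
                          seed = 10)
  tab <- runBenchmark(cfg, methods = c("clipper", "BH-pair"),
                      qGrid = c(0.05, 0.2), nReps = 3)
  expect_s3_class(tab, "BenchmarkTable")
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mean_FDP >= 0 & tab$mean_FDP <= 1))
  expect_true(all(tab$mean_power >= 0 & tab$mean_power <= 1))
  expect_true(all(tab$n_reps == 3))

  # single replicate: metrics still in [0, 1]
  tab1 <- runBenchmark(cfg, methods = "clipper", qGrid = 0.05, nReps = 1)
  expect_equal(tab1$n_reps, 1)
  expect_true(tab1$mean_FDP >= 0 && tab1$mean_FDP <= 1)

  # deterministic given the config (per-replicate seeds are base + r)
  tab2 <- runBenchmark(cfg, methods = c("clipper", "BH-pair"),
                       qGrid = c(0.05, 0.2), nReps = 3)
  expect_equal(tab, tab2)
})

test_that("methods that cannot run on a design are recorded, not fatal", {
  cfg <- simulationConfig(d = 100, m = 1, n = 1, family = "gaussian",
                          background = "homogeneous", seed = 12)
  tab <- runBenchmark(cfg, methods = c("clipper", "BH-pair"),
                      qGrid = 0.05, nReps = 2)
  bhRow <- tab[tab$method == "BH-pair", ]
  expect_equal(bhRow$n_fail, 2) # gaussian two-sample test needs m + n >= 3
  expect_equal(tab[tab$method == "clipper", "n_fail"], 0)
})
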