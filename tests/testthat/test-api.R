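test_that("auto resolution picks the documented defaults", {
  set.seed(21)
  mp33 <- randomPair(d = 50, m = 3, n = 3)
  r <- runClipper(mp33, mode = "enrichment", q = 0.1)
  expect_equal(r@procedure, "BC")
  expect_equal(r@score, "minus")
  expect_null(r@plan)

  mp21 <- randomPair(d = 50, m = 2, n = 1)
  r2 <- runClipper(mp21, mode = "enrichment", q = 0.1)
  expect_equal(r2@procedure, "GZ")
  expect_equal(r2@score, "max")
  expect_equal(r2@h, 2L)

  r3 <- runClipper(mp33, mode = "differential", q = 0.1)
  expect_equal(r3@procedure, "GZ")
  expect_equal(r3@score, "max")
  expect_equal(r3@h, 9L) # C(6,3)/2 - 1 exhaustive classes

  mp11 <- randomPair(d = 50, m = 1, n = 1)
  expect_error(runClipper(mp11, mode = "differential"), "at least 3")
  expect_error(runClipper(mp33, mode = "enrichment", q = 1.5), "\\(0, 1\\)")
  expect_error(runClipper(mp21, mode = "enrichment", procedure = "BC"),
               "equal replicate")
})

test_that("equal-replicate enrichment equals the direct BC composition", {
  set.seed(22)
  mp <- randomPair(d = 300, m = 3, n = 3)
  r <- runClipper(mp, mode = "enrichment", q = 0.2)
  direct <- directContrastScores(mp, "minus")
  expect_equal(unname(contrastScores(r)), unname(direct))
  oracle <- bcThreshold(direct, 0.2)
  expect_equal(scoreCutoff(r), scoreCutoff(oracle))
  expect_equal(discoveryIndices(r), discoveryIndices(oracle))
  # explicit max-score override still runs the BC path
  rmax <- runClipper(mp, mode = "enrichment", q = 0.2, score = "max")
  expect_equal(unname(contrastScores(rmax)),
               unname(directContrastScores(mp, "max")))
})

test_that("results are reproducible given data, config and seed", {
  set.seed(23)
  mp <- randomPair(d = 200, m = 10, n = 10) # forces sampled plan for GZ
  r1 <- runClipper(mp, mode = "differential", q = 0.1, seed = 5)
  r2 <- runClipper(mp, mode = "differential", q = 0.1, seed = 5)
  expect_equal(resultTable(r1), resultTable(r2))
  expect_identical(r1@plan@classes, r2@plan@classes)
})

test_that("swapping conditions leaves differential discoveries unchanged", {
  set.seed(24)
  for (i in 1:5) {
    mp <- randomPair(d = 150, m = 2, n = 1, lambda = 6)
    swapped <- MeasurementPair(backgroundMatrix(mp), experimentalMatrix(mp))
    a <- runClipper(mp, mode = "differential", q = 0.2, h = "max")
    b <- runClipper(swapped, mode = "differential", q = 0.2, h = "max")
    expect_equal(discoveryIndices(a), discoveryIndices(b))
  }
})

test_that("all-zero features are retained but never discovered", {
  set.seed(25)
  x <- matrix(rpois(60, 8), nrow = 20)
  y <- matrix(rpois(60, 2), nrow = 20)
  x[1:3, ] <- 0
  y[1:3, ] <- 0
  r <- runClipper(MeasurementPair(x, y), mode = "enrichment", q = 0.3)
  expect_length(contrastScores(r), 20)
  expect_equal(unname(contrastScores(r)[1:3]), rep(0, 3))
  expect_false(any(1:3 %in% discoveryIndices(r)))
})

test_that("paired q-value rescoring follows the 1vs1 enrichment path", {
  same <- rescorePairedQvalues(c(0.5, 0.2), c(0.5, 0.2), q = 0.5)
  expect_equal(unname(contrastScores(same)), c(0, 0))
  expect_length(discoveryIndices(same), 0)

  # d = 2 worked example: scores +-4.699; at t = 4.699 the BC ratio is
  # (1+1)/1 = 2 > 0.5, so nothing is discovered
  r <- rescorePairedQvalues(c(1e-5, 0.5), c(0.5, 1e-5), q = 0.5)
  expect_equal(unname(contrastScores(r)),
               c(-log10(1e-5) + log10(0.5), log10(1e-5) - log10(0.5)))
  expect_equal(r@procedure, "BC")
  expect_equal(scoreCutoff(r), Inf)
  expect_length(discoveryIndices(r), 0)

  expect_error(rescorePairedQvalues(c(0, 0.5), c(0.5, 0.5)), "\\(0, 1\\]")
  expect_error(rescorePairedQvalues(0.5, c(0.5, 0.5)), "same length")
})

test_that("rescoring a planted target/decoy set controls the FDP", {
  # 100 features, 50 planted true targets with tiny target q-values
  set.seed(26)
  fdps <- replicate(20, {
    d <- 100
    true <- 1:50
    targetQ <- runif(d, 0.05, 1)
    decoyQ <- runif(d, 0.05, 1)
    targetQ[true] <- 10^runif(50, -8, -4)
    r <- rescorePairedQvalues(targetQ, decoyQ, q = 0.1)
    disc <- discoveryIndices(r)
    sum(!(disc %in% true)) / max(length(disc), 1)
  })
  expect_lte(mean(fdps), 0.1 + 3 * sd(fdps) / sqrt(length(fdps)))
})
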