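test_that("equivalence-class counts follow the design", {
  expect_equal(countEquivalenceClasses(2, 1, "enrichment"), 3)
  expect_equal(countEquivalenceClasses(3, 3, "differential"), 10)
  expect_equal(countEquivalenceClasses(1, 1, "differential"), 1)
  expect_equal(countEquivalenceClasses(3, 3, "enrichment"), 20)
  expect_equal(countEquivalenceClasses(2, 3, "differential"), 10)
})

test_that("exhaustive plans enumerate every class exactly once", {
  for (spec in list(c(2, 1), c(3, 3), c(2, 3), c(1, 1))) {
    for (mode in c("enrichment", "differential")) {
      m <- spec[1]
      n <- spec[2]
      if (mode == "differential" && m + n < 3) next
      plan <- buildPermutationPlan(m, n, mode, h = "max")
      oracle <- enumerateClassesOracle(m, n, mode)
      expect_length(plan@classes, length(oracle))
      key <- function(s) paste(sort(s), collapse = ",")
      got <- vapply(plan@classes, key, character(1))
      expect_false(anyDuplicated(got) > 0)
      if (mode == "differential" && m == n) {
        # match up to complement
        wanted <- vapply(oracle, function(s) {
          comp <- setdiff(seq_len(m + n), s)
          min(key(s), key(comp))
        }, character(1))
        gotCanon <- vapply(plan@classes, function(s) {
          comp <- setdiff(seq_len(m + n), s)
          min(key(s), key(comp))
        }, character(1))
        expect_setequal(gotCanon, wanted)
      } else {
        expect_setequal(got, vapply(oracle, key, character(1)))
      }
      expect_identical(plan@classes[[1]], seq_len(m))
    }
  }
})

test_that("2vs1 enrichment plan matches the closed-form class list", {
  plan <- buildPermutationPlan(2, 1, "enrichment", h = "max")
  expect_equal(plan@h, 2L)
  expect_true(plan@exhaustive)
  expect_equal(plan@classes, list(1:2, c(1L, 3L), c(2L, 3L)))
})

test_that("sampled plans are seeded and deterministic", {
  p1 <- buildPermutationPlan(10, 10, "enrichment", h = 5, seed = 7)
  p2 <- buildPermutationPlan(10, 10, "enrichment", h = 5, seed = 7)
  p3 <- buildPermutationPlan(10, 10, "enrichment", h = 5, seed = 8)
  expect_identical(p1@classes, p2@classes)
  expect_false(identical(p1@classes, p3@classes))
  expect_false(p1@exhaustive)
  # default h rule: exhaustive for small designs, 100 otherwise
  expect_true(buildPermutationPlan(3, 3, "enrichment")@exhaustive)
  expect_equal(buildPermutationPlan(10, 10, "enrichment")@h, 100L)
  # sampling never disturbs the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(buildPermutationPlan(10, 10, "enrichment", h = 3, seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("differential needs m + n >= 3 and h respects h_max", {
  expect_error(buildPermutationPlan(1, 1, "differential"), "at least 3")
  expect_error(buildPermutationPlan(2, 1, "enrichment", h = 3), "h_max")
  expect_error(buildPermutationPlan(2, 1, "enrichment", h = 0), "h_max")
})

test_that("permuted statistics reproduce the 2vs1 worked example", {
  plan <- buildPermutationPlan(2, 1, "enrichment", h = "max")
  mp <- MeasurementPair(matrix(c(10, 8), nrow = 1), matrix(1, nrow = 1))
  st <- permutedStatistics(mp, plan)
  # classes {1,2}, {1,3}, {2,3}: 9-1, 5.5-8, 4.5-10
  expect_equal(unname(st[1, ]), c(8, -2.5, -5.5))

  dplan <- buildPermutationPlan(2, 1, "differential", h = "max")
  dst <- permutedStatistics(mp, dplan)
  expect_equal(unname(dst[1, ]), c(8, 2.5, 5.5))

  const <- MeasurementPair(matrix(c(3, 3), nrow = 1), matrix(3, nrow = 1))
  expect_equal(unname(permutedStatistics(const, plan)[1, ]), c(0, 0, 0))
})

test_that("contrast scores from sorted statistics follow the tie rules", {
  st <- rbind(c(8, -2.5, -5.5), c(2, 5, 1), c(4, 4, 1))
  expect_equal(unname(contrastFromPermutations(st, "minus")),
               c(10.5, -3, 0))
  expect_equal(unname(contrastFromPermutations(st, "max")),
               c(8, -5, 0))
})

test_that("contrast scores ignore the order of permutation columns", {
  set.seed(11)
  st <- cbind(rnorm(50), matrix(rnorm(50 * 4), nrow = 50))
  shuffled <- st[, c(1, 1 + sample(4))]
  for (kind in c("minus", "max")) {
    expect_equal(contrastFromPermutations(st, kind),
                 contrastFromPermutations(shuffled, kind))
  }
})

test_that("identity rank is uniform across classes under the null", {
  # exchangeable feature rows: the identity statistic's rank among the
  # h + 1 per-class statistics must be uniform
  set.seed(202)
  d <- 5000
  plan <- buildPermutationPlan(2, 1, "enrichment", h = "max")
  mp <- MeasurementPair(matrix(rexp(d * 2), ncol = 2),
                        matrix(rexp(d), ncol = 1))
  st <- permutedStatistics(mp, plan)
  ranks <- apply(st, 1, function(r) rank(r, ties.method = "random")[1])
  gof <- chisq.test(tabulate(ranks, nbins = 3),
                    p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("a positive exhaustive max score implies a positive direct minus score", {
  # if the identity split is the strict maximum over all equivalence
  # classes it beats its own complement, so xbar - ybar must be positive;
  # the converse does not hold (another split can dominate)
  set.seed(5)
  mp <- randomPair(d = 200, m = 2, n = 2, lambda = 8)
  direct <- directContrastScores(mp, "minus")
  plan <- buildPermutationPlan(2, 2, "enrichment", h = "max")
  maxScore <- contrastFromPermutations(permutedStatistics(mp, plan), "max")
  expect_true(all(direct[maxScore > 0] > 0))
  expect_gt(sum(maxScore > 0), 0)
})
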