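test_that("the benchmark fixture meets its design constraints", {
  set.seed(1)
  fx <- makeFixtureTree()
  expect_equal(nLeaves(fx$tree), 105L)
  expect_length(nodeIds(fx$tree), 9L)
  expect_equal(sum(fx$n), 19920L)
  expect_true(all(fx$n >= 10 & fx$n <= 4670))
  # every node holds at least two leaves
  sizes <- table(vapply(fx$tree@paths, `[`, "", 1))
  expect_true(all(sizes >= 2))
})

test_that("infeasible fixture requests are rejected", {
  expect_error(makeFixtureTree(leaves = 200, nodes = 9, Ntotal = 1000),
               "infeasible")
  expect_error(makeFixtureTree(leaves = 10, nodes = 9), "2 leaves per node")
})

test_that("the fixture is deterministic for a seed", {
  a <- withr::with_seed(33, makeFixtureTree())
  b <- withr::with_seed(33, makeFixtureTree())
  expect_identical(a$n, b$n)
  expect_identical(leafIds(a$tree), leafIds(b$tree))
  expect_identical(a$tree@paths, b$tree@paths)
})

test_that("structural zeros are allocated exactly and uniformly", {
  set.seed(3)
  expect_equal(sum(allocateTrueZeros(105L, 0)), 0)
  expect_equal(sum(allocateTrueZeros(105L, 70)), 70)
  expect_error(allocateTrueZeros(105L, 105), "\\[0, I\\)")
  # each leaf selected with frequency k/I
  draws <- vapply(1:4000, function(i) allocateTrueZeros(105L, 10),
                  numeric(105))
  freq <- rowMeans(draws)
  p <- 10 / 105
  se <- sqrt(p * (1 - p) / 4000)
  expect_true(all(abs(freq - p) < 4 * se))
})

test_that("scenario datasets respect zeros, totals and the RR tilt", {
  set.seed(5)
  fx <- makeFixtureTree(leaves = 30, nodes = 5, Ntotal = 3000,
                        maxMarginal = 800)
  sc <- scanScenario(fx$tree, fx$n, C = 200, kTrueZero = 8, sTrueSignal = 3,
                     rr = 6)
  for (i in 1:25) {
    gen <- generateScenarioCounts(sc)
    expect_equal(totalCases(gen$counts), 200)
    expect_true(all(caseCounts(gen$counts)[gen$delta == 1] == 0))
    expect_length(gen$signalLeaves, 3)
    expect_true(all(gen$delta[gen$signalLeaves] == 0))
  }
  # expected count of a signal leaf is inflated by its tilted weight
  sc1 <- scanScenario(fx$tree, fx$n, C = 500, kTrueZero = 0,
                      sTrueSignal = 1, rr = 6)
  tot <- 0; m <- 400
  set.seed(6)
  for (i in 1:m) {
    gen <- generateScenarioCounts(sc1)
    w <- rep(1, 30); w[gen$signalLeaves] <- 6
    expected <- 500 * 6 * fx$n[gen$signalLeaves] / sum(w * fx$n)
    tot <- tot + caseCounts(gen$counts)[gen$signalLeaves] - expected
  }
  expect_lt(abs(tot / m), 1.5)   # mean deviation ~ 0 within MC error
  # infeasible allocations rejected
  expect_error(scanScenario(fx$tree, fx$n, C = 10, kTrueZero = 20,
                            sTrueSignal = 10), "less than the number")
})

test_that("a null scenario with rr = 1 and k = 0 reduces to conditional null draws", {
  set.seed(7)
  fx <- makeFixtureTree(leaves = 12, nodes = 3, Ntotal = 1200,
                        maxMarginal = 400)
  sc <- scanScenario(fx$tree, fx$n, C = 60)
  gen <- generateScenarioCounts(sc)
  expect_length(gen$signalLeaves, 0)
  expect_equal(sum(gen$delta), 0)
  expect_equal(totalCases(gen$counts), 60)
})

test_that("the critical value is the alpha-level order statistic", {
  set.seed(9)
  fx <- makeFixtureTree(leaves = 12, nodes = 3, Ntotal = 1200,
                        maxMarginal = 400)
  sc <- scanScenario(fx$tree, fx$n, C = 40)
  t10 <- estimateCriticalValue(sc, "poisson", nNull = 200, alpha = 0.10)
  t01 <- estimateCriticalValue(sc, "poisson", nNull = 200, alpha = 0.01)
  expect_gt(t01[["poisson"]], t10[["poisson"]])
  # fresh nulls exceed T* at about the nominal rate
  tst <- estimateCriticalValue(sc, "poisson", nNull = 400, alpha = 0.05)
  cuts <- enumerateCuts(fx$tree)
  exceed <- mean(vapply(1:400, function(i) {
    g <- generateScenarioCounts(sc)
    testStatistic(scanPoisson(g$counts, cuts)) > tst[["poisson"]]
  }, logical(1)))
  expect_lt(abs(exceed - 0.05), 0.035)
})

test_that("sensitivity and PPV follow the set-intersection formulas", {
  m <- leafDetectionMetrics(c("a", "b", "c"), c("a", "b", "d", "e"))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$ppv, 2 / 3)
  m2 <- leafDetectionMetrics(1:4, 1:4)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$ppv, 1)
  expect_true(is.na(leafDetectionMetrics(integer(0), 1:2)$ppv))
})

test_that("a null scenario yields type-I error near alpha and NA sensitivity", {
  set.seed(11)
  fx <- makeFixtureTree(leaves = 12, nodes = 3, Ntotal = 1200,
                        maxMarginal = 400)
  sc <- scanScenario(fx$tree, fx$n, C = 40)
  res <- runScenario(sc, method = "poisson", nNull = 300, B = 300)
  expect_lt(abs(res$rate - 0.05), 0.045)
  expect_true(is.na(res$sensitivity))
  expect_equal(res$B_prime, as.integer(res$rate * 300))
  # an unreachable critical value gives B' = 0 and NA metrics
  res2 <- evaluatePerformance(sc, "poisson", c(poisson = Inf), B = 20)
  expect_equal(res2$B_prime, 0L)
  expect_true(is.na(res2$ppv))
})

test_that("power increases with relative risk", {
  set.seed(13)
  fx <- makeFixtureTree(leaves = 20, nodes = 4, Ntotal = 2000,
                        maxMarginal = 600)
  base <- scanScenario(fx$tree, fx$n, C = 100, sTrueSignal = 2, rr = 2)
  Tstar <- estimateCriticalValue(base, "poisson", nNull = 300)
  pw <- vapply(c(2, 8), function(r) {
    sc <- scanScenario(fx$tree, fx$n, C = 100, sTrueSignal = 2, rr = r)
    evaluatePerformance(sc, "poisson", Tstar, B = 200)$rate
  }, numeric(1))
  expect_gt(pw[2], pw[1])
})
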