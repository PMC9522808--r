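test_that("zipPmf reproduces the mixture mass function and sums to 1", {
  expect_equal(zipPmf(0, 0, 1), exp(-1))                     # Poisson limit
  expect_equal(zipPmf(0, 0.3, 1), 0.3 + 0.7 * exp(-1))
  expect_equal(zipPmf(2, 0.3, 1), 0.7 * exp(-1) / 2)
  expect_equal(zipPmf(0, 0.3, 1), 0.55751, tolerance = 1e-4)
  expect_equal(zipPmf(2, 0.3, 1), 0.12876, tolerance = 1e-4)
  for (p in c(0, 0.4, 1)) {
    expect_equal(sum(zipPmf(0:80, p, 6)), 1, tolerance = 1e-12)
  }
  expect_equal(zipPmf(c(0, 1), 1, 5), c(1, 0))   # all-structural-zero limit
})

test_that("ZIP moments show over-dispersion exactly as derived", {
  m <- zipMoments(0, 3)
  expect_equal(m$mean, 3); expect_equal(m$variance, 3)
  m <- zipMoments(0.5, 2)
  expect_equal(m$mean, 1); expect_equal(m$variance, 2)
  m <- zipMoments(1, 5)
  expect_equal(m$mean, 0); expect_equal(m$variance, 0)
  # variance exceeds mean whenever p > 0 and mu > 0
  m <- zipMoments(0.2, 4)
  expect_gt(m$variance, m$mean)
})

test_that("simulated ZIP counts match the moment identities within MC error", {
  set.seed(99)
  p <- 0.3; mu <- 4; nrep <- 20000
  x <- ifelse(stats::rbinom(nrep, 1, p) == 1, 0, stats::rpois(nrep, mu))
  m <- zipMoments(p, mu)
  expect_equal(mean(x), m$mean, tolerance = 3 * sqrt(m$variance / nrep) / m$mean)
  expect_equal(stats::var(x), m$variance, tolerance = 0.05)
})

test_that("closed-form MLEs with known structural zeros", {
  ct <- AeCounts(c("a", "b", "c"), n = c(10, 10, 10), cases = c(0, 2, 4))
  fit <- mleKnownDeltaNull(ct, c(1, 0, 0))
  expect_equal(fit$lambda0, 0.3)
  expect_equal(fit$p, 1 / 3)
  # all-zero delta reduces to the Poisson MLE
  fit0 <- mleKnownDeltaNull(ct, c(0, 0, 0))
  expect_equal(fit0$lambda0, 6 / 30)
  expect_equal(fit0$p, 0)
  # degenerate all-structural-zero table
  ctz <- AeCounts(c("a", "b"), n = c(10, 10), cases = c(0, 0))
  expect_error(mleKnownDeltaNull(ctz, c(1, 1)), "degenerate")
  # alternative-model MLEs
  ct2 <- AeCounts(c("a", "b", "c"), n = c(10, 10, 10), cases = c(3, 0, 1))
  alt <- mleKnownDeltaAlt(ct2, c(0, 1, 0), 1L)
  expect_equal(alt$lambdaG, 0.3)
  expect_equal(alt$lambdaR, 0.1)
  expect_equal(alt$p, 1 / 3)
  expect_false(alt$degenerate)
  # a cut whose only leaf is a declared structural zero
  alt2 <- mleKnownDeltaAlt(ct2, c(0, 1, 0), 2L)
  expect_equal(alt2$lambdaG, 0)
  expect_true(alt2$degenerate)
  # weight on a positive count is inconsistent
  expect_error(mleKnownDeltaAlt(ct2, c(1, 0, 0), 2L), "positive count")
})

test_that("EM short-circuits on tables with no zero counts", {
  ct <- AeCounts(c("a", "b", "c"), n = c(10, 20, 30), cases = c(2, 3, 4))
  fit <- emEstimate(ct)
  expect_equal(fit@p, 0)
  expect_equal(fit@lambda0, 9 / 60)
  expect_equal(fit@iterations, 1L)
  expect_true(all(fit@delta == 0))
  alt <- emEstimate(ct, cut = 1L)
  expect_equal(alt@lambdaG, 2 / 10)
  expect_equal(alt@lambdaR, 7 / 50)
})

test_that("the E-step posterior follows p / (p + (1-p) exp(-n lambda))", {
  # frozen arithmetic: n * lambda = log(3), p = 0.5 gives posterior 0.75
  expect_equal(0.5 / (0.5 + 0.5 * exp(-log(3))), 0.75)
  # a converged fit satisfies the self-consistency identity at every leaf
  set.seed(5)
  ct <- simulateZipTable(60, n = 40, p = 0.3, lambda = 0.08)
  fit <- emEstimate(ct)
  z <- caseCounts(ct) == 0
  expected <- fit@p / (fit@p + (1 - fit@p) *
                         exp(-marginalTotals(ct)[z] * fit@lambda0))
  expect_equal(fit@delta[z], expected, tolerance = 1e-10)
  expect_true(all(fit@delta[!z] == 0))
  expect_true(all(fit@delta >= 0 & fit@delta <= 1))
})

test_that("the EM posterior increases with p and with the Poisson mean", {
  post <- function(p, mu) p / (p + (1 - p) * exp(-mu))
  expect_true(all(diff(post(seq(0.1, 0.9, 0.1), 2)) > 0))
  expect_true(all(diff(post(0.4, seq(0.5, 5, 0.5))) > 0))
})

test_that("EM log-likelihood never decreases, for null and cut fits", {
  set.seed(17)
  tr <- toyTree6()
  cs <- enumerateCuts(tr)
  for (i in 1:20) {
    ct <- randomCounts(tr, C = sample(3:20, 1))
    fit <- emEstimate(ct)
    expect_true(all(diff(fit@loglik) >= -1e-10))
    k <- sample(nCuts(cs), 1)
    fita <- emEstimate(ct, cut = cs[k])
    expect_true(all(diff(fita@loglik) >= -1e-10))
  }
})

test_that("EM recovers the structural-zero probability on synthetic tables", {
  set.seed(31)
  ct <- simulateZipTable(1000, n = 100, p = 0.3, lambda = 0.05)
  fit <- emEstimate(ct)
  expect_true(fit@converged)
  expect_lt(abs(fit@p - 0.3), 0.05)
  expect_lt(abs(fit@lambda0 - 0.05), 0.01)
})

test_that("zipLR reduces to the Poisson LR at zero delta and obeys the indicator", {
  tr <- toyTree6()
  set.seed(41)
  ct <- randomCounts(tr, C = 15)
  cs <- enumerateCuts(tr)
  for (k in seq_len(nCuts(cs))) {
    m <- cs@members[[k]]
    lr <- zipLR(ct, rep(0, 6), cs[k])
    expect_equal(log(as.numeric(lr)),
                 poissonLogLR(sum(caseCounts(ct)[m]),
                              sum(marginalTotals(ct)[m]),
                              totalCases(ct), totalPatients(ct)),
                 tolerance = 1e-12)
  }
  # indicator false: LR is exactly 1
  ct2 <- AeCounts(paste0("L", 1:6), rep(100, 6), c(0, 2, 2, 2, 2, 2))
  expect_equal(as.numeric(zipLR(ct2, rep(0, 6), 1L)), 1)
})

test_that("zipLR matches the formula-substitution oracle", {
  ct <- AeCounts(c("a", "b", "c"), n = c(10, 10, 10), cases = c(3, 0, 1))
  d <- c(0, 1, 0)
  expect_equal(as.numeric(zipLR(ct, d, 1L)), zipLROracle(ct, d, 1L),
               tolerance = 1e-12)
  # fractional posterior weights
  set.seed(53)
  tr <- toyTree6()
  for (i in 1:15) {
    ct <- randomCounts(tr, C = 10)
    d <- ifelse(caseCounts(ct) == 0, stats::runif(6), 0)
    g <- sample(1:6, sample(1:3, 1))
    expect_equal(as.numeric(zipLR(ct, d, g)), zipLROracle(ct, d, g),
                 tolerance = 1e-9)
  }
  # degenerate side: LR 1 with a flag
  ctz <- AeCounts(c("a", "b", "c"), n = c(10, 10, 10), cases = c(0, 2, 3))
  lr <- zipLR(ctz, c(1, 0, 0), 1L)
  expect_equal(as.numeric(lr), 1)
  expect_true(attr(lr, "degenerate"))
})

test_that("scanZip equals scanPoisson exactly on tables without zeros", {
  set.seed(61)
  tr <- toyTree6()
  cs <- enumerateCuts(tr)
  ct <- AeCounts(leafIds(tr), n = rep(50, 6), cases = c(5, 1, 2, 4, 1, 3))
  rp <- scanPoisson(ct, cs)
  rz <- scanZip(ct, cs)
  expect_equal(perCutStats(rz)$stat, perCutStats(rp)$stat, tolerance = 1e-9)
  expect_identical(mostLikelyCut(rz), mostLikelyCut(rp))
  expect_equal(testStatistic(rz), testStatistic(rp), tolerance = 1e-9)
})

test_that("vectorized per-cut EM agrees with the scalar reference fit", {
  set.seed(71)
  fx <- makeFixtureTree(leaves = 40, nodes = 5, Ntotal = 6000,
                        maxMarginal = 2000)
  cs <- enumerateCuts(fx$tree)
  sc <- scanScenario(fx$tree, fx$n, C = 200, kTrueZero = 12)
  gen <- generateScenarioCounts(sc)
  r <- scanZip(gen$counts, cs)
  for (k in seq_len(nCuts(cs))) {
    fit <- emEstimate(gen$counts, cut = cs[k])
    expect_equal(perCutStats(r)$stat[k],
                 as.numeric(zipLR(gen$counts, fit@delta, cs[k], log = TRUE)),
                 tolerance = 1e-8)
    expect_equal(perCutStats(r)$p_hat[k], fit@p, tolerance = 1e-8)
  }
})

test_that("scanZip matches exhaustive per-cut evaluation on a toy instance", {
  set.seed(83)
  tr <- toyTree6()
  cs <- enumerateCuts(tr)
  ct <- AeCounts(leafIds(tr), n = c(30, 40, 25, 60, 20, 45),
                 cases = c(6, 0, 0, 3, 0, 1))
  r <- scanZip(ct, cs)
  oracle <- vapply(seq_len(nCuts(cs)), function(k) {
    fit <- emEstimate(ct, cut = cs[k])
    log(zipLROracle(ct, fit@delta, cs@members[[k]]))
  }, numeric(1))
  expect_equal(perCutStats(r)$stat, oracle, tolerance = 1e-8)
  expect_equal(testStatistic(r), max(oracle), tolerance = 1e-8)
  expect_equal(mostLikelyCut(r), cutIds(cs)[which.max(oracle)])
})

test_that("a strongly elevated leaf among many structural zeros is found", {
  set.seed(97)
  fx <- makeFixtureTree()
  cs <- enumerateCuts(fx$tree)
  sc <- scanScenario(fx$tree, fx$n, C = 640, kTrueZero = 50,
                     sTrueSignal = 1, rr = 25)
  gen <- generateScenarioCounts(sc)
  r <- scanZip(gen$counts, cs)
  hit <- leafIds(fx$tree)[gen$signalLeaves]
  parent <- fx$tree@paths[[gen$signalLeaves]][1]
  expect_true(mostLikelyCut(r) %in% c(hit, parent))
})

test_that("config variants run: hard zeros and null-fit delta source", {
  set.seed(101)
  tr <- toyTree6()
  cs <- enumerateCuts(tr)
  ct <- AeCounts(leafIds(tr), n = c(30, 40, 25, 60, 20, 45),
                 cases = c(6, 0, 0, 3, 0, 1))
  r1 <- scanZip(ct, cs, emConfig(hardZeros = TRUE))
  r2 <- scanZip(ct, cs, emConfig(deltaSource = "null"))
  expect_true(all(perCutStats(r1)$stat >= 0))
  expect_true(all(perCutStats(r2)$stat >= 0))
  # null-source weights are shared: p_hat identical across cuts
  expect_equal(length(unique(perCutStats(r2)$p_hat)), 1L)
})
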