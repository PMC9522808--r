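# Shared builders and independent oracles for the test suite.

# small two-level tree: 4 leaves under 2 nodes
toyTree4 <- function() {
  parseTree(data.frame(leaf_id = c("a", "b", "c", "d"),
                       path = c("n1", "n1", "n2", "n2"),
                       stringsAsFactors = FALSE))
}

# 6 leaves under 3 nodes, used for brute-force comparisons
toyTree6 <- function() {
  parseTree(data.frame(leaf_id = paste0("L", 1:6),
                       path = c("A", "A", "B", "B", "C", "C"),
                       stringsAsFactors = FALSE))
}

randomCounts <- function(tree, C, nRange = c(5, 60)) {
  I <- nLeaves(tree)
  n <- sample(nRange[1]:nRange[2], I, replace = TRUE)
  cases <- as.vector(stats::rmultinom(1, C, n / sum(n)))
  AeCounts(leafIds(tree), n, cases)
}

# Independent oracle for the Poisson scan statistic of one cut: numerically
# maximize the conditional multinomial log-likelihood over the rate ratio
# t = lambda_G / lambda_R >= 1, instead of using the closed form.
# Probabilities: q_i = t n_i / (t n_G + n_R) inside the cut, n_i / (...)
# outside; the null is t = 1.
poissonLogLROracle <- function(cG, nG, C, N) {
  nR <- N - nG
  if (nG <= 0 || nR <= 0 || C <= 0) return(0)
  obj <- function(logt) {
    t <- exp(logt)
    cG * logt - C * log(t * nG + nR) + C * log(N)
  }
  opt <- stats::optimize(obj, c(0, 40), maximum = TRUE, tol = 1e-12)
  max(opt$objective, 0)   # constrained to t >= 1
}

# Literal transcription of the ZIP likelihood-ratio formula with shared
# structural-zero weights, evaluated term by term (log scale only at the
# end via exact power sums).
zipLROracle <- function(counts, d, memberIdx) {
  cth <- caseCounts(counts)
  n <- marginalTotals(counts)
  g <- memberIdx
  cw <- cth * (1 - d)
  nw <- n * (1 - d)
  sCG <- sum(cw[g]);  sNG <- sum(nw[g])
  sCR <- sum(cw[-g]); sNR <- sum(nw[-g])
  sCT <- sum(cw);     sNT <- sum(nw)
  if (sNG <= 0 || sNR <= 0) return(1)
  if (!(sCG / sNG > sCR / sNR)) return(1)
  pw <- function(base, expo) if (expo == 0) 0 else expo * log(base)
  exp(pw(sCG / sNG, sCG) + pw(sCR / sNR, sCR) - pw(sCT / sNT, sCT))
}

# exhaustive member-set enumeration for cut counting: every leaf singleton
# plus every distinct internal-node leaf set that is a strict subset
cutCountOracle <- function(tree) {
  I <- nLeaves(tree)
  sets <- lapply(seq_len(I), identity)
  for (nd in nodeIds(tree)) {
    idx <- which(vapply(tree@paths, function(p) nd %in% p, logical(1)))
    if (length(idx) < I) sets <- c(sets, list(idx))
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), "")
  length(unique(keys))
}

# draw a ZIP count table directly from the model definition
simulateZipTable <- function(I, n, p, lambda) {
  delta <- stats::rbinom(I, 1, p)
  cases <- ifelse(delta == 1, 0, stats::rpois(I, n * lambda))
  AeCounts(paste0("L", seq_len(I)), rep(n, I), cases)
}
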