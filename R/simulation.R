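#' Build a synthetic benchmark tree and marginal totals
#'
#' Generates a two-level hierarchy for simulation work: `nodes` internal
#' nodes partitioning `leaves` leaf terms (each node gets at least two
#' leaves, the remainder spread at random), with right-skewed marginal
#' totals drawn from a log-normal distribution, clipped to
#' `[minMarginal, maxMarginal]` and integer-rescaled to sum exactly to
#' `Ntotal`. The defaults emulate a WHO-ART SOC/PT excerpt of 105 preferred
#' terms under 9 system-organ classes, marginals between 10 and 4670
#' summing to 19,920. Deterministic for a given RNG state (seed with
#' [set.seed()]).
#'
#' @param leaves number of leaf terms (default 105).
#' @param nodes number of internal nodes (default 9).
#' @param minMarginal,maxMarginal bounds on each leaf's marginal total.
#' @param Ntotal sum of all marginal totals (default 19,920).
#' @param sdlog log-scale standard deviation of the marginal distribution
#'   (default 1.4, giving a heavy right tail like real AE term frequencies).
#' @return list with elements `tree` (an [AeTree]) and `n` (integer
#'   marginals in leaf order).
#' @export
makeFixtureTree <- function(leaves = 105L, nodes = 9L, minMarginal = 10L,
                            maxMarginal = 4670L, Ntotal = 19920L,
                            sdlog = 1.4) {
  leaves <- as.integer(leaves); nodes <- as.integer(nodes)
  if (leaves < 2L * nodes)
    stop("need at least 2 leaves per node")
  if (Ntotal < leaves * minMarginal || Ntotal > leaves * maxMarginal)
    stop(sprintf("infeasible: Ntotal = %d cannot be split over %d leaves in [%d, %d]",
                 Ntotal, leaves, minMarginal, maxMarginal))
  sizes <- 2L + as.vector(stats::rmultinom(1L, leaves - 2L * nodes,
                                           rep(1 / nodes, nodes)))
  nodeIds <- sprintf("SOC%d", seq_len(nodes))
  leafIds <- sprintf("PT%03d", seq_len(leaves))
  paths <- rep(nodeIds, sizes)
  tree <- parseTree(data.frame(leaf_id = leafIds, path = paths,
                               stringsAsFactors = FALSE))
  x <- stats::rlnorm(leaves, meanlog = log(Ntotal / leaves) - sdlog^2 / 2,
                     sdlog = sdlog)
  n <- .rescaleBounded(x, Ntotal, minMarginal, maxMarginal)
  list(tree = tree, n = n)
}

# scale positive reals to integer counts summing to total within [lo, hi]
.rescaleBounded <- function(x, total, lo, hi) {
  x <- x / sum(x) * total
  for (i in 1:50) {
    out <- x < lo | x > hi
    if (!any(out)) break
    x[x < lo] <- lo
    x[x > hi] <- hi
    free <- !out
    rem <- total - sum(x[out])
    if (!any(free)) break
    if (rem < sum(free) * lo) {        # clipping pushed too much mass out
      x[free] <- lo
      break
    }
    x[free] <- x[free] / sum(x[free]) * rem
  }
  y <- floor(x)
  y <- pmax(y, lo)
  d <- total - sum(y)
  if (d > 0) {
    room <- which(y < hi)
    ord <- room[order(x[room] - y[room], decreasing = TRUE)]
    bump <- rep_len(ord, d)
    for (i in bump) y[i] <- y[i] + 1L
  } else if (d < 0) {
    room <- which(y > lo)
    ord <- room[order(x[room] - y[room])]
    drop <- rep_len(ord, -d)
    for (i in drop) y[i] <- y[i] - 1L
  }
  if (sum(y) != total || any(y < lo) || any(y > hi))
    stop("failed to rescale marginals within bounds")
  as.integer(y)
}

#' Define a simulation scenario
#'
#' A scenario bundles the tree, the marginal totals, the drug total C, the
#' number of structural-zero ("true zero") leaves, the number of elevated
#' ("true signal") leaves and their relative risks. True-zero and
#' true-signal leaves are re-drawn uniformly at random on every generated
#' dataset (disjointly), so performance metrics marginalize over
#' placements; all other leaves have relative risk 1.
#'
#' @param tree an [AeTree].
#' @param n marginal totals in leaf order.
#' @param C drug total to distribute per dataset (default 640).
#' @param kTrueZero number of structural-zero leaves (default 0).
#' @param sTrueSignal number of elevated leaves (default 0: a null
#'   scenario).
#' @param rr relative risk of the elevated leaves: a scalar, or a vector of
#'   length `sTrueSignal` assigning one value per signal leaf.
#' @return list of class `scanScenario`.
#' @export
scanScenario <- function(tree, n, C = 640L, kTrueZero = 0L,
                         sTrueSignal = 0L, rr = 1) {
  stopifnot(is(tree, "AeTree"), length(n) == nLeaves(tree), C >= 1)
  I <- nLeaves(tree)
  kTrueZero <- as.integer(kTrueZero)
  sTrueSignal <- as.integer(sTrueSignal)
  if (kTrueZero < 0L || kTrueZero >= I)
    stop("kTrueZero must be in [0, I)")
  if (sTrueSignal < 0L || sTrueSignal + kTrueZero >= I)
    stop("sTrueSignal + kTrueZero must be less than the number of leaves")
  if (!length(rr) %in% c(1L, max(sTrueSignal, 1L)))
    stop("rr must be a scalar or one value per signal leaf")
  if (any(rr <= 0)) stop("relative risks must be positive")
  structure(list(tree = tree, n = as.numeric(n), C = as.integer(C),
                 kTrueZero = kTrueZero, sTrueSignal = sTrueSignal, rr = rr),
            class = "scanScenario")
}

#' Randomly allocate structural-zero leaves
#'
#' Chooses exactly `k` of the tree's leaves uniformly at random to be
#' structural zeros.
#'
#' @param tree an [AeTree] (or an integer leaf count).
#' @param k number of structural-zero leaves.
#' @return 0/1 vector over leaves with exactly `k` ones.
#' @export
allocateTrueZeros <- function(tree, k) {
  I <- if (is(tree, "AeTree")) nLeaves(tree) else as.integer(tree)
  k <- as.integer(k)
  if (k < 0L || k >= I) stop("k must be in [0, I)")
  delta <- numeric(I)
  if (k > 0L) delta[sample.int(I, k)] <- 1
  delta
}

#' Generate one dataset under a scenario
#'
#' Draws the structural-zero leaves, then the signal leaves uniformly from
#' the remaining leaves, then distributes the drug total C multinomially
#' with probabilities proportional to `rr_i * n_i` (relative risk 1 off the
#' signal leaves, probability 0 on the structural-zero leaves). With
#' `sTrueSignal = 0` and `kTrueZero = 0` this reduces to a plain
#' conditional null draw.
#'
#' @param scenario a [scanScenario()].
#' @return list with `counts` (an [AeCounts]), `signalLeaves` (integer
#'   indices, possibly empty) and `delta` (the 0/1 structural-zero vector).
#' @export
generateScenarioCounts <- function(scenario) {
  stopifnot(inherits(scenario, "scanScenario"))
  I <- nLeaves(scenario$tree)
  delta <- allocateTrueZeros(scenario$tree, scenario$kTrueZero)
  nonzero <- which(delta == 0)
  signal <- integer(0)
  rrvec <- rep(1, I)
  if (scenario$sTrueSignal > 0L) {
    signal <- sort(sample(nonzero, scenario$sTrueSignal))
    rrvec[signal] <- rep_len(scenario$rr, scenario$sTrueSignal)
  }
  prob <- rrvec * scenario$n
  prob[delta == 1] <- 0
  prob <- prob / sum(prob)
  cases <- as.vector(stats::rmultinom(1L, scenario$C, prob))
  counts <- new("AeCounts", leafIds = leafIds(scenario$tree),
                n = scenario$n, cases = as.numeric(cases))
  list(counts = counts, signalLeaves = signal, delta = delta)
}

.nullScenario <- function(scenario) {
  scanScenario(scenario$tree, scenario$n, scenario$C,
               kTrueZero = scenario$kTrueZero, sTrueSignal = 0L, rr = 1)
}

#' Estimate the simulation critical value T*
#'
#' Draws `nNull` datasets under the null variant of the scenario (relative
#' risk 1 everywhere, structural-zero leaves re-drawn each replicate),
#' scans each, and returns the `ceiling(alpha * nNull)`-th largest maximum
#' statistic per method. A dataset's statistic exceeding T* is then
#' declared significant at level `alpha`.
#'
#' @param scenario a [scanScenario()] (its signal settings are ignored).
#' @param method character vector of methods (`"poisson"`, `"zip"`); both
#'   are evaluated on the same replicate tables.
#' @param nNull number of null datasets (default 1000; at least 20).
#' @param alpha significance level (default 0.05).
#' @param config [emConfig()] for the ZIP scan.
#' @return named numeric vector of critical values (log scale).
#' @export
estimateCriticalValue <- function(scenario, method = c("poisson", "zip"),
                                  nNull = 1000L, alpha = 0.05,
                                  config = emConfig()) {
  method <- match.arg(method, several.ok = TRUE)
  stopifnot(nNull >= 20L)
  nullSc <- .nullScenario(scenario)
  cuts <- enumerateCuts(scenario$tree)
  Tnull <- matrix(NA_real_, nrow = nNull, ncol = length(method),
                  dimnames = list(NULL, method))
  for (b in seq_len(nNull)) {
    gen <- generateScenarioCounts(nullSc)
    for (m in method)
      Tnull[b, m] <- .scanOnce(gen$counts, cuts, m, config)@logT
  }
  idx <- ceiling(alpha * nNull)
  apply(Tnull, 2L, function(v) sort(v, decreasing = TRUE)[idx])
}

#' Sensitivity and PPV of a detected leaf set
#'
#' Leaf-level detection metrics: sensitivity is the fraction of true signal
#' leaves that were detected, PPV the fraction of detected leaves that are
#' true signals.
#'
#' @param detected integer indices (or ids) of detected leaves.
#' @param truth integer indices (or ids) of planted signal leaves.
#' @return list with `sensitivity` and `ppv` (NA when the respective
#'   denominator is empty).
#' @export
leafDetectionMetrics <- function(detected, truth) {
  hits <- length(intersect(detected, truth))
  list(sensitivity = if (length(truth)) hits / length(truth) else NA_real_,
       ppv = if (length(detected)) hits / length(detected) else NA_real_)
}

#' Evaluate type-I error or power, sensitivity and PPV
#'
#' Generates `B` datasets under the scenario (its null variant when
#' `sTrueSignal = 0`), computes each dataset's maximum statistic `T_k`, and
#' estimates `rate = mean(T_k > T*)` — the type-I error for a null
#' scenario, the power otherwise. For each significant dataset the detected
#' signal is the union of leaves in every cut whose statistic exceeds T*;
#' sensitivity and PPV against the planted signal leaves are averaged over
#' the `B'` significant datasets only (NA when `B' = 0`).
#'
#' @inheritParams estimateCriticalValue
#' @param Tstar named critical values from [estimateCriticalValue()] (one
#'   per method, log scale).
#' @param B number of evaluation datasets (default 1000).
#' @return data.frame with one row per method: `method`, `rate`,
#'   `sensitivity`, `ppv`, `B`, `B_prime`, `Tstar`.
#' @export
evaluatePerformance <- function(scenario, method = c("poisson", "zip"),
                                Tstar, B = 1000L, config = emConfig()) {
  method <- match.arg(method, several.ok = TRUE)
  stopifnot(B >= 1L, all(method %in% names(Tstar)))
  cuts <- enumerateCuts(scenario$tree)
  members <- cuts@members
  nsig <- stats::setNames(integer(length(method)), method)
  senssum <- ppvsum <- stats::setNames(numeric(length(method)), method)
  nsp <- stats::setNames(integer(length(method)), method)  # datasets with metrics
  for (b in seq_len(B)) {
    gen <- generateScenarioCounts(scenario)
    for (m in method) {
      res <- .scanOnce(gen$counts, cuts, m, config)
      if (res@logT > Tstar[[m]]) {
        nsig[[m]] <- nsig[[m]] + 1L
        if (scenario$sTrueSignal > 0L) {
          hot <- which(res@perCut$stat > Tstar[[m]])
          detected <- unique(unlist(members[hot], use.names = FALSE))
          metr <- leafDetectionMetrics(detected, gen$signalLeaves)
          senssum[[m]] <- senssum[[m]] + metr$sensitivity
          ppvsum[[m]] <- ppvsum[[m]] + metr$ppv
          nsp[[m]] <- nsp[[m]] + 1L
        }
      }
    }
  }
  data.frame(
    method = method,
    rate = as.numeric(nsig[method]) / B,
    sensitivity = ifelse(nsp[method] > 0, senssum[method] / nsp[method],
                         NA_real_),
    ppv = ifelse(nsp[method] > 0, ppvsum[method] / nsp[method], NA_real_),
    B = B,
    B_prime = as.integer(nsig[method]),
    Tstar = as.numeric(Tstar[method]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run a full scenario: critical values then operating characteristics
#'
#' Convenience wrapper chaining [estimateCriticalValue()] and
#' [evaluatePerformance()].
#'
#' @inheritParams evaluatePerformance
#' @param nNull null datasets for the critical value.
#' @param alpha significance level.
#' @return the [evaluatePerformance()] data.frame, with attribute
#'   `"Tstar"`.
#' @export
runScenario <- function(scenario, method = c("poisson", "zip"),
                        nNull = 1000L, B = 1000L, alpha = 0.05,
                        config = emConfig()) {
  method <- match.arg(method, several.ok = TRUE)
  Tstar <- estimateCriticalValue(scenario, method, nNull = nNull,
                                 alpha = alpha, config = config)
  out <- evaluatePerformance(scenario, method, Tstar, B = B, config = config)
  attr(out, "Tstar") <- Tstar
  out
}
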