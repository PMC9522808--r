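#' Draw a conditional null count table
#'
#' Conditional on the drug total C and the marginal totals n, a null table
#' is a single draw from Multinomial(C; n_1/N, ..., n_I/N). Leaves marked
#' structural-zero in `zeroProfile` get probability 0 (their counts are 0 in
#' every draw) and the remaining probabilities are renormalized. Uses R's
#' global random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param n per-leaf marginal totals.
#' @param C drug total to distribute.
#' @param zeroProfile optional 0/1 vector (or logical) marking structural
#'   zeros; `NULL` for none.
#' @param leafIds leaf identifiers for the returned table (defaults to
#'   `"L1"..."LI"`).
#' @return an [AeCounts] with `sum(cases) == C` exactly.
#' @export
generateNullCounts <- function(n, C, zeroProfile = NULL, leafIds = NULL) {
  if (is(n, "AeCounts")) {
    if (is.null(leafIds)) leafIds <- n@leafIds
    n <- n@n
  }
  stopifnot(C >= 0, sum(n) > 0)
  if (is.null(leafIds)) leafIds <- paste0("L", seq_along(n))
  prob <- n / sum(n)
  if (!is.null(zeroProfile)) {
    zp <- as.logical(zeroProfile > 0)
    if (length(zp) != length(n))
      stop("zeroProfile length must equal the number of leaves")
    if (all(zp | n == 0))
      stop("zeroProfile excludes every leaf with positive marginal total")
    prob[zp] <- 0
    prob <- prob / sum(prob)
  }
  cases <- as.vector(stats::rmultinom(1L, size = C, prob = prob))
  new("AeCounts", leafIds = as.character(leafIds), n = as.numeric(n),
      cases = as.numeric(cases))
}

.scanOnce <- function(counts, cuts, method, config) {
  if (method == "poisson") scanPoisson(counts, cuts)
  else scanZip(counts, cuts, config)
}

#' Monte Carlo test of the maximum scan statistic
#'
#' Compares the observed maximum statistic to its conditional null
#' distribution: B replicate tables are drawn with the same C, N and
#' marginals (see [generateNullCounts()]), each is scanned, and the
#' p-value is `rank / (1 + B)` where `rank = 1 + #\{b : T_b >= T_obs\}`
#' (null values tied with the observed count against it, which keeps the
#' null p-values conservative). The smallest attainable p-value is
#' `1 / (1 + B)`.
#'
#' @param counts observed [AeCounts].
#' @param cuts a [CutSet].
#' @param method `"poisson"` or `"zip"`.
#' @param B number of Monte Carlo replicates (e.g. 999).
#' @param zeroProfile optional structural-zero profile for the null draws
#'   (used by the simulation framework; real-data nulls are plain
#'   conditional multinomials).
#' @param config [emConfig()] for the ZIP scan.
#' @return a [MonteCarloResult].
#' @export
monteCarloTest <- function(counts, cuts, method = c("poisson", "zip"),
                           B = 999L, zeroProfile = NULL,
                           config = emConfig()) {
  method <- match.arg(method)
  stopifnot(B >= 1L)
  if (sum(counts@cases) < 1) stop("the observed table has no drug cases")
  obs <- .scanOnce(counts, cuts, method, config)
  nullT <- vapply(seq_len(B), function(b) {
    rep <- generateNullCounts(counts@n, sum(counts@cases),
                              zeroProfile = zeroProfile,
                              leafIds = counts@leafIds)
    .scanOnce(rep, cuts, method, config)@logT
  }, numeric(1))
  rank <- 1L + sum(nullT >= obs@logT)
  new("MonteCarloResult", observed = obs@logT, nullT = nullT,
      rank = rank, pValue = rank / (1 + B), B = as.integer(B),
      method = method)
}

#' @rdname accessors
#' @export
setMethod("pValue", "MonteCarloResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("nullStatistics", "MonteCarloResult", function(x) x@nullT)

#' @rdname accessors
#' @export
setMethod("testStatistic", "MonteCarloResult",
          function(x, log = TRUE) if (log) x@observed else exp(x@observed))

setMethod("show", "MonteCarloResult", function(object) {
  cat(sprintf("MonteCarloResult (%s): log T = %.4f, rank %d of %d, p = %.4g\n",
              object@method, object@observed, object@rank, object@B + 1L,
              object@pValue))
})

#' Scan a table and report signals
#'
#' Runs the chosen scan, builds the null distribution of the maximum
#' statistic by Monte Carlo, and refers every cut's statistic to that same
#' distribution: `p_cut = (1 + #\{b : T_b >= stat_cut\}) / (1 + B)`.
#' Because all cuts share the null maximum distribution this controls the
#' family-wise error rate, the standard scan-statistic adjustment for the
#' overlapping multiple comparisons. Cuts with `p < alpha` are flagged as
#' signals.
#'
#' The expected count is `n_G * C / N` for the Poisson method and the ZIP
#' marginal mean `(1 - p0) * n_G * lambda0` (null-model EM fit) for the
#' ZIP method, which discounts the baseline by the estimated
#' structural-zero mass.
#'
#' @inheritParams monteCarloTest
#' @param alpha signal threshold on the Monte Carlo p-value (default 0.05).
#' @param labels optional per-cut labels (e.g. AE term names); defaults to
#'   empty.
#' @return a [SignalReport].
#' @export
detectSignals <- function(counts, cuts, method = c("poisson", "zip"),
                          B = 999L, alpha = 0.05, zeroProfile = NULL,
                          config = emConfig(), labels = NULL) {
  method <- match.arg(method)
  obs <- .scanOnce(counts, cuts, method, config)
  mc <- monteCarloTest(counts, cuts, method, B = B,
                       zeroProfile = zeroProfile, config = config)
  stat <- obs@perCut$stat
  pcut <- vapply(stat, function(s) (1 + sum(mc@nullT >= s)) / (1 + B),
                 numeric(1))
  C <- sum(counts@cases)
  N <- sum(counts@n)
  if (method == "poisson") {
    expd <- expectedCountPoisson(obs@perCut$n_G, C, N)
  } else {
    nullFit <- emEstimate(counts, cut = NULL, config = config)
    expd <- (1 - nullFit@p) * obs@perCut$n_G * nullFit@lambda0
  }
  if (is.null(labels)) labels <- rep("", nrow(obs@perCut))
  tab <- data.frame(
    cut_id = obs@perCut$cut_id,
    level = obs@perCut$level,
    label = labels,
    marginal_total = obs@perCut$n_G,
    obs = obs@perCut$c_G,
    exp = expd,
    obs_over_exp = obsOverExpected(obs@perCut$c_G, expd, digits = NULL),
    p_value = pcut,
    signal_flag = pcut < alpha,
    stringsAsFactors = FALSE
  )
  new("SignalReport", table = tab, alpha = alpha, method = method,
      B = as.integer(B))
}

#' @rdname accessors
#' @export
setMethod("signalTable", "SignalReport", function(x) x@table)

setMethod("show", "SignalReport", function(object) {
  cat(sprintf("SignalReport (%s, B = %d, alpha = %.3g): %d cuts, %d signals\n",
              object@method, object@B, object@alpha, nrow(object@table),
              sum(object@table$signal_flag)))
})

#' Write a signal report as TSV
#'
#' Columns `cut_id`, `level`, `label`, `marginal_total`, `obs`, `exp`,
#' `obs_over_exp`, `p_value`, `signal_flag`, one row per cut in tree order.
#'
#' @param report a [SignalReport].
#' @param file output path.
#' @param digits rounding for `exp` and `obs_over_exp` (default 1, the
#'   convention of printed signal tables); `NULL` for full precision.
#' @return `file`, invisibly.
#' @export
writeSignalReport <- function(report, file, digits = 1) {
  stopifnot(is(report, "SignalReport"))
  tab <- report@table
  if (!is.null(digits)) {
    tab$exp <- round(tab$exp, digits)
    tab$obs_over_exp <- round(tab$obs_over_exp, digits)
  }
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
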