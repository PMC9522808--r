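# x * log(y) with the multinomial convention 0 * log(0) = 0
.xlogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(y[pos])
  out
}

# Core two-sample log likelihood ratio for rates cG/nG vs cR/nR against the
# pooled rate, with the one-sided (high inside rate) indicator. Weights may
# be fractional (effective sample sizes under ZIP posterior weighting).
# Indicator evaluated by cross-multiplication to avoid division round-off.
.logLRcore <- function(cG, nG, cR, nR) {
  K <- max(length(cG), length(nG), length(cR), length(nR))
  cG <- rep_len(cG, K); nG <- rep_len(nG, K)
  cR <- rep_len(cR, K); nR <- rep_len(nR, K)
  stat <- numeric(K)
  Ctot <- cG + cR
  Ntot <- nG + nR
  ok <- nG > 0 & nR > 0 & Ctot > 0 & (cG * nR > cR * nG)
  if (any(ok)) {
    stat[ok] <- .xlogy(cG[ok], cG[ok] / nG[ok]) +
      .xlogy(cR[ok], cR[ok] / nR[ok]) -
      .xlogy(Ctot[ok], Ctot[ok] / Ntot[ok])
  }
  # numeric safety: tiny negatives from cancellation clipped to 0
  pmax(stat, 0)
}

#' Poisson/multinomial scan log likelihood ratio for one cut
#'
#' The log likelihood ratio comparing the drug-attributable AE rate inside a
#' cut (c_G out of n_G) against the rate outside (C - c_G out of N - n_G),
#' under multinomial conditioning on the drug total C. Returns
#' `C*log(N/C) + c_G*log(c_G/n_G) + (C-c_G)*log((C-c_G)/(N-n_G))` when the
#' inside rate exceeds the outside rate, and 0 otherwise, with the
#' convention 0*log(0) = 0. The additive constant `C*log(N/C)` makes the
#' statistic a true non-negative log likelihood ratio (0 exactly when the
#' cut shows no excess); it is constant across cuts and across conditional
#' null replicates, so rankings and Monte Carlo p-values are unchanged
#' relative to the display form that omits it.
#'
#' @param cG,nG drug cases and marginal total inside the cut (vectorized).
#' @param C,N overall drug cases and marginal total.
#' @return non-negative log likelihood ratio(s). Degenerate inputs
#'   (`nG` 0 or `N`, or `C = 0`) give 0: no cases, no evidence.
#' @examples
#' poissonLogLR(1, 10, 10, 100)     # inside rate equals pooled rate -> 0
#' poissonLogLR(5, 50, 10, 1000)    # ~8.3037
#' @export
poissonLogLR <- function(cG, nG, C, N) {
  .logLRcore(cG, nG, C - cG, N - nG)
}

#' Expected count under the null rate
#'
#' Expected number of drug cases in a cut with marginal total `nG` when the
#' drug-attributable rate is homogeneous: `nG * C / N`. This is the "Exp"
#' column of a Poisson-scan signal report; O/E is the observed count divided
#' by this value.
#'
#' @param nG marginal total of the cut.
#' @param C,N overall drug cases and marginal total.
#' @return expected count (vectorized over `nG`).
#' @export
expectedCountPoisson <- function(nG, C, N) {
  stopifnot(N > 0)
  nG * C / N
}

#' Observed-over-expected ratio
#'
#' @param obs observed count.
#' @param expected expected count; the ratio is undefined (NA) when 0.
#' @param digits rounding used in printed reports (1 decimal, the field's
#'   convention); use `NULL` for no rounding.
#' @return O/E ratio.
#' @export
obsOverExpected <- function(obs, expected, digits = 1) {
  oe <- ifelse(expected > 0, obs / expected, NA_real_)
  if (!is.null(digits)) oe <- round(oe, digits)
  oe
}

#' Poisson/multinomial tree-based scan
#'
#' Evaluates [poissonLogLR()] on every candidate cut and records the
#' maximum statistic and the most likely cut (first cut in enumeration
#' order on ties).
#'
#' @param counts an [AeCounts].
#' @param cuts a [CutSet] on the same leaf set.
#' @return a [ScanResult] with `method = "poisson"`. When the table has no
#'   drug cases (C = 0) all statistics are 0 and the result carries a
#'   `"no-cases"` flag.
#' @export
scanPoisson <- function(counts, cuts) {
  agg <- aggregateCounts(counts, cuts)
  C <- sum(counts@cases)
  N <- sum(counts@n)
  flags <- character()
  if (C == 0) {
    warning("count table has no drug cases (C = 0); all statistics are 0")
    flags <- "no-cases"
  }
  stat <- poissonLogLR(agg$c_G, agg$n_G, C, N)
  rr <- .relativeRisk(agg$c_G, agg$n_G, C, N)
  perCut <- data.frame(agg, stat = stat, rr_est = rr,
                       stringsAsFactors = FALSE)
  best <- which.max(stat)   # first maximum wins
  new("ScanResult", perCut = perCut, logT = stat[best],
      mostLikelyCut = agg$cut_id[best], method = "poisson", flags = flags)
}

# MLE of lambda_G / lambda_R given the cut
.relativeRisk <- function(cG, nG, C, N) {
  cR <- C - cG
  nR <- N - nG
  ifelse(nG > 0 & nR > 0 & cR > 0, (cG / nG) / (cR / nR),
         ifelse(nG > 0 & nR > 0 & cG > 0, Inf, NA_real_))
}

#' @rdname accessors
#' @param log for `testStatistic` on a [ScanResult]: return the log
#'   statistic (default) or the likelihood ratio itself.
#' @export
setMethod("testStatistic", "ScanResult", function(x, log = TRUE) {
  if (log) x@logT else exp(x@logT)
})

#' @rdname accessors
#' @export
setMethod("mostLikelyCut", "ScanResult", function(x) x@mostLikelyCut)

#' @rdname accessors
#' @export
setMethod("perCutStats", "ScanResult", function(x) x@perCut)

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d cuts, log T = %.4f, most likely cut '%s'\n",
              object@method, nrow(object@perCut), object@logT,
              object@mostLikelyCut))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
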