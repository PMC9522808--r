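#' EM configuration for the ZIP scan
#'
#' @param tol relative change in observed-data log-likelihood below which EM
#'   stops (default 1e-8).
#' @param maxIter maximum EM iterations (default 500).
#' @param hardZeros if TRUE, threshold the posterior structural-zero weights
#'   to 0/1 at `hardThreshold` before evaluating the likelihood ratio
#'   (sensitivity analysis; default off, soft posteriors are used directly).
#' @param hardThreshold threshold for `hardZeros` (default 0.5).
#' @param deltaSource `"alternative"` (default): each cut's likelihood ratio
#'   uses the posterior weights from that cut's own alternative-model EM
#'   fit; `"null"`: all cuts share the weights from the single null-model
#'   fit (comparison variant).
#' @return a list of class `emConfig`.
#' @export
emConfig <- function(tol = 1e-8, maxIter = 500L, hardZeros = FALSE,
                     hardThreshold = 0.5,
                     deltaSource = c("alternative", "null")) {
  stopifnot(tol > 0, maxIter >= 1)
  structure(list(tol = tol, maxIter = as.integer(maxIter),
                 hardZeros = isTRUE(hardZeros),
                 hardThreshold = hardThreshold,
                 deltaSource = match.arg(deltaSource)),
            class = "emConfig")
}

#' Zero-inflated Poisson probability mass function
#'
#' A ZIP(p, mu) variable is 0 with probability `p` (a structural zero) and
#' Poisson(mu) with probability `1 - p`, so
#' `P(X = 0) = p + (1-p) exp(-mu)` and
#' `P(X = c) = (1-p) exp(-mu) mu^c / c!` for `c > 0`.
#'
#' @param x non-negative integer count(s).
#' @param p structural-zero probability in \[0, 1\].
#' @param mu Poisson mean (here `n_i * lambda_i`).
#' @param log return log probabilities.
#' @return probability mass at `x` (vectorized).
#' @examples
#' zipPmf(0, 0.3, 1)  # 0.3 + 0.7 * exp(-1)
#' @export
zipPmf <- function(x, p, mu, log = FALSE) {
  stopifnot(all(p >= 0 & p <= 1), all(mu >= 0))
  K <- max(length(x), length(p), length(mu))
  x <- rep_len(x, K); p <- rep_len(p, K); mu <- rep_len(mu, K)
  out <- numeric(K)
  z <- x == 0
  out[z] <- p[z] + (1 - p[z]) * exp(-mu[z])
  out[!z] <- (1 - p[!z]) * stats::dpois(x[!z], mu[!z])
  if (log) base::log(out) else out
}

#' Mean and variance of the ZIP distribution
#'
#' `E = (1-p) mu` and `V = (1-p) mu (1 + p mu)`; the variance exceeds the
#' mean whenever `p > 0` and `mu > 0`, which is the over-dispersion that
#' motivates the zero-inflated model for AE count tables.
#'
#' @inheritParams zipPmf
#' @return list with elements `mean` and `variance`.
#' @export
zipMoments <- function(p, mu) {
  stopifnot(all(p >= 0 & p <= 1), all(mu >= 0))
  list(mean = (1 - p) * mu, variance = (1 - p) * mu * (1 + p * mu))
}

# guard: structural-zero weight on a positive count is inconsistent
.checkDelta <- function(counts, d) {
  if (length(d) != length(counts@cases))
    stop("delta vector length must equal the number of leaves")
  if (any(d < 0 | d > 1))
    stop("delta weights must lie in [0, 1]")
  if (any(d > 0 & counts@cases > 0))
    stop("delta weight positive on a leaf with a positive count")
}

#' Closed-form ZIP MLEs with known structural zeros (null model)
#'
#' With known indicators `d_i` (1 = structural zero), the null-model MLEs
#' are `lambda0 = sum(c_i (1-d_i)) / sum(n_i (1-d_i))` and `p0 = sum(d_i)/I`.
#' Fractional weights (EM posteriors) are accepted in place of indicators.
#'
#' @param counts an [AeCounts].
#' @param d per-leaf structural-zero indicators or weights in \[0, 1\];
#'   positive only where the observed count is 0.
#' @return list with elements `p` and `lambda0`.
#' @export
mleKnownDeltaNull <- function(counts, d) {
  stopifnot(is(counts, "AeCounts"))
  .checkDelta(counts, d)
  wN <- sum(counts@n * (1 - d))
  if (wN <= 0)
    stop("all leaves carry structural-zero weight: the table is degenerate")
  list(p = sum(d) / length(d), lambda0 = sum(counts@cases * (1 - d)) / wN)
}

#' Closed-form ZIP MLEs with known structural zeros (alternative model)
#'
#' Per-side rate MLEs for a cut G:
#' `lambdaG = sum_G(c_i (1-d_i)) / sum_G(n_i (1-d_i))`, analogously
#' `lambdaR` over the complement, and the shared `p = sum(d_i)/I`. A side
#' whose effective weight `sum(n_i (1-d_i))` is zero gets rate 0 and the
#' `degenerate` flag.
#'
#' @inheritParams mleKnownDeltaNull
#' @param cut a single-cut [CutSet] or an integer vector of member leaf
#'   indices.
#' @return list with `p`, `lambdaG`, `lambdaR`, `degenerate`.
#' @export
mleKnownDeltaAlt <- function(counts, d, cut) {
  stopifnot(is(counts, "AeCounts"))
  .checkDelta(counts, d)
  g <- .cutIndices(cut, length(counts@cases))
  w <- counts@n * (1 - d)
  cw <- counts@cases * (1 - d)
  wG <- sum(w[g]); wR <- sum(w[-g])
  degenerate <- wG <= 0 || wR <= 0
  list(p = sum(d) / length(d),
       lambdaG = if (wG > 0) sum(cw[g]) / wG else 0,
       lambdaR = if (wR > 0) sum(cw[-g]) / wR else 0,
       degenerate = degenerate)
}

.cutIndices <- function(cut, I) {
  if (is(cut, "CutSet")) {
    if (length(cut@cutIds) != 1L)
      stop("supply a single cut (subset the CutSet first)")
    g <- cut@members[[1L]]
  } else {
    g <- as.integer(cut)
  }
  if (length(g) == 0L || length(g) >= I || any(g < 1L | g > I))
    stop("cut members must be a non-empty strict subset of the leaves")
  g
}

#' EM estimation of the ZIP model with unknown structural zeros
#'
#' Fits the ZIP model by expectation-maximization when it is unknown which
#' zero counts are structural. The E-step computes the posterior
#' structural-zero weight of each zero-count leaf,
#' `delta_i = p / (p + (1-p) exp(-n_i lambda))`, where `lambda` is the null
#' rate for a null-model fit and the side-specific rate (`lambdaG` inside
#' the cut, `lambdaR` outside) for an alternative-model fit. The M-step
#' plugs the posteriors into the closed-form known-delta MLEs. Iteration
#' stops when the observed-data log-likelihood changes by less than
#' `config$tol` (relative) or at `config$maxIter`.
#'
#' Tables with no zero counts short-circuit: the posterior is identically
#' 0, `p = 0`, and the rates are the ordinary Poisson MLEs.
#'
#' @param counts an [AeCounts].
#' @param cut `NULL` for the null model, or a single cut ([CutSet] or
#'   member-index vector) for the alternative model.
#' @param config an [emConfig()].
#' @return a [ZipFit].
#' @export
emEstimate <- function(counts, cut = NULL, config = emConfig()) {
  stopifnot(is(counts, "AeCounts"))
  cases <- counts@cases
  n <- counts@n
  I <- length(cases)
  C <- sum(cases)
  N <- sum(n)
  null_model <- is.null(cut)
  if (!null_model) g <- .cutIndices(cut, I)
  z <- which(cases == 0)

  if (length(z) == 0L) {
    # no zeros: the E-step indicator kills all posteriors
    if (null_model) {
      lam0 <- C / N
      ll <- sum(stats::dpois(cases, n * lam0, log = TRUE))
      return(new("ZipFit", p = 0, lambda0 = lam0, lambdaG = NA_real_,
                 lambdaR = NA_real_, delta = numeric(I), loglik = ll,
                 converged = TRUE, iterations = 1L, degenerate = FALSE))
    }
    lamG <- sum(cases[g]) / sum(n[g])
    lamR <- sum(cases[-g]) / sum(n[-g])
    mu <- ifelse(seq_len(I) %in% g, n * lamG, n * lamR)
    ll <- sum(stats::dpois(cases, mu, log = TRUE))
    return(new("ZipFit", p = 0, lambda0 = NA_real_, lambdaG = lamG,
               lambdaR = lamR, delta = numeric(I), loglik = ll,
               converged = TRUE, iterations = 1L, degenerate = FALSE))
  }
  if (C == 0)
    stop("cannot fit the ZIP model to a table with no drug cases (C = 0)")

  nz <- n[z]
  pos <- which(cases > 0)
  inG <- logical(I); if (!null_model) inG[g] <- TRUE
  # per-side constants over positive-count leaves
  kconst <- sum(cases[pos] * log(n[pos]) - lfactorial(cases[pos]))
  p <- 0.5 * length(z) / I
  lamG <- lamR <- lam0 <- C / N
  trace <- numeric(0)
  llprev <- -Inf
  converged <- FALSE
  it <- 0L
  dz <- numeric(length(z))
  repeat {
    it <- it + 1L
    lamz <- if (null_model) rep(lam0, length(z)) else
      ifelse(inG[z], lamG, lamR)
    dz <- p / (p + (1 - p) * exp(-nz * lamz))          # E-step
    # M-step (posteriors in place of known indicators)
    p <- sum(dz) / I
    wG <- wR <- wN <- NA_real_
    if (null_model) {
      wN <- N - sum(nz * dz)
      lam0 <- if (wN > 1e-12) C / wN else 0
    } else {
      wG <- sum(n[g]) - sum(nz[inG[z]] * dz[inG[z]])
      wR <- (N - sum(n[g])) - sum(nz[!inG[z]] * dz[!inG[z]])
      lamG <- if (wG > 1e-12) sum(cases[g]) / wG else 0
      lamR <- if (wR > 1e-12) (C - sum(cases[g])) / wR else 0
    }
    # observed-data log-likelihood at the updated parameters
    lamz <- if (null_model) rep(lam0, length(z)) else
      ifelse(inG[z], lamG, lamR)
    lampos <- if (null_model) rep(lam0, length(pos)) else
      ifelse(inG[pos], lamG, lamR)
    ll <- length(pos) * log1p(-p) + kconst +
      sum(.xlogy(cases[pos], lampos)) - sum(n[pos] * lampos) +
      sum(log(p + (1 - p) * exp(-nz * lamz)))
    trace <- c(trace, ll)
    if (is.finite(llprev) &&
        abs(ll - llprev) < config$tol * (abs(llprev) + 1)) {
      converged <- TRUE
      break
    }
    if (it >= config$maxIter) break
    llprev <- ll
  }
  # report the posterior at the final parameter values
  lamz <- if (null_model) rep(lam0, length(z)) else ifelse(inG[z], lamG, lamR)
  dz <- p / (p + (1 - p) * exp(-nz * lamz))
  delta <- numeric(I)
  delta[z] <- dz
  degenerate <- if (null_model) wN <= 1e-12 else (wG <= 1e-12 || wR <= 1e-12)
  new("ZipFit", p = p,
      lambda0 = if (null_model) lam0 else NA_real_,
      lambdaG = if (null_model) NA_real_ else lamG,
      lambdaR = if (null_model) NA_real_ else lamR,
      delta = delta, loglik = trace, converged = converged,
      iterations = it, degenerate = isTRUE(degenerate))
}

setMethod("show", "ZipFit", function(object) {
  kind <- if (is.na(object@lambda0)) "alternative" else "null"
  cat(sprintf("ZipFit (%s model): p = %.4f, %s, %d iteration(s), %s\n",
              kind, object@p,
              if (kind == "null")
                sprintf("lambda0 = %.6g", object@lambda0)
              else
                sprintf("lambdaG = %.6g, lambdaR = %.6g",
                        object@lambdaG, object@lambdaR),
              object@iterations,
              if (object@converged) "converged" else "NOT converged"))
})

#' ZIP likelihood ratio for one cut with given structural-zero weights
#'
#' The likelihood ratio for cut G under the ZIP model with a shared set of
#' structural-zero weights `d` (known 0/1 indicators or EM posteriors):
#' writing `wG = sum_G n_i (1-d_i)` and `wR` for the complement, and noting
#' that `c_i (1-d_i) = c_i` because weights are positive only on zero
#' counts, the ratio is
#' `(cG/wG)^cG (cR/wR)^cR / (C/(wG+wR))^C` when the weighted inside rate
#' exceeds the weighted outside rate, and 1 otherwise. Computed in log
#' space.
#'
#' @inheritParams mleKnownDeltaAlt
#' @param log return the log likelihood ratio instead of the ratio.
#' @return likelihood ratio (>= 1), or its log (>= 0). Degenerate
#'   zero-weight sides give 1 (log 0) with attribute `degenerate = TRUE`.
#' @export
zipLR <- function(counts, d, cut, log = FALSE) {
  stopifnot(is(counts, "AeCounts"))
  .checkDelta(counts, d)
  g <- .cutIndices(cut, length(counts@cases))
  w <- counts@n * (1 - d)
  cG <- sum(counts@cases[g])
  cR <- sum(counts@cases) - cG
  wG <- sum(w[g])
  wR <- sum(w) - wG
  degenerate <- wG <= 0 || wR <= 0
  stat <- if (degenerate) 0 else .logLRcore(cG, wG, cR, wR)
  out <- if (log) stat else exp(stat)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

# Vectorized alternative-model EM across all cuts at once.
# Rows index cuts, columns index the zero-count leaves; each EM iteration is
# a handful of dense matrix operations. Returns final parameters, posterior
# matrix and per-cut convergence.
.emAllCuts <- function(cases, n, M, config) {
  I <- length(cases)
  C <- sum(cases)
  N <- sum(n)
  K <- nrow(M)
  z <- which(cases == 0)
  nz <- n[z]
  Mz <- M[, z, drop = FALSE] * 1          # K x Z numeric
  cG <- as.vector(M %*% cases)
  nG <- as.vector(M %*% n)
  cR <- C - cG
  pos <- which(cases > 0)
  kpos <- cases[pos] * log(n[pos]) - lfactorial(cases[pos])
  Mp <- M[, pos, drop = FALSE] * 1
  KG <- as.vector(Mp %*% kpos);      KR <- sum(kpos) - KG
  nposG <- as.vector(Mp %*% n[pos]); nposR <- sum(n[pos]) - nposG
  mpos <- length(pos)

  p <- rep(0.5 * length(z) / I, K)
  lamG <- rep(C / N, K)
  lamR <- rep(C / N, K)
  llprev <- rep(-Inf, K)
  converged <- rep(FALSE, K)
  it <- 0L
  repeat {
    it <- it + 1L
    Lam <- Mz * lamG + (1 - Mz) * lamR
    Ez <- exp(-sweep(Lam, 2L, nz, "*"))
    D <- p / (p + (1 - p) * Ez)                        # E-step
    W <- sweep(D, 2L, nz, "*")                         # M-step
    sG <- rowSums(W * Mz)
    enG <- nG - sG
    enR <- (N - nG) - (rowSums(W) - sG)
    lamGnew <- ifelse(enG > 1e-12, cG / enG, 0)
    lamRnew <- ifelse(enR > 1e-12, cR / enR, 0)
    pnew <- rowSums(D) / I
    # cuts already converged keep their final parameter values, so each
    # cut's trajectory matches the per-cut reference fit exactly
    upd <- !converged
    lamG[upd] <- lamGnew[upd]
    lamR[upd] <- lamRnew[upd]
    p[upd] <- pnew[upd]
    Lam <- Mz * lamG + (1 - Mz) * lamR
    Ez <- exp(-sweep(Lam, 2L, nz, "*"))
    ll <- mpos * log1p(-p) +
      .xlogy(cG, lamG) + KG - lamG * nposG +
      .xlogy(cR, lamR) + KR - lamR * nposR +
      rowSums(log(p + (1 - p) * Ez))
    converged <- converged | (is.finite(llprev) &
      abs(ll - llprev) < config$tol * (abs(llprev) + 1))
    if (all(converged) || it >= config$maxIter) break
    llprev <- ll
  }
  D <- p / (p + (1 - p) * Ez)    # posterior at the final parameters
  list(p = p, lamG = lamG, lamR = lamR, D = D, zeroIdx = z,
       converged = converged, iterations = it)
}

#' Zero-inflated Poisson tree-based scan
#'
#' For every candidate cut, fits the alternative ZIP model by EM (posterior
#' structural-zero weights shared between the numerator and denominator of
#' the likelihood ratio), evaluates the ZIP likelihood ratio, and takes the
#' maximum as the test statistic. On tables with no zero counts the result
#' is identical to [scanPoisson()] (the zero-inflation component is
#' inactive).
#'
#' @param counts an [AeCounts].
#' @param cuts a [CutSet] on the same leaf set.
#' @param config an [emConfig()]; `deltaSource = "null"` switches all cuts
#'   to the weights of the single null-model fit.
#' @return a [ScanResult] with `method = "zip"`; per-cut columns include
#'   the EM estimates `p_hat`, `lambda_G`, `lambda_R`.
#' @export
scanZip <- function(counts, cuts, config = emConfig()) {
  stopifnot(is(counts, "AeCounts"), is(cuts, "CutSet"))
  if (!identical(counts@leafIds, cuts@leafIds))
    stop("counts and cuts are defined on different leaf sets")
  cases <- counts@cases
  n <- counts@n
  C <- sum(cases)
  N <- sum(n)
  M <- .membershipMatrix(cuts)
  cG <- as.vector(M %*% cases)
  nG <- as.vector(M %*% n)
  flags <- character()

  if (C == 0) {
    warning("count table has no drug cases (C = 0); all statistics are 0")
    perCut <- data.frame(cut_id = cuts@cutIds, level = cuts@level,
                         c_G = cG, n_G = nG, stat = 0,
                         rr_est = NA_real_, p_hat = NA_real_,
                         lambda_G = NA_real_, lambda_R = NA_real_,
                         stringsAsFactors = FALSE)
    return(new("ScanResult", perCut = perCut, logT = 0,
               mostLikelyCut = cuts@cutIds[1L], method = "zip",
               flags = "no-cases"))
  }

  if (all(cases > 0)) {
    stat <- poissonLogLR(cG, nG, C, N)
    pHat <- rep(0, length(stat))
    lamG <- cG / nG
    lamR <- (C - cG) / (N - nG)
  } else if (config$deltaSource == "null") {
    fit <- emEstimate(counts, cut = NULL, config = config)
    d <- fit@delta
    if (config$hardZeros) d <- as.numeric(d >= config$hardThreshold)
    w <- n * (1 - d)
    wG <- as.vector(M %*% w)
    wR <- sum(w) - wG
    stat <- ifelse(wG > 0 & wR > 0,
                   .logLRcore(cG, wG, C - cG, wR), 0)
    pHat <- rep(fit@p, length(stat))
    lamG <- ifelse(wG > 0, cG / wG, 0)
    lamR <- ifelse(wR > 0, (C - cG) / wR, 0)
    if (!fit@converged) flags <- c(flags, "em-not-converged")
  } else {
    em <- .emAllCuts(cases, n, M, config)
    D <- em$D
    if (config$hardZeros) D <- (D >= config$hardThreshold) * 1
    nz <- n[em$zeroIdx]
    Mz <- M[, em$zeroIdx, drop = FALSE] * 1
    W <- sweep(D, 2L, nz, "*")
    sG <- rowSums(W * Mz)
    wG <- nG - sG
    wR <- (N - nG) - (rowSums(W) - sG)
    stat <- ifelse(wG > 0 & wR > 0,
                   .logLRcore(cG, wG, C - cG, wR), 0)
    pHat <- em$p
    lamG <- em$lamG
    lamR <- em$lamR
    if (!all(em$converged)) flags <- c(flags, "em-not-converged")
  }

  stat <- unname(stat)
  perCut <- data.frame(cut_id = cuts@cutIds, level = cuts@level,
                       c_G = cG, n_G = nG, stat = stat,
                       rr_est = .relativeRisk(cG, nG, C, N),
                       p_hat = unname(pHat), lambda_G = unname(lamG),
                       lambda_R = unname(lamR), stringsAsFactors = FALSE)
  best <- which.max(stat)
  new("ScanResult", perCut = perCut, logT = stat[best],
      mostLikelyCut = cuts@cutIds[best], method = "zip", flags = flags)
}
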