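#' @import methods
NULL

#' Hierarchical adverse-event classification tree
#'
#' An `AeTree` holds the leaf-level adverse-event (AE) terms of a
#' hierarchical coding dictionary (WHO-ART or MedDRA style) together with
#' the path of internal node identifiers leading from the root to each leaf.
#' Leaves are stored in the order of first appearance in the input; that
#' order fixes the ordering of every count vector and scan report built on
#' the tree.
#'
#' @slot leafIds character vector of unique leaf identifiers (e.g. PT codes).
#' @slot paths list of character vectors, one per leaf, giving the ancestor
#'   node identifiers from the root down (e.g. the SOC code for a two-level
#'   SOC/PT tree). Paths are non-empty and consistent: a node identifier
#'   always appears under the same parent.
#' @slot nodeIds character vector of the distinct internal node identifiers
#'   in order of first appearance.
#' @slot labels optional human-readable leaf labels (empty strings when
#'   absent).
#'
#' @seealso [parseTree()], [enumerateCuts()]
#' @export
setClass("AeTree",
  slots = c(
    leafIds = "character",
    paths   = "list",
    nodeIds = "character",
    labels  = "character"
  )
)

setValidity("AeTree", function(object) {
  msg <- character()
  if (length(object@leafIds) < 2L)
    msg <- c(msg, "a tree needs at least 2 leaves")
  if (anyDuplicated(object@leafIds))
    msg <- c(msg, sprintf("duplicate leaf_id: %s",
                          object@leafIds[duplicated(object@leafIds)][1L]))
  if (length(object@paths) != length(object@leafIds))
    msg <- c(msg, "paths and leafIds lengths differ")
  if (any(lengths(object@paths) == 0L))
    msg <- c(msg, sprintf("empty path for leaf_id '%s'",
                          object@leafIds[lengths(object@paths) == 0L][1L]))
  if (length(object@labels) != length(object@leafIds))
    msg <- c(msg, "labels and leafIds lengths differ")
  # node consistency: a node id must always sit under one parent prefix
  seen <- list()
  for (i in seq_along(object@paths)) {
    p <- object@paths[[i]]
    for (d in seq_along(p)) {
      parent <- if (d == 1L) "<root>" else p[[d - 1L]]
      prev <- seen[[p[[d]]]]
      if (is.null(prev)) {
        seen[[p[[d]]]] <- parent
      } else if (!identical(prev, parent)) {
        msg <- c(msg, sprintf(
          "inconsistent paths: node '%s' appears under both '%s' and '%s' (leaf '%s')",
          p[[d]], prev, parent, object@leafIds[[i]]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Candidate cuts of a tree
#'
#' A `CutSet` enumerates the candidate branches ("cuts") of an [AeTree]:
#' one cut per leaf plus one per internal node whose descendant leaf set is
#' a strict, non-singleton subset of all leaves. Each cut is the hypothesis
#' that the drug-attributable AE rate inside its member leaves exceeds the
#' rate in the remaining leaves.
#'
#' @slot cutIds identifier of each cut (the leaf or node id).
#' @slot level `"leaf"` or `"node"` for each cut.
#' @slot members list of integer vectors: member leaf indices (into the
#'   tree's leaf order) of each cut.
#' @slot leafIds leaf identifiers of the originating tree, for alignment
#'   checks against count tables.
#'
#' @seealso [enumerateCuts()], [aggregateCounts()]
#' @export
setClass("CutSet",
  slots = c(
    cutIds  = "character",
    level   = "character",
    members = "list",
    leafIds = "character"
  )
)

setValidity("CutSet", function(object) {
  msg <- character()
  I <- length(object@leafIds)
  if (length(object@cutIds) != length(object@members) ||
      length(object@cutIds) != length(object@level))
    msg <- c(msg, "cutIds, level and members lengths differ")
  if (anyDuplicated(object@cutIds))
    msg <- c(msg, "duplicate cut ids")
  if (!all(object@level %in% c("leaf", "node")))
    msg <- c(msg, "level must be 'leaf' or 'node'")
  for (m in object@members) {
    if (length(m) == 0L || length(m) >= I || any(m < 1L | m > I))
      msg <- c(msg, "each cut must be a non-empty strict subset of the leaves")
  }
  if (length(msg)) head(msg, 3L) else TRUE
})

#' Per-leaf adverse-event counts for one drug
#'
#' Count table aligned with an [AeTree]: for leaf i, `n[i]` is the total
#' number of patients reporting that AE for any drug (the marginal total),
#' and `cases[i]` is the number reporting it for the drug under study.
#' Derived totals are `N = sum(n)` and `C = sum(cases)`.
#'
#' @slot leafIds leaf identifiers, in tree order.
#' @slot n numeric vector of marginal AE totals (symbolically n_i).
#' @slot cases numeric vector of drug-specific AE counts (c_i).
#' @export
setClass("AeCounts",
  slots = c(
    leafIds = "character",
    n       = "numeric",
    cases   = "numeric"
  )
)

setValidity("AeCounts", function(object) {
  msg <- character()
  I <- length(object@leafIds)
  if (length(object@n) != I || length(object@cases) != I)
    msg <- c(msg, "n and cases must have one entry per leaf")
  if (anyDuplicated(object@leafIds))
    msg <- c(msg, "duplicate leaf ids")
  if (any(object@n < 0) || any(object@cases < 0))
    msg <- c(msg, "counts must be non-negative")
  if (I > 0 && sum(object@n) <= 0)
    msg <- c(msg, "total marginal count N must be positive")
  if (any(object@n != floor(object@n)) || any(object@cases != floor(object@cases)))
    msg <- c(msg, "counts must be integers")
  if (length(msg)) msg else TRUE
})

#' Result of a tree-based scan
#'
#' Per-cut statistics from [scanPoisson()] or [scanZip()], the maximum
#' log-likelihood-ratio statistic, and the most likely cut (the argmax,
#' with ties broken by enumeration order).
#'
#' @slot perCut data.frame with one row per cut: `cut_id`, `level`, `c_G`,
#'   `n_G`, `stat` (log likelihood ratio, >= 0), `rr_est` (the MLE of
#'   lambda_G / lambda_R), plus method-specific columns for the ZIP scan
#'   (`p_hat`, `lambda_G`, `lambda_R`).
#' @slot logT maximum statistic on the log scale.
#' @slot mostLikelyCut cut id attaining the maximum.
#' @slot method `"poisson"` or `"zip"`.
#' @slot flags character vector of warning states (e.g. `"no-cases"`).
#' @export
setClass("ScanResult",
  slots = c(
    perCut        = "data.frame",
    logT          = "numeric",
    mostLikelyCut = "character",
    method        = "character",
    flags         = "character"
  )
)

#' Zero-inflated Poisson model fit
#'
#' Result of [emEstimate()]: EM maximum-likelihood estimates of the
#' structural-zero probability and the Poisson rate(s), the per-leaf
#' posterior structural-zero weights, and the observed-data log-likelihood
#' trace (non-decreasing by EM monotonicity).
#'
#' @slot p structural-zero probability estimate.
#' @slot lambda0 null rate estimate (NA for an alternative-model fit).
#' @slot lambdaG,lambdaR inside/outside-cut rate estimates (NA for a null fit).
#' @slot delta per-leaf posterior structural-zero weights in \[0, 1\];
#'   exactly 0 wherever the observed count is positive.
#' @slot loglik observed-data log-likelihood trace over EM iterations.
#' @slot converged logical.
#' @slot iterations number of EM iterations performed.
#' @slot degenerate TRUE when a side of the cut carried no effective
#'   Poisson weight (its rate is reported as 0).
#' @export
setClass("ZipFit",
  slots = c(
    p          = "numeric",
    lambda0    = "numeric",
    lambdaG    = "numeric",
    lambdaR    = "numeric",
    delta      = "numeric",
    loglik     = "numeric",
    converged  = "logical",
    iterations = "integer",
    degenerate = "logical"
  )
)

#' Monte Carlo test of the maximum scan statistic
#'
#' Holds the observed maximum statistic, the null replicate maxima, and the
#' rank-based p-value `rank / (1 + B)` where `rank` is the position of the
#' observed statistic among the observed plus null values in descending
#' order (ties counted against the observed).
#'
#' @slot observed observed log maximum statistic.
#' @slot nullT vector of B null log maximum statistics.
#' @slot rank integer rank of the observed value.
#' @slot pValue rank / (1 + B).
#' @slot B number of Monte Carlo replicates.
#' @slot method `"poisson"` or `"zip"`.
#' @export
setClass("MonteCarloResult",
  slots = c(
    observed = "numeric",
    nullT    = "numeric",
    rank     = "integer",
    pValue   = "numeric",
    B        = "integer",
    method   = "character"
  )
)

setValidity("MonteCarloResult", function(object) {
  msg <- character()
  if (object@B < 1L) msg <- c(msg, "B must be >= 1")
  if (object@rank < 1L || object@rank > object@B + 1L)
    msg <- c(msg, "rank out of range")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value out of (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Signal detection report
#'
#' Per-cut report in the layout of a drug-safety signal table: marginal
#' total, observed and expected counts, O/E ratio and Monte Carlo p-value
#' (each cut's statistic referred to the null distribution of the maximum,
#' giving family-wise control), with cuts at p < alpha flagged as signals.
#'
#' @slot table data.frame with columns `cut_id`, `level`, `label`,
#'   `marginal_total`, `obs`, `exp`, `obs_over_exp`, `p_value`,
#'   `signal_flag`.
#' @slot alpha significance level used for flagging.
#' @slot method `"poisson"` or `"zip"`.
#' @slot B Monte Carlo replicates behind the p-values.
#' @export
setClass("SignalReport",
  slots = c(
    table  = "data.frame",
    alpha  = "numeric",
    method = "character",
    B      = "integer"
  )
)
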