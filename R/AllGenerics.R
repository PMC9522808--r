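#' Accessors for tree, count and scan objects
#'
#' Small accessor generics in the Bioconductor style: `leafIds()` and
#' `nodeIds()` return identifiers, `nLeaves()` the number of leaves,
#' `marginalTotals()` / `caseCounts()` the per-leaf count vectors,
#' `totalPatients()` / `totalCases()` the derived totals N and C,
#' `testStatistic()` the (log) maximum statistic, `mostLikelyCut()` the
#' argmax cut id, `perCutStats()` the per-cut table, `pValue()` the Monte
#' Carlo p-value, `nullStatistics()` the null replicate maxima, and
#' `signalTable()` the report rows.
#'
#' @param x an object of the appropriate class.
#' @param ... unused.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @rdname accessors
#' @export
setGeneric("nCuts", function(x) standardGeneric("nCuts"))

#' @rdname accessors
#' @export
setGeneric("cutMembers", function(x) standardGeneric("cutMembers"))

#' @rdname accessors
#' @export
setGeneric("marginalTotals", function(x) standardGeneric("marginalTotals"))

#' @rdname accessors
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' @rdname accessors
#' @export
setGeneric("totalPatients", function(x) standardGeneric("totalPatients"))

#' @rdname accessors
#' @export
setGeneric("totalCases", function(x) standardGeneric("totalCases"))

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(x, ...) standardGeneric("testStatistic"))

#' @rdname accessors
#' @export
setGeneric("mostLikelyCut", function(x) standardGeneric("mostLikelyCut"))

#' @rdname accessors
#' @export
setGeneric("perCutStats", function(x) standardGeneric("perCutStats"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nullStatistics", function(x) standardGeneric("nullStatistics"))

#' @rdname accessors
#' @export
setGeneric("signalTable", function(x) standardGeneric("signalTable"))
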