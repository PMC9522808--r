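#' Construct a per-leaf count table
#'
#' @param leafIds character vector of leaf identifiers (tree order).
#' @param n per-leaf marginal AE totals across all drugs.
#' @param cases per-leaf AE counts for the drug under study.
#' @return an [AeCounts].
#' @examples
#' ct <- AeCounts(c("a", "b", "c"), n = c(10, 20, 30), cases = c(1, 0, 4))
#' totalCases(ct)     # 5
#' totalPatients(ct)  # 60
#' @export
AeCounts <- function(leafIds, n, cases) {
  obj <- new("AeCounts", leafIds = as.character(leafIds),
             n = as.numeric(n), cases = as.numeric(cases))
  validObject(obj)
  # report-derived tables always satisfy this; simulated draws from a
  # strongly tilted multinomial may construct the object directly instead
  if (any(obj@cases > obj@n))
    stop(sprintf("cases exceed marginal total at leaf '%s'",
                 obj@leafIds[obj@cases > obj@n][1L]))
  obj
}

#' @rdname accessors
#' @export
setMethod("leafIds", "AeCounts", function(x) x@leafIds)

#' @rdname accessors
#' @export
setMethod("nLeaves", "AeCounts", function(x) length(x@leafIds))

#' @rdname accessors
#' @export
setMethod("marginalTotals", "AeCounts", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("caseCounts", "AeCounts", function(x) x@cases)

#' @rdname accessors
#' @export
setMethod("totalPatients", "AeCounts", function(x) sum(x@n))

#' @rdname accessors
#' @export
setMethod("totalCases", "AeCounts", function(x) sum(x@cases))

setMethod("show", "AeCounts", function(object) {
  cat(sprintf("AeCounts: %d leaves, N = %d patients, C = %d drug cases, %d zero-count leaves\n",
              length(object@leafIds), as.integer(sum(object@n)),
              as.integer(sum(object@cases)), sum(object@cases == 0)))
})

#' Read / write a count table
#'
#' Plain delimited text with columns `leaf_id`, `n`, `c` (TSV by default);
#' `#` starts a comment line. The leaf order of the file is kept.
#'
#' @param file path.
#' @param sep field separator.
#' @return `readCounts()` returns an [AeCounts]; `writeCounts()` returns
#'   `file` invisibly.
#' @export
readCounts <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric"))
  need <- c("leaf_id", "n", "c")
  if (!all(need %in% names(df)))
    stop("count file needs columns 'leaf_id', 'n', 'c'")
  AeCounts(df$leaf_id, df$n, df$c)
}

#' @param counts an [AeCounts] to write.
#' @rdname readCounts
#' @export
writeCounts <- function(counts, file, sep = "\t") {
  stopifnot(is(counts, "AeCounts"))
  df <- data.frame(leaf_id = counts@leafIds, n = counts@n, c = counts@cases)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
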