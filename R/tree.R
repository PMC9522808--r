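#' Build an adverse-event tree from leaf records
#'
#' Constructs an [AeTree] from one record per leaf: the leaf identifier and
#' its ancestor path. For a two-level SOC/PT dictionary the path is just the
#' SOC code; deeper hierarchies join ancestor node ids with `delim`.
#'
#' @param records data.frame with columns `leaf_id` and `path` (and an
#'   optional `label`), or a named character vector of paths whose names are
#'   the leaf ids.
#' @param delim delimiter separating node ids inside a path string
#'   (default `"."`).
#' @return an [AeTree]; leaves keep the input order.
#' @examples
#' tr <- parseTree(data.frame(leaf_id = c("0363", "0410.0137"),
#'                            path    = c("0800", "0410")))
#' nLeaves(tr)   # 2
#' nodeIds(tr)   # "0800" "0410"
#' @export
parseTree <- function(records, delim = ".") {
  if (is.character(records)) {
    records <- data.frame(leaf_id = names(records), path = unname(records),
                          stringsAsFactors = FALSE)
  }
  records <- as.data.frame(records)
  need <- c("leaf_id", "path")
  if (!all(need %in% names(records)))
    stop("tree records need columns 'leaf_id' and 'path'")
  leaf_id <- as.character(records$leaf_id)
  path <- as.character(records$path)
  if (length(leaf_id) < 2L)
    stop("a tree needs at least 2 leaves")
  bad <- which(is.na(path) | !nzchar(path))
  if (length(bad))
    stop(sprintf("empty path for leaf_id '%s'", leaf_id[bad[1L]]))
  dup <- which(duplicated(leaf_id))
  if (length(dup))
    stop(sprintf("duplicate leaf_id '%s'", leaf_id[dup[1L]]))
  paths <- strsplit(path, delim, fixed = TRUE)
  labels <- if ("label" %in% names(records))
    as.character(records$label) else rep("", length(leaf_id))
  labels[is.na(labels)] <- ""
  nodeIds <- unique(unlist(paths, use.names = FALSE))
  new("AeTree", leafIds = leaf_id, paths = paths, nodeIds = nodeIds,
      labels = labels)
}

#' Read a tree definition file
#'
#' Reads a delimited text file (TSV by default) with columns `leaf_id`,
#' `path` and optional `label`; lines starting with `#` are comments.
#'
#' @param file path to the file.
#' @param sep field separator (default tab).
#' @param pathDelim delimiter inside path strings.
#' @return an [AeTree].
#' @export
readTree <- function(file, sep = "\t", pathDelim = ".") {
  df <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  parseTree(df, delim = pathDelim)
}

#' @rdname accessors
#' @export
setMethod("leafIds", "AeTree", function(x) x@leafIds)

#' @rdname accessors
#' @export
setMethod("nodeIds", "AeTree", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("nLeaves", "AeTree", function(x) length(x@leafIds))

setMethod("show", "AeTree", function(object) {
  cat(sprintf("AeTree: %d leaves, %d internal nodes, depth %d\n",
              length(object@leafIds), length(object@nodeIds),
              max(lengths(object@paths))))
})

#' Leaf labels of a tree
#'
#' @param x an [AeTree].
#' @return character vector of leaf labels ("" where none was given).
#' @export
leafLabels <- function(x) {
  stopifnot(is(x, "AeTree"))
  x@labels
}

#' Enumerate the candidate cuts of a tree
#'
#' Produces one cut per leaf (in tree order) and one per internal node (in
#' first-appearance order) whose descendant leaf set is a strict subset of
#' all leaves. A node covering the whole tree yields no cut: its complement
#' would be empty and the outside rate undefined. Node cuts whose member set
#' duplicates an earlier cut (e.g. a node with a single leaf child) are
#' dropped, keeping the most specific (leaf-level) cut.
#'
#' @param tree an [AeTree].
#' @return a [CutSet].
#' @examples
#' tr <- parseTree(data.frame(leaf_id = letters[1:4],
#'                            path = c("n1", "n1", "n2", "n2")))
#' nCuts(enumerateCuts(tr))  # 4 leaf cuts + 2 node cuts
#' @export
enumerateCuts <- function(tree) {
  stopifnot(is(tree, "AeTree"))
  validObject(tree)
  I <- length(tree@leafIds)
  cutIds <- tree@leafIds
  level <- rep("leaf", I)
  members <- as.list(seq_len(I))
  # node cuts in first-appearance order of the node ids
  seen <- character()
  for (nd in tree@nodeIds) {
    idx <- which(vapply(tree@paths, function(p) nd %in% p, logical(1)))
    if (length(idx) <= 1L) next            # duplicate of the leaf cut
    if (length(idx) >= I) next             # whole tree: complement empty
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next                # identical member set (chain node)
    seen <- c(seen, key)
    cutIds <- c(cutIds, nd)
    level <- c(level, "node")
    members <- c(members, list(idx))
  }
  new("CutSet", cutIds = cutIds, level = level, members = members,
      leafIds = tree@leafIds)
}

#' @rdname accessors
#' @export
setMethod("nCuts", "CutSet", function(x) length(x@cutIds))

#' @rdname accessors
#' @export
setMethod("cutMembers", "CutSet", function(x) {
  stats::setNames(x@members, x@cutIds)
})

#' @rdname accessors
#' @export
setMethod("leafIds", "CutSet", function(x) x@leafIds)

#' Cut identifiers
#' @param x a [CutSet] or [ScanResult].
#' @return character vector of cut ids.
#' @export
cutIds <- function(x) {
  if (is(x, "CutSet")) x@cutIds
  else if (is(x, "ScanResult")) x@perCut$cut_id
  else stop("no cut ids for this object")
}

#' Subset a CutSet
#' @param x a [CutSet].
#' @param i index (numeric, logical, or cut id).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CutSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@cutIds)
  new("CutSet", cutIds = x@cutIds[i], level = x@level[i],
      members = x@members[i], leafIds = x@leafIds)
})

setMethod("show", "CutSet", function(object) {
  cat(sprintf("CutSet: %d cuts (%d leaf-level, %d node-level) over %d leaves\n",
              length(object@cutIds), sum(object@level == "leaf"),
              sum(object@level == "node"), length(object@leafIds)))
})

# dense cuts x leaves membership matrix; the workhorse for vectorized scans
.membershipMatrix <- function(cuts) {
  I <- length(cuts@leafIds)
  K <- length(cuts@cutIds)
  M <- matrix(FALSE, nrow = K, ncol = I)
  for (k in seq_len(K)) M[k, cuts@members[[k]]] <- TRUE
  dimnames(M) <- list(cuts@cutIds, cuts@leafIds)
  M
}

#' Aggregate counts over cuts
#'
#' For each cut G, sums the drug-specific counts `c_G = sum(cases[G])` and
#' the marginal totals `n_G = sum(n[G])` over its member leaves.
#'
#' @param counts an [AeCounts] on the same leaf set as `cuts`.
#' @param cuts a [CutSet] (possibly subset to a single cut).
#' @return data.frame with columns `cut_id`, `level`, `c_G`, `n_G`.
#' @export
aggregateCounts <- function(counts, cuts) {
  stopifnot(is(counts, "AeCounts"), is(cuts, "CutSet"))
  if (!identical(counts@leafIds, cuts@leafIds))
    stop("counts and cuts are defined on different leaf sets")
  cG <- vapply(cuts@members, function(m) sum(counts@cases[m]), numeric(1))
  nG <- vapply(cuts@members, function(m) sum(counts@n[m]), numeric(1))
  data.frame(cut_id = cuts@cutIds, level = cuts@level, c_G = cG, n_G = nG,
             stringsAsFactors = FALSE)
}
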