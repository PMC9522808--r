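#' Causality grades of spontaneous reports
#'
#' The six WHO-UMC style causality grades, strongest first. Grade
#' comparisons (e.g. "possible or above") use this ordering.
#'
#' @return character vector of the grades in decreasing strength.
#' @export
causalityGrades <- function() {
  c("certain", "probable", "possible", "unlikely", "conditional",
    "unassessable")
}

#' Read drug-AE pair records
#'
#' Reads a delimited file of spontaneous-report drug-AE pairs with header
#' columns `report_id`, `drug_id`, `ae_leaf_id` and `causality`. Causality
#' strings are matched case-insensitively against [causalityGrades()];
#' unknown grades are rejected.
#'
#' @param file path to the file.
#' @param sep field separator (default tab; use "," for CSV).
#' @return data.frame of pair records in file order.
#' @export
readPairs <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                          quote = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("report_id", "drug_id", "ae_leaf_id", "causality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair file is missing column(s): ", paste(miss, collapse = ", "))
  grade <- tolower(trimws(df$causality))
  bad <- !grade %in% causalityGrades()
  if (any(bad))
    stop(sprintf("unknown causality grade '%s' (row %d)",
                 df$causality[which(bad)[1L]], which(bad)[1L]))
  df$causality <- grade
  df[need]
}

#' Clean pair records: deduplicate and filter by causality
#'
#' Applies the standard cleansing rules for spontaneous-report data: within
#' each (report, drug, AE) triple only the first record in file order is
#' kept (repeat administrations of the same drug generate repeat reports of
#' the same pair), and records rated below `minGrade` are dropped. The
#' operation is idempotent.
#'
#' @param records data.frame from [readPairs()].
#' @param minGrade weakest causality grade retained (default `"possible"`).
#' @param dedupeKey `"order"` (default: first record in file order wins) or
#'   `"report_id"` (record with the lexicographically smallest report id
#'   wins).
#' @return the cleaned data.frame.
#' @export
cleanPairs <- function(records, minGrade = "possible",
                       dedupeKey = c("order", "report_id")) {
  dedupeKey <- match.arg(dedupeKey)
  minGrade <- match.arg(tolower(minGrade), causalityGrades())
  grades <- causalityGrades()
  keep <- match(records$causality, grades) <= match(minGrade, grades)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  if (dedupeKey == "report_id")
    records <- records[order(records$report_id), , drop = FALSE]
  key <- paste(records$report_id, records$drug_id, records$ae_leaf_id,
               sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Aggregate pair records into a per-leaf count table
#'
#' For each tree leaf, `n_i` counts the distinct reports mentioning that AE
#' for any drug (a report naming the AE with several drugs is counted
#' once), and `c_i` counts the distinct reports pairing the AE with
#' `targetDrug`. Records whose AE id does not resolve to a tree leaf are
#' excluded with a summary message.
#'
#' @param records cleaned pair records ([cleanPairs()]).
#' @param tree an [AeTree]; its leaf order fixes the count order.
#' @param targetDrug drug id whose AE profile is scanned.
#' @return an [AeCounts].
#' @export
pairsToCounts <- function(records, tree, targetDrug) {
  stopifnot(is(tree, "AeTree"))
  known <- records$ae_leaf_id %in% tree@leafIds
  if (any(!known)) {
    miss <- unique(records$ae_leaf_id[!known])
    message(sprintf("excluded %d record(s) with %d AE id(s) not in the tree: %s%s",
                    sum(!known), length(miss),
                    paste(utils::head(miss, 5L), collapse = ", "),
                    if (length(miss) > 5L) ", ..." else ""))
    records <- records[known, , drop = FALSE]
  }
  if (!targetDrug %in% records$drug_id) {
    tab <- sort(table(records$drug_id), decreasing = TRUE)
    stop(sprintf("drug '%s' not present; available drugs (records): %s",
                 targetDrug,
                 paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  leafFac <- factor(records$ae_leaf_id, levels = tree@leafIds)
  # distinct reports per leaf, all drugs
  allKey <- !duplicated(paste(records$report_id, records$ae_leaf_id,
                              sep = "\r"))
  n <- as.vector(table(leafFac[allKey]))
  # distinct (report, leaf) among target-drug records
  tgt <- records[records$drug_id == targetDrug, , drop = FALSE]
  tgt <- tgt[!duplicated(paste(tgt$report_id, tgt$ae_leaf_id, sep = "\r")),
             , drop = FALSE]
  cases <- as.vector(table(factor(tgt$ae_leaf_id, levels = tree@leafIds)))
  AeCounts(tree@leafIds, n, cases)
}
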