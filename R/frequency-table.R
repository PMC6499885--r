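#' Construct a FrequencyTable
#'
#' @param records data.frame with columns `drug`, `adr_term`, `count`.
#'   Duplicate (drug, term) rows are aggregated by summing counts.
#' @param termGroups named character vector mapping adverse-event terms to
#'   group labels.  Terms absent from the map belong to no group (they still
#'   contribute to the "all other ADR" cell).
#' @param drugClass drugs forming the within-class comparator; defaults to
#'   all drugs present.
#' @return A \linkS4class{FrequencyTable}.
#' @examples
#' tab <- FrequencyTable(
#'   data.frame(drug = c("a", "a", "b", "b"),
#'              adr_term = c("t1", "t2", "t1", "t2"),
#'              count = c(5, 95, 50, 950)),
#'   termGroups = c(t1 = "glomerular"))
#' rorTable(computeRor(buildContingency(tab, "a", "glomerular")))
#' @export
FrequencyTable <- function(records, termGroups = character(),
                           drugClass = unique(records$drug)) {
  records$drug <- as.character(records$drug)
  records$adr_term <- as.character(records$adr_term)
  records$count <- as.numeric(records$count)
  agg <- stats::aggregate(count ~ drug + adr_term, data = records, FUN = sum)
  agg <- agg[order(agg$drug, agg$adr_term), , drop = FALSE]
  rownames(agg) <- NULL
  new("FrequencyTable", records = agg,
      termGroups = termGroups, drugClass = as.character(drugClass))
}

#' @rdname FrequencyTable
#' @param x a FrequencyTable.
#' @export
records <- function(x) x@records

#' @rdname FrequencyTable
#' @export
termGroups <- function(x) x@termGroups

#' @rdname FrequencyTable
#' @export
drugClass <- function(x) x@drugClass

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable:", length(unique(object@records$drug)), "drugs x",
      length(unique(object@records$adr_term)), "ADR terms;",
      sum(object@records$count), "reports\n")
  cat("  drug class:", length(object@drugClass), "drugs\n")
  grp <- table(object@termGroups)
  if (length(grp))
    cat("  term groups:",
        paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
})

#' Read / write frequency tables
#'
#' The on-disk format is a plain CSV with columns `drug,adr_term,count`, plus
#' an optional term-to-group map CSV with columns `adr_term,group`.
#'
#' @param file path to the frequency CSV.
#' @param groupsFile optional path to the term-group map CSV.
#' @param drugClass optional drug class; defaults to all drugs in the file.
#' @return `readFrequencyTable` returns a \linkS4class{FrequencyTable};
#'   `writeFrequencyTable` invisibly returns the file paths written.
#' @export
readFrequencyTable <- function(file, groupsFile = NULL, drugClass = NULL) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  tg <- character()
  if (!is.null(groupsFile)) {
    gm <- utils::read.csv(groupsFile, stringsAsFactors = FALSE)
    tg <- stats::setNames(as.character(gm$group), gm$adr_term)
  }
  if (is.null(drugClass)) drugClass <- unique(rec$drug)
  FrequencyTable(rec, termGroups = tg, drugClass = drugClass)
}

#' @rdname readFrequencyTable
#' @param x a FrequencyTable to write.
#' @export
writeFrequencyTable <- function(x, file, groupsFile = NULL) {
  utils::write.csv(records(x), file, row.names = FALSE, quote = FALSE)
  if (!is.null(groupsFile))
    utils::write.csv(
      data.frame(adr_term = names(termGroups(x)), group = termGroups(x)),
      groupsFile, row.names = FALSE, quote = FALSE)
  invisible(c(file, groupsFile))
}
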