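#' Construct a SpectralCountMatrix
#'
#' @param counts non-negative integer matrix, proteins in rows (rownames
#'   required), samples in columns.
#' @param condition character vector of `"control"`/`"treated"` labels, one
#'   per column, at least two of each.
#' @return A \linkS4class{SpectralCountMatrix}.
#' @export
SpectralCountMatrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
  new("SpectralCountMatrix", se)
}

#' @rdname SpectralCountMatrix
#' @param x a SpectralCountMatrix.
#' @export
spectralCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname SpectralCountMatrix
#' @export
condition <- function(x)
  as.character(SummarizedExperiment::colData(x)$condition)

setMethod("show", "SpectralCountMatrix", function(object) {
  cond <- table(condition(object))
  cat("SpectralCountMatrix:", nrow(object), "proteins x", ncol(object),
      "samples (", paste(sprintf("%s n=%d", names(cond), cond),
                         collapse = ", "), ")\n")
})

#' Read / write spectral-count matrices
#'
#' On disk: a TSV with protein identifiers in the first column and one count
#' column per sample, plus a conditions CSV (`sample,condition`).
#'
#' @param file counts TSV path.
#' @param conditionsFile conditions CSV path.
#' @export
readSpectralCounts <- function(file, conditionsFile) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  cond <- utils::read.csv(conditionsFile, stringsAsFactors = FALSE)
  SpectralCountMatrix(m, cond$condition[match(colnames(m), cond$sample)])
}

#' @rdname readSpectralCounts
#' @param x a SpectralCountMatrix.
#' @export
writeSpectralCounts <- function(x, file, conditionsFile = NULL) {
  m <- spectralCounts(x)
  utils::write.table(data.frame(protein = rownames(m), m, check.names = FALSE),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(conditionsFile))
    utils::write.csv(data.frame(sample = colnames(m), condition = condition(x)),
                     conditionsFile, row.names = FALSE, quote = FALSE)
  invisible(c(file, conditionsFile))
}
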