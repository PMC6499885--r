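#' Construct a KinomeMatrix
#'
#' @param residuals numeric matrix of percent-of-control residual kinase
#'   activities; kinases in rows (rownames required), drugs in columns.
#' @return A \linkS4class{KinomeMatrix}.
#' @export
KinomeMatrix <- function(residuals) {
  new("KinomeMatrix", residuals = as.matrix(residuals))
}

#' @rdname KinomeMatrix
#' @param x a KinomeMatrix.
#' @export
residualActivity <- function(x) x@residuals

#' @rdname KinomeMatrix
#' @export
kinases <- function(x) rownames(x@residuals)

#' @rdname KinomeMatrix
#' @export
panelDrugs <- function(x) colnames(x@residuals)

setMethod("show", "KinomeMatrix", function(object) {
  cat("KinomeMatrix:", nrow(object@residuals), "kinases x",
      ncol(object@residuals), "drugs; residual activity",
      sprintf("%.3g-%.3g%%\n", min(object@residuals), max(object@residuals)))
})

#' @rdname KinomeMatrix
#' @param file CSV path (kinase identifiers in the first column).
#' @export
readKinomeMatrix <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  KinomeMatrix(m)
}

#' @rdname KinomeMatrix
#' @export
writeKinomeMatrix <- function(x, file) {
  m <- residualActivity(x)
  utils::write.csv(data.frame(kinase = rownames(m), m, check.names = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname filterGeneSet
#' @param label gene set label.
#' @param members gene identifiers (non-empty).
#' @export
GeneSet <- function(label, members)
  new("GeneSet", label = label, members = unique(as.character(members)))

#' Retain kinases inhibited by at least one panel drug
#'
#' A kinase is relevant when at least one panel drug leaves it with residual
#' activity strictly below `threshold` percent; kinases with more than
#' (100 - threshold)% residual activity across *all* panel drugs are removed.
#' Residuals above 100% (activation) never count as inhibition.
#'
#' @param m a \linkS4class{KinomeMatrix}.
#' @param panel drug identifiers to consider (must be panel columns);
#'   defaults to all columns.
#' @param threshold residual-activity cut in percent (default 50; the
#'   boundary value itself does not qualify).
#' @param strict use strict `<` (default); `FALSE` uses `<=`.
#' @return the filtered \linkS4class{KinomeMatrix}.
#' @export
filterActive <- function(m, panel = panelDrugs(m), threshold = 50,
                         strict = TRUE) {
  if (!length(panel)) stop("panel must name at least one drug")
  if (!all(panel %in% panelDrugs(m)))
    stop("panel drugs absent from the matrix: ",
         paste(setdiff(panel, panelDrugs(m)), collapse = ", "))
  r <- m@residuals[, panel, drop = FALSE]
  hit <- if (strict) r < threshold else r <= threshold
  KinomeMatrix(m@residuals[rowSums(hit) > 0, , drop = FALSE])
}

#' Retain kinases belonging to a gene set
#'
#' Membership is tested after case-folding both sides, so panel and gene-set
#' identifier conventions need not match in case.
#'
#' @param m a \linkS4class{KinomeMatrix}.
#' @param gs a \linkS4class{GeneSet} (e.g. the union of genes annotated to
#'   actin-related ontology terms).
#' @return the filtered matrix; an empty intersection yields a warning and an
#'   empty matrix.
#' @export
filterGeneSet <- function(m, gs) {
  stopifnot(is(m, "KinomeMatrix"), is(gs, "GeneSet"))
  keep <- toupper(kinases(m)) %in% toupper(gs@members)
  if (!any(keep))
    warning("no kinase belongs to gene set '", gs@label, "'")
  KinomeMatrix(m@residuals[keep, , drop = FALSE])
}

#' Mean residual activity per drug
#'
#' @param m a (filtered) \linkS4class{KinomeMatrix} with at least one kinase.
#' @return named numeric vector, one mean per drug.
#' @export
meanResidual <- function(m) {
  if (!nrow(m@residuals)) stop("no kinases to average over")
  colMeans(m@residuals)
}

#' Kinases inhibited by exactly one drug
#'
#' Maps each kinase whose residual activity falls below `threshold` under
#' exactly one drug to that drug -- the "inhibited by this drug alone"
#' selectivity pattern.
#'
#' @param m a \linkS4class{KinomeMatrix}.
#' @param threshold residual-activity cut in percent (strict `<`, default 50).
#' @return named character vector mapping kinase to its unique inhibitor;
#'   empty when no kinase qualifies.
#' @export
uniqueInhibition <- function(m, threshold = 50) {
  r <- m@residuals
  hit <- r < threshold
  one <- rowSums(hit) == 1L
  out <- colnames(r)[apply(hit[one, , drop = FALSE], 1, which.max)]
  stats::setNames(out, rownames(r)[one])
}

#' Build an "actin" gene set from a term-to-genes library
#'
#' Aggregates the member genes of every term whose name matches a pattern
#' (case-insensitive `"actin"` by default), emulating the aggregation of all
#' actin-related ontology terms.  GMT-format libraries can be loaded with
#' `fgsea::gmtPathways()` and passed in directly.
#'
#' @param library named list mapping term names to character gene vectors.
#' @param pattern regular expression matched against term names.
#' @param label label for the resulting set.
#' @return A \linkS4class{GeneSet}.
#' @export
aggregateTermGenes <- function(library, pattern = "actin",
                               label = pattern) {
  hits <- grepl(pattern, names(library), ignore.case = TRUE)
  if (!any(hits)) stop("no term matches pattern '", pattern, "'")
  GeneSet(label, unique(unlist(library[hits], use.names = FALSE)))
}
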