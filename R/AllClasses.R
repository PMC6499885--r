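#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Drug-by-adverse-event report frequency table
#'
#' Long-format report counts for a class of drugs, together with a flat
#' mapping from adverse-event terms to term groups (e.g. "glomerular",
#' "hypertension") and the set of drugs that constitutes the comparator
#' class.  This is the input to the disproportionality (reporting odds
#' ratio) analysis.
#'
#' @slot records data.frame with columns \code{drug}, \code{adr_term},
#'   \code{count} (non-negative integers).
#' @slot termGroups named character vector mapping each adverse-event term to
#'   at most one group label.
#' @slot drugClass character vector of drug identifiers forming the
#'   within-class comparator set; must be a subset of the drugs present.
#' @exportClass FrequencyTable
setClass("FrequencyTable",
  representation(records = "data.frame",
                 termGroups = "character",
                 drugClass = "character"))

setValidity("FrequencyTable", function(object) {
  rec <- object@records
  msg <- character()
  need <- c("drug", "adr_term", "count")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (any(rec$count < 0) || any(rec$count != round(rec$count)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(names(object@termGroups)) && length(object@termGroups))
    msg <- c(msg, "termGroups must be a named character vector")
  if (anyDuplicated(names(object@termGroups)))
    msg <- c(msg, "each term may map to at most one group")
  if (!all(object@drugClass %in% rec$drug))
    msg <- c(msg, "drugClass must be a subset of the drugs present in records")
  if (length(msg)) msg else TRUE
})

#' Two-by-two contingency counts for disproportionality analysis
#'
#' Holds the four cells used by the reporting odds ratio: reports of the
#' target adverse events for the index drug (\code{fDt}), all other reports
#' for the index drug (\code{fDn}), and the same two sums pooled over all
#' other drugs of the class (\code{fNt}, \code{fNn}).
#'
#' @exportClass ContingencyCounts
setClass("ContingencyCounts",
  representation(fDt = "numeric", fDn = "numeric",
                 fNt = "numeric", fNn = "numeric"))

setValidity("ContingencyCounts", function(object) {
  v <- c(object@fDt, object@fDn, object@fNt, object@fNn)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    "all four cells must be finite and non-negative" else TRUE
})

#' Reporting odds ratio with log-scale confidence interval
#'
#' @slot ror the reporting odds ratio.
#' @slot logRor,seLogRor natural log of the ROR and the standard error of the
#'   log, \eqn{\sqrt{1/f_{dt} + 1/f_{dn} + 1/f_{nt} + 1/f_{nn}}}.
#' @slot ciLow,ciHigh confidence limits \eqn{\exp(\log ROR \pm z\,SE)}.
#' @slot z the normal quantile used (1.96 for a 95 percent interval).
#' @slot corrected TRUE when the Haldane-Anscombe +0.5 zero-cell correction
#'   was applied before computing the ratio.
#' @exportClass RorResult
setClass("RorResult",
  representation(ror = "numeric", logRor = "numeric", seLogRor = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", z = "numeric",
                 corrected = "logical"))

setValidity("RorResult", function(object) {
  if (object@ror <= 0) return("ror must be positive")
  if (abs(exp(object@logRor) - object@ror) >
      1e-8 * max(1, object@ror)) return("logRor inconsistent with ror")
  if (object@ciLow > object@ror || object@ciHigh < object@ror)
    return("confidence interval must bracket the ROR")
  TRUE
})

#' Spectral-count matrix with condition labels
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{counts} assay of
#' non-negative integer spectral counts (proteins in rows, replicate samples
#' in columns) with a \code{condition} column in \code{colData} taking values
#' \code{"control"} or \code{"treated"}, at least two samples each.
#'
#' @exportClass SpectralCountMatrix
setClass("SpectralCountMatrix", contains = "SummarizedExperiment")

setValidity("SpectralCountMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% names(cd))
    return("colData must contain a 'condition' column")
  cond <- as.character(cd$condition)
  if (!all(cond %in% c("control", "treated")))
    return("condition labels must be 'control' or 'treated'")
  if (any(table(factor(cond, c("control", "treated"))) < 2L))
    return("at least two samples per condition are required")
  TRUE
})

#' Evidence-weighted protein-protein interactome
#'
#' An undirected simple graph stored as an edge list; each unordered node
#' pair appears once, with a positive integer evidence count (e.g. number of
#' supporting literature sources).  Self-loops are disallowed; duplicate
#' pairs are aggregated by summing evidence at construction.
#'
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{evidence}; rows canonicalized so \code{node_a < node_b}.
#' @exportClass Interactome
setClass("Interactome", representation(edges = "data.frame"))

setValidity("Interactome", function(object) {
  e <- object@edges
  need <- c("node_a", "node_b", "evidence")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (any(e$node_a == e$node_b)) return("self-loops are not allowed")
  if (any(e$evidence <= 0) || any(e$evidence != round(e$evidence)))
    return("evidence must be positive integers")
  key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
  if (anyDuplicated(key)) return("at most one edge per unordered node pair")
  TRUE
})

#' Seed-plus-intermediate subnetwork
#'
#' Result of expanding a seed protein set over an interactome: the seeds, the
#' intermediate nodes added because they touch at least two seeds, the edges
#' of the induced subgraph, and connectivity metrics of its largest
#' connected component.
#'
#' @exportClass SubnetworkResult
setClass("SubnetworkResult",
  representation(seedNodes = "character", intermediateNodes = "character",
                 edges = "data.frame", metrics = "list",
                 minEvidence = "numeric", missingSeeds = "character"))

setValidity("SubnetworkResult", function(object) {
  if (length(intersect(object@seedNodes, object@intermediateNodes)))
    return("intermediate nodes must be disjoint from seed nodes")
  TRUE
})

#' Monte Carlo null distribution for a subnetwork metric
#'
#' @slot metric name of the connectivity metric resampled under the null.
#' @slot samples the null metric values, one per iteration.
#' @slot observed the observed metric value being tested.
#' @slot empiricalP \eqn{(1 + \#\{null \ge observed\}) / (1 + n)}.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(metric = "character", samples = "numeric",
                 nIterations = "integer", observed = "numeric",
                 empiricalP = "numeric"))

setValidity("NullDistribution", function(object) {
  if (length(object@samples) != object@nIterations)
    return("samples length must equal nIterations")
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empirical p must lie in (0, 1]")
  TRUE
})

#' Kinase-by-drug residual activity matrix
#'
#' Percent-of-control catalytic activities from an in vitro kinase panel;
#' rows are kinases, columns are compounds.  Values below 100 indicate
#' inhibition; values above 100 (activation) are allowed.
#'
#' @slot residuals numeric matrix with kinase rownames and drug colnames.
#' @exportClass KinomeMatrix
setClass("KinomeMatrix", representation(residuals = "matrix"))

setValidity("KinomeMatrix", function(object) {
  m <- object@residuals
  if (nrow(m) > 0 && is.null(rownames(m)))
    return("residual matrix must carry kinase rownames")
  if (ncol(m) > 0 && is.null(colnames(m)))
    return("residual matrix must carry drug colnames")
  if (any(!is.finite(m))) return("residual activities must be finite")
  if (any(m < 0)) return("residual activities must be non-negative")
  TRUE
})

#' Named gene set
#' @exportClass GeneSet
setClass("GeneSet", representation(label = "character", members = "character"))

setValidity("GeneSet", function(object) {
  if (!length(object@members)) "gene set must be non-empty" else TRUE
})

#' AFM probe metadata
#'
#' @slot springConstant cantilever spring constant in N/m (default 0.1).
#' @slot halfAngle pyramidal tip half-angle in radians.
#' @slot poissonRatio sample Poisson ratio (0.5 for an incompressible cell).
#' @exportClass AfmProbe
setClass("AfmProbe",
  representation(springConstant = "numeric", halfAngle = "numeric",
                 poissonRatio = "numeric"))

setValidity("AfmProbe", function(object) {
  if (object@springConstant <= 0) return("spring constant must be positive")
  if (object@halfAngle <= 0 || object@halfAngle >= pi / 2)
    return("tip half-angle must lie in (0, pi/2)")
  if (object@poissonRatio < 0 || object@poissonRatio > 0.5 + 1e-9)
    return("Poisson ratio must lie in [0, 0.5]")
  TRUE
})

#' Approach-phase AFM force curve
#'
#' Tip-sample position (m, increasing into the cell) versus force (N) for
#' the advance phase of one indentation, plus probe metadata.
#'
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(z = "numeric", force = "numeric", probe = "AfmProbe"))

setValidity("ForceCurve", function(object) {
  if (length(object@z) != length(object@force))
    return("z and force must have equal length")
  if (length(object@z) < 20L) return("a curve needs at least 20 samples")
  if (any(!is.finite(object@force)) || any(!is.finite(object@z)))
    return("z and force must be finite")
  if (is.unsorted(object@z, strictly = FALSE))
    return("z must be non-decreasing (approach phase)")
  TRUE
})

#' Per-curve elastography result
#'
#' @slot contactPoint detected contact position z0 (m).
#' @slot eFit Hertz-fitted apparent elastic modulus (Pa).
#' @slot fitR2 coefficient of determination of the Hertz fit post contact.
#' @slot pointwiseDelta,pointwiseE depth-dependent pointwise apparent modulus
#'   profile (m, Pa) for depths beyond \code{deltaMin}.
#' @slot eMedian median of the pointwise profile (Pa).
#' @slot substrateFlag TRUE when the depth trend of the pointwise modulus
#'   exceeds the relative-stiffening threshold (substrate artifact marker).
#' @slot substrateSlope relative stiffening slope (fraction of median per m).
#' @exportClass ElasticityResult
setClass("ElasticityResult",
  representation(contactPoint = "numeric", eFit = "numeric", fitR2 = "numeric",
                 pointwiseDelta = "numeric", pointwiseE = "numeric",
                 eMedian = "numeric", substrateFlag = "logical",
                 substrateSlope = "numeric"))

#' Spatial elastography map
#'
#' Grid of per-pixel \linkS4class{ElasticityResult}s in row-major order;
#' pixels whose curves could not be analyzed are NULL (missing), never
#' interpolated.
#'
#' @exportClass ElastographyMap
setClass("ElastographyMap",
  representation(nRows = "integer", nCols = "integer", spacing = "numeric",
                 results = "list"))

setValidity("ElastographyMap", function(object) {
  if (length(object@results) != object@nRows * object@nCols)
    return("results length must equal nRows * nCols")
  TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Parameters of \eqn{V(c) = bottom + (top - bottom) / (1 + (c/EC50)^{hill})}
#' fitted by nonlinear least squares on log-concentration.
#'
#' @slot bottom,top lower/upper viability asymptotes (percent of vehicle).
#' @slot hillSlope Hill coefficient (positive for a decreasing curve).
#' @slot ec50 half-maximal effective concentration (nM).
#' @slot se named standard errors of the four parameters.
#' @slot converged FALSE when the optimizer failed; parameters then carry the
#'   last iterate and should not be trusted.
#' @slot extrapolated TRUE when the fitted EC50 falls outside the tested
#'   concentration range.
#' @exportClass FourPLFit
setClass("FourPLFit",
  representation(bottom = "numeric", top = "numeric", hillSlope = "numeric",
                 ec50 = "numeric", se = "numeric", converged = "logical",
                 extrapolated = "logical", concRange = "numeric"))

setValidity("FourPLFit", function(object) {
  if (object@converged && object@ec50 <= 0) return("EC50 must be positive")
  TRUE
})
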