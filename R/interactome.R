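#' Construct an Interactome
#'
#' Builds an undirected evidence-weighted interaction graph from an edge
#' list.  Self-loops are dropped; duplicate unordered pairs are aggregated by
#' summing their evidence counts.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `evidence`
#'   (positive integers, e.g. number of supporting literature sources).
#' @return An \linkS4class{Interactome}.
#' @export
Interactome <- function(edges) {
  a <- as.character(edges$node_a); b <- as.character(edges$node_b)
  ev <- as.numeric(edges$evidence)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; ev <- ev[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  agg <- stats::aggregate(ev, by = list(node_a = lo, node_b = hi), FUN = sum)
  names(agg)[3] <- "evidence"
  agg <- agg[order(agg$node_a, agg$node_b), , drop = FALSE]
  rownames(agg) <- NULL
  new("Interactome", edges = agg)
}

#' @rdname Interactome
#' @param x an Interactome.
#' @export
interactomeEdges <- function(x) x@edges

#' @rdname Interactome
#' @export
interactomeNodes <- function(x) sort(unique(c(x@edges$node_a, x@edges$node_b)))

setMethod("show", "Interactome", function(object) {
  cat("Interactome:", length(interactomeNodes(object)), "nodes,",
      nrow(object@edges), "edges; evidence range",
      paste(range(object@edges$evidence), collapse = "-"), "\n")
})

#' Read / write interactome edge lists
#'
#' Plain TSV with columns `node_a`, `node_b`, `evidence`.
#' @param file edge list TSV path.
#' @export
readEdgeList <- function(file)
  Interactome(utils::read.delim(file, stringsAsFactors = FALSE))

#' @rdname readEdgeList
#' @param x an Interactome.
#' @export
writeEdgeList <- function(x, file) {
  utils::write.table(interactomeEdges(x), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Index an interactome for repeated expansion: integer endpoint vectors after
# the evidence filter, plus per-node incidence lists so that per-seed-set work
# scales with the degree of the touched nodes, not with the whole graph.
compileInteractome <- function(g, minEvidence = 2) {
  e <- g@edges[g@edges$evidence >= minEvidence, , drop = FALSE]
  nodes <- sort(unique(c(g@edges$node_a, g@edges$node_b)))
  a <- match(e$node_a, nodes)
  b <- match(e$node_b, nodes)
  n <- length(nodes)
  incid <- vector("list", n)
  if (length(a)) {
    byA <- split(seq_along(a), factor(a, levels = seq_len(n)))
    byB <- split(seq_along(b), factor(b, levels = seq_len(n)))
    incid <- mapply(c, byA, byB, SIMPLIFY = FALSE)
  } else incid <- rep(list(integer()), n)
  list(nodes = nodes, n = n, a = a, b = b, incid = incid)
}
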