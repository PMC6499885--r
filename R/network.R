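# Core expansion on a compiled interactome with integer seed indices.
# Returns the subnetwork's node/edge index sets and connectivity metrics.
expandCompiled <- function(cg, seedIdx) {
  seedIdx <- seedIdx[!is.na(seedIdx)]
  seedMask <- logical(cg$n); seedMask[seedIdx] <- TRUE
  touch <- unique(unlist(cg$incid[seedIdx], use.names = FALSE))
  interIdx <- integer()
  if (length(touch)) {
    ta <- cg$a[touch]; tb <- cg$b[touch]
    sa <- seedMask[ta]; sb <- seedMask[tb]
    other <- c(tb[sa & !sb], ta[sb & !sa])  # non-seed endpoints of seed edges
    cnt <- tabulate(other, nbins = cg$n)    # distinct seeds: edges are unique
    interIdx <- which(cnt >= 2L)
  }
  subIdx <- c(seedIdx, interIdx)
  subMask <- seedMask; subMask[interIdx] <- TRUE
  subTouch <- unique(unlist(cg$incid[subIdx], use.names = FALSE))
  keep <- subTouch[subMask[cg$a[subTouch]] & subMask[cg$b[subTouch]]]
  ea <- cg$a[keep]; eb <- cg$b[keep]
  m <- length(subIdx)
  metrics <- if (m == 0L) {
    list(n_nodes = 0L, n_edges = 0L, mean_degree = NaN, n_components = 0L,
         largest_component_node_count = 0L, largest_component_edge_count = 0L,
         largest_component_share = NaN)
  } else {
    a2 <- match(ea, subIdx); b2 <- match(eb, subIdx)
    gr <- igraph::make_graph(rbind(a2, b2), n = m, directed = FALSE)
    comp <- igraph::components(gr)
    big <- which.max(comp$csize)
    inBig <- comp$membership[a2] == big
    list(n_nodes = m, n_edges = length(ea),
         mean_degree = 2 * length(ea) / m,
         n_components = comp$no,
         largest_component_node_count = as.integer(max(comp$csize)),
         largest_component_edge_count = as.integer(sum(inBig)),
         largest_component_share = max(comp$csize) / m)
  }
  list(seedIdx = seedIdx, interIdx = interIdx,
       edgeIdx = keep, metrics = metrics)
}

#' Expand a seed set into a one-intermediate subnetwork
#'
#' Drops interactome edges with evidence below `minEvidence`, then adds every
#' non-seed node adjacent to at least two distinct seeds (a node touching a
#' single seed cannot connect anything), and returns the induced subgraph on
#' seeds plus intermediates.  Connectivity metrics are reported for the whole
#' subgraph and for its largest connected component (the "interconnected
#' island").
#'
#' Seeds absent from the interactome are recorded in the result, not fatal.
#'
#' @param g an \linkS4class{Interactome}.
#' @param seeds character vector of seed node identifiers (non-empty).
#' @param minEvidence minimum per-edge evidence (default 2, i.e. at least two
#'   supporting sources).
#' @return A \linkS4class{SubnetworkResult}.
#' @examples
#' g <- Interactome(data.frame(node_a = c("A", "B", "C", "A"),
#'                             node_b = c("X", "X", "Y", "B"),
#'                             evidence = c(2, 3, 2, 2)))
#' expandSubnetwork(g, c("A", "B", "C"))
#' @export
expandSubnetwork <- function(g, seeds, minEvidence = 2) {
  stopifnot(is(g, "Interactome"))
  if (!length(seeds)) stop("seed set must be non-empty")
  seeds <- unique(as.character(seeds))
  cg <- compileInteractome(g, minEvidence)
  idx <- match(seeds, cg$nodes)
  missing <- seeds[is.na(idx)]
  ex <- expandCompiled(cg, idx)
  # retained edge rows, by index into the evidence-filtered edge table
  eAll <- g@edges[g@edges$evidence >= minEvidence, , drop = FALSE]
  e <- eAll[ex$edgeIdx, , drop = FALSE]
  rownames(e) <- NULL
  new("SubnetworkResult",
      seedNodes = cg$nodes[ex$seedIdx],
      intermediateNodes = cg$nodes[ex$interIdx],
      edges = e, metrics = ex$metrics,
      minEvidence = minEvidence, missingSeeds = missing)
}

setMethod("show", "SubnetworkResult", function(object) {
  m <- object@metrics
  cat("SubnetworkResult:", length(object@seedNodes), "seeds +",
      length(object@intermediateNodes), "intermediates,",
      m$n_edges, "edges\n")
  cat(sprintf("  largest component: %d nodes / %d edges; mean degree %.3g\n",
              m$largest_component_node_count, m$largest_component_edge_count,
              m$mean_degree))
  if (length(object@missingSeeds))
    cat("  seeds absent from interactome:", length(object@missingSeeds), "\n")
})

#' Connectivity metrics of a subnetwork
#'
#' Recomputes node count, edge count, mean degree (2E/N), component count,
#' and the node/edge counts and node share of the largest connected
#' component, directly from the stored edge set and node sets.
#'
#' @param sub a \linkS4class{SubnetworkResult}.
#' @return named list of metrics.
#' @export
componentMetrics <- function(sub) {
  nodes <- c(sub@seedNodes, sub@intermediateNodes)
  m <- length(nodes)
  if (m == 0L)
    return(list(n_nodes = 0L, n_edges = 0L, mean_degree = NaN,
                n_components = 0L, largest_component_node_count = 0L,
                largest_component_edge_count = 0L,
                largest_component_share = NaN))
  a2 <- match(sub@edges$node_a, nodes); b2 <- match(sub@edges$node_b, nodes)
  gr <- igraph::make_graph(rbind(a2, b2), n = m, directed = FALSE)
  comp <- igraph::components(gr)
  big <- which.max(comp$csize)
  list(n_nodes = m, n_edges = nrow(sub@edges),
       mean_degree = 2 * nrow(sub@edges) / m,
       n_components = comp$no,
       largest_component_node_count = as.integer(max(comp$csize)),
       largest_component_edge_count =
         as.integer(sum(comp$membership[a2] == big)),
       largest_component_share = max(comp$csize) / m)
}

#' Monte Carlo resampling null for subnetwork specificity
#'
#' Repeatedly samples `k` nodes without replacement from `universe` (the
#' experimentally measured protein list, *not* the whole interactome),
#' expands each random seed set exactly as the observed one, and records the
#' chosen connectivity metric.  The empirical p-value is
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{iter})}.
#'
#' @param g an \linkS4class{Interactome}.
#' @param universe character vector of candidate seed nodes (the sampling
#'   frame); nodes absent from the interactome are allowed and simply carry
#'   no edges.
#' @param k number of seeds per null draw (must not exceed the universe).
#' @param observed a \linkS4class{SubnetworkResult} or a single observed
#'   metric value.
#' @param nIterations number of null draws (at least 20, default 1000).
#' @param metric which metric to resample (default
#'   `"largest_component_edge_count"`).
#' @param minEvidence evidence threshold, matching the observed expansion.
#' @param seed optional integer seed for the null draws; the global RNG state
#'   is restored afterwards.
#' @return A \linkS4class{NullDistribution}.
#' @export
monteCarloNull <- function(g, universe, k, observed, nIterations = 1000,
                           metric = "largest_component_edge_count",
                           minEvidence = 2, seed = NULL) {
  stopifnot(is(g, "Interactome"))
  universe <- unique(as.character(universe))
  if (k > length(universe)) stop("k exceeds the universe size")
  if (nIterations < 20) stop("at least 20 iterations are needed for any p resolution")
  obs <- if (is(observed, "SubnetworkResult"))
    as.numeric(observed@metrics[[metric]]) else as.numeric(observed)
  cg <- compileInteractome(g, minEvidence)
  uniIdx <- match(universe, cg$nodes)
  samples <- withSeed(seed, {
    vapply(seq_len(nIterations), function(i) {
      sel <- uniIdx[sample.int(length(uniIdx), k)]
      as.numeric(expandCompiled(cg, sel)$metrics[[metric]])
    }, numeric(1))
  })
  new("NullDistribution", metric = metric, samples = samples,
      nIterations = as.integer(nIterations), observed = obs,
      empiricalP = (1 + sum(samples >= obs)) / (1 + nIterations))
}

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution of %s: %d iterations, observed %.4g, empirical p = %.4g\n",
              object@metric, object@nIterations, object@observed,
              object@empiricalP))
})

#' @rdname monteCarloNull
#' @param x a NullDistribution.
#' @export
empiricalP <- function(x) x@empiricalP

#' @rdname monteCarloNull
#' @export
nullSamples <- function(x) x@samples
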