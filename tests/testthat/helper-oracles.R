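# Independent reference implementations used as oracles.  These are written
# from the definitions, deliberately not sharing code with the package.

# direct ROR evaluation: ratio of report odds, Woolf SE, log-scale CI
oracleRor <- function(a, b, c, d, z = 1.96) {
  r <- (a / b) / (c / d)
  s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = r, se = s, lo = exp(log(r) - z * s), hi = exp(log(r) + z * s))
}

# step-up BH from the definition: q_(i) = min_{j >= i} min(1, m p_(j) / j)
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m / i * p[o[i]])
    q[o[i]] <- running
  }
  q
}

# two-loop kinome filter chain reference
bruteKinomeChain <- function(resid, geneSetMembers, threshold = 50) {
  keep <- character()
  for (k in rownames(resid)) {
    inhibited <- FALSE
    for (d in colnames(resid))
      if (resid[k, d] < threshold) inhibited <- TRUE
    if (inhibited && toupper(k) %in% toupper(geneSetMembers))
      keep <- c(keep, k)
  }
  resid[keep, , drop = FALSE]
}

bruteUnique <- function(resid, threshold = 50) {
  out <- character()
  for (k in rownames(resid)) {
    hits <- colnames(resid)[resid[k, ] < threshold]
    if (length(hits) == 1L) out[k] <- hits
  }
  out
}

# graph metrics recomputed with igraph straight from an edge data.frame
oracleMetrics <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  bigNodes <- names(comp$membership)[comp$membership == big]
  inBig <- edges$node_a %in% bigNodes & edges$node_b %in% bigNodes
  list(n_nodes = length(nodes), n_edges = nrow(edges),
       mean_degree = 2 * nrow(edges) / length(nodes),
       largest_component_node_count = max(comp$csize),
       largest_component_edge_count = sum(inBig))
}

# random frequency table for ROR property tests
randomContingency <- function() {
  ContingencyCounts(sample(1:500, 1), sample(1:5000, 1),
                    sample(1:500, 1), sample(1:50000, 1))
}

# synthetic pyramidal Hertz curve built outside the generator
referenceCurve <- function(z0, E, probe = AfmProbe(), gamma = 0,
                           noiseFrac = 0, dz = 20e-9, depth = 4e-6) {
  z <- seq(0, z0 + depth, by = dz)
  delta <- pmax(0, z - z0)
  coef <- tan(probe@halfAngle) / sqrt(2) / (1 - probe@poissonRatio^2)
  f <- coef * E * (1 + gamma * delta) * delta^2
  if (noiseFrac > 0) f <- f * (1 + rnorm(length(f), 0, noiseFrac))
  ForceCurve(z, f, probe)
}
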