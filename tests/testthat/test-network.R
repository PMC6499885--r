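handGraph <- function() {
  Interactome(data.frame(node_a = c("A", "B", "C", "A"),
                         node_b = c("X", "X", "Y", "B"),
                         evidence = c(2, 3, 2, 2)))
}

test_that("construction canonicalizes, aggregates and rejects loops", {
  g <- Interactome(data.frame(node_a = c("B", "A", "A", "C"),
                              node_b = c("A", "B", "A", "D"),
                              evidence = c(1, 2, 5, 1)))
  e <- interactomeEdges(g)
  expect_equal(nrow(e), 2)              # A-A loop dropped, A-B aggregated
  expect_equal(e$evidence[e$node_a == "A" & e$node_b == "B"], 3)
})

test_that("expansion adds nodes touching two seeds and keeps the island", {
  sub <- expandSubnetwork(handGraph(), c("A", "B", "C"))
  expect_setequal(sub@intermediateNodes, "X")   # Y touches only one seed
  m <- sub@metrics
  expect_equal(m$largest_component_node_count, 3L)   # A, B, X
  expect_equal(m$largest_component_edge_count, 3L)
  expect_equal(m$n_nodes, 4L)
})

test_that("a seed clique with no qualifying neighbors stays a clique", {
  g <- Interactome(data.frame(node_a = c("A", "A", "B", "A"),
                              node_b = c("B", "C", "C", "Z"),
                              evidence = c(2, 2, 2, 2)))
  sub <- expandSubnetwork(g, c("A", "B", "C"))
  expect_length(sub@intermediateNodes, 0)
  expect_equal(sub@metrics$n_edges, 3L)
})

test_that("an evidence threshold above every edge leaves isolated seeds", {
  sub <- expandSubnetwork(handGraph(), c("A", "B", "C"), minEvidence = 10)
  expect_equal(sub@metrics$n_edges, 0L)
  expect_equal(sub@metrics$largest_component_node_count, 1L)
  expect_error(expandSubnetwork(handGraph(), character()), "non-empty")
})

test_that("absent seeds are recorded, not fatal", {
  sub <- expandSubnetwork(handGraph(), c("A", "B", "QQQ"))
  expect_identical(sub@missingSeeds, "QQQ")
})

test_that("component metrics match direct computation on basic shapes", {
  tri <- Interactome(data.frame(node_a = c("A", "B", "A"),
                                node_b = c("B", "C", "C"), evidence = 2))
  m <- componentMetrics(expandSubnetwork(tri, c("A", "B", "C")))
  expect_equal(m$mean_degree, 2)
  expect_equal(m$n_edges, 3L)
  path <- Interactome(data.frame(node_a = c("A", "B", "C"),
                                 node_b = c("B", "C", "D"), evidence = 2))
  mp <- componentMetrics(expandSubnetwork(path, c("A", "B", "C", "D")))
  expect_equal(mp$mean_degree, 1.5)
})

test_that("metrics equal an igraph recomputation on random subnetworks", {
  for (s in 1:5) {
    gen <- genInteractome(scenarioConfig(rngSeed = 40 + s,
      network = list(nNodes = 300, plantedSeedSize = 25L,
                     plantedIntermediates = 5L)))
    sub <- expandSubnetwork(gen$interactome, gen$seeds)
    o <- oracleMetrics(c(sub@seedNodes, sub@intermediateNodes), sub@edges)
    m <- componentMetrics(sub)
    expect_equal(m$n_nodes, o$n_nodes)
    expect_equal(m$n_edges, o$n_edges)
    expect_equal(m$mean_degree, o$mean_degree)
    expect_equal(m$largest_component_node_count,
                 o$largest_component_node_count)
    expect_equal(m$largest_component_edge_count,
                 o$largest_component_edge_count)
    expect_identical(sub@metrics[names(m)], m)
  }
})

test_that("raising the evidence threshold never adds nodes or edges", {
  gen <- genInteractome(scenarioConfig(rngSeed = 47,
    network = list(nNodes = 300, plantedSeedSize = 25L)))
  prevNodes <- Inf; prevEdges <- Inf
  for (ev in 1:4) {
    sub <- expandSubnetwork(gen$interactome, gen$seeds, minEvidence = ev)
    expect_lte(sub@metrics$n_nodes, prevNodes)
    expect_lte(sub@metrics$n_edges, prevEdges)
    prevNodes <- sub@metrics$n_nodes; prevEdges <- sub@metrics$n_edges
  }
})

test_that("the empirical p-value follows its definition and is reproducible", {
  gen <- genInteractome(scenarioConfig(rngSeed = 48,
    network = list(nNodes = 300, plantedSeedSize = 25L)))
  sub <- expandSubnetwork(gen$interactome, gen$seeds)
  nd <- monteCarloNull(gen$interactome, gen$universe, 25, sub,
                       nIterations = 99, seed = 7)
  expect_equal(empiricalP(nd),
               (1 + sum(nullSamples(nd) >= nd@observed)) / 100)
  nd2 <- monteCarloNull(gen$interactome, gen$universe, 25, sub,
                        nIterations = 99, seed = 7)
  expect_identical(nullSamples(nd), nullSamples(nd2))
  expect_error(monteCarloNull(gen$interactome, gen$universe, 25, sub,
                              nIterations = 10, seed = 1), "at least 20")
  expect_error(monteCarloNull(gen$interactome, gen$universe, 1000, sub,
                              nIterations = 99, seed = 1), "exceeds")
})

test_that("an observed value above every null sample gives p = 1/(n+1)", {
  gen <- genInteractome(scenarioConfig(rngSeed = 49,
    network = list(nNodes = 300, plantedSeedSize = 25L)))
  nd <- monteCarloNull(gen$interactome, gen$universe, 25, observed = 1e9,
                       nIterations = 99, seed = 3)
  expect_equal(empiricalP(nd), 1 / 100)
})

test_that("a planted dense module is called specific", {
  gen <- genInteractome(scenarioConfig(rngSeed = 50))  # 2130 nodes, 76 seeds
  sub <- expandSubnetwork(gen$interactome, gen$seeds)
  nd <- monteCarloNull(gen$interactome, gen$universe, 76, sub,
                       nIterations = 500, seed = 9)
  expect_lte(empiricalP(nd), 0.01)
})

test_that("null-density planted sets look like random draws", {
  gen <- genInteractome(nullScenario(scenarioConfig(rngSeed = 51,
    network = list(nNodes = 600, plantedSeedSize = 40L))))
  sub <- expandSubnetwork(gen$interactome, gen$seeds)
  nd <- monteCarloNull(gen$interactome, gen$universe, 40, sub,
                       nIterations = 200, seed = 11)
  expect_gt(empiricalP(nd), 0.01)
})
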