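test_that("identical configurations reproduce identical outputs", {
  cfg <- scenarioConfig(rngSeed = 5, network = list(nNodes = 400,
                                                    plantedSeedSize = 30L))
  expect_identical(genFaers(cfg), genFaers(cfg))
  expect_identical(spectralCounts(genSpectralCounts(cfg)$matrix),
                   spectralCounts(genSpectralCounts(cfg)$matrix))
  expect_identical(interactomeEdges(genInteractome(cfg)$interactome),
                   interactomeEdges(genInteractome(cfg)$interactome))
  expect_identical(residualActivity(genKinome(cfg)$matrix),
                   residualActivity(genKinome(cfg)$matrix))
  expect_identical(genForceCurves(cfg)$curves[[1]]@force,
                   genForceCurves(cfg)$curves[[1]]@force)
  expect_identical(genDoseResponse(cfg)$plate, genDoseResponse(cfg)$plate)
})

test_that("stages draw from independent substreams", {
  cfg <- scenarioConfig(rngSeed = 6)
  a <- genSpectralCounts(cfg)
  # consuming another stage's stream must not disturb this stage
  invisible(genFaers(cfg)); invisible(genKinome(cfg))
  b <- genSpectralCounts(cfg)
  expect_identical(spectralCounts(a$matrix), spectralCounts(b$matrix))
})

test_that("degenerate configurations are rejected", {
  expect_error(scenarioConfig(faers = list(nDrugs = 1L)), "two drugs")
  expect_error(scenarioConfig(faers = list(nGlomTerms = 0L)), "non-empty")
  expect_error(scenarioConfig(faers = list(trueRor = -1)), "positive")
  expect_error(scenarioConfig(phospho = list(effectRatio = 1)),
               "unidentifiable")
  expect_error(scenarioConfig(phospho = list(nReplicates = 1L)),
               "two replicates")
  expect_error(scenarioConfig(network = list(plantedSeedSize = 5000L)),
               "smaller")
  expect_error(scenarioConfig(kinome = list(plantedDrug = "nope")), "panel")
  expect_error(scenarioConfig(afm = list(forceNoiseFrac = -0.1)),
               "non-negative")
  expect_error(scenarioConfig(afm = list(modulusPa = -5)), "positive")
  expect_error(scenarioConfig(dose = list(concentrations = c(2, 1))),
               "increasing")
})

test_that("default scales mirror the study shapes", {
  cfg <- scenarioConfig(rngSeed = 7)
  gen <- genSpectralCounts(cfg)
  expect_equal(dim(spectralCounts(gen$matrix)), c(2130, 6))
  expect_length(gen$truth, 76)
  gk <- genKinome(cfg)
  expect_equal(dim(residualActivity(gk$matrix)), c(300, 6))
  expect_equal(cfg$afm$gridShape, c(6L, 6L))
  ga <- genForceCurves(cfg)
  expect_length(ga$curves, 36)
  expect_equal(range(cfg$dose$concentrations), c(0.5, 50000))
  expect_equal(cfg$dose$ec50, 253)
  expect_equal(cfg$phospho$effectRatio, 0.165)
})

test_that("a unit true ROR centers the estimated ROR on one", {
  logs <- vapply(1:30, function(s) {
    gen <- genFaers(nullScenario(scenarioConfig(rngSeed = 1000 + s)))
    computeRor(buildContingency(gen$table, "drug01", "glomerular"))@logRor
  }, numeric(1))
  expect_lt(abs(mean(logs)), 3 * sd(logs) / sqrt(length(logs)) + 0.02)
})

test_that("a planted ROR of 8 is recovered within sampling error", {
  rors <- vapply(1:30, function(s) {
    gen <- genFaers(scenarioConfig(rngSeed = 1100 + s))
    computeRor(buildContingency(gen$table, "drug01", "glomerular"))@ror
  }, numeric(1))
  expect_lt(abs(mean(log(rors)) - log(8)), 0.05)
})

test_that("without planting, conditions are exchangeable", {
  gen <- genSpectralCounts(scenarioConfig(rngSeed = 8,
    phospho = list(nProteins = 800L, plantedFraction = 0)))
  expect_length(gen$truth, 0)
  m <- spectralCounts(gen$matrix)
  expect_lt(abs(mean(m[, 1:3]) - mean(m[, 4:6])),
            3 * sd(m) / sqrt(length(m) / 2))
})

test_that("planted kinome residuals stay in range and single-hit", {
  gen <- genKinome(scenarioConfig(rngSeed = 9))
  m <- residualActivity(gen$matrix)
  expect_true(all(m >= 0 & m <= 120))
  hit <- m[names(gen$truth), ] < 50
  expect_identical(colnames(m)[hit], unname(gen$truth))
  expect_true(names(gen$truth) %in% gen$geneSet@members)
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- scenarioConfig(rngSeed = 10, phospho = list(nProteins = 99L))
  path <- tempfile(fileext = ".yaml")
  writeScenarioConfig(cfg, path)
  cfg2 <- readScenarioConfig(path)
  expect_equal(cfg2$phospho$nProteins, 99L)
  expect_identical(spectralCounts(genSpectralCounts(cfg)$matrix),
                   spectralCounts(genSpectralCounts(cfg2)$matrix))
})
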