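#' Scenario configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator.  Each stage draws from
#' its own L'Ecuyer-CMRG substream of the scenario seed, so stages can be
#' regenerated in isolation and never share random draws.  Defaults mirror
#' the scales of the motivating study: 16 drugs with a planted
#' glomerular-risk outlier at ROR 8; 2130 proteins with 76 planted
#' down-regulated at a 0.165 count ratio (the paxillin-like 20 vs 3.3
#' contrast), n = 3 per condition; a 2130-node interactome with a 76-seed
#' module at 5x background density; a 300-kinase x 6-drug panel with one
#' uniquely inhibited kinase; 6x6 grids of 4-um indentations with a 0.1 N/m
#' pyramidal probe; and an 8-point 0.5-50,000 nM dilution with a planted
#' EC50 of 253 nM.
#'
#' @param rngSeed integer scenario seed.
#' @param faers,phospho,network,kinome,afm,dose named lists overriding the
#'   per-stage defaults (see the package vignette for every knob).
#' @return A `ScenarioConfig` object.
#' @export
scenarioConfig <- function(rngSeed = 1L, faers = list(), phospho = list(),
                           network = list(), kinome = list(), afm = list(),
                           dose = list()) {
  def <- list(
    faers = list(
      nDrugs = 16L, nGlomTerms = 5L, nHypTerms = 5L, nOtherTerms = 50L,
      baselineRate = 50, plantedDrug = "drug01",
      plantedGroup = "glomerular", trueRor = 8, groupBRor = 1,
      volumeSdLog = 0.5, coRiskSdLog = 0.3),
    phospho = list(
      nProteins = 2130L, nReplicates = 3L, baselineMean = 20,
      plantedFraction = 76 / 2130, effectRatio = 0.165, dispersion = NULL),
    network = list(
      nNodes = 2130L, meanDegree = 6, evidenceProbs = c(0.3, 0.3, 0.2, 0.1, 0.1),
      plantedSeedSize = 76L, plantedDensity = 5, plantedIntermediates = 20L),
    kinome = list(
      nKinases = 300L, drugs = paste0("KI", 1:6),
      plantedKinase = "K001", plantedDrug = "KI1",
      backgroundMean = 90, backgroundSd = 10, backgroundMin = 55,
      nPromiscuous = 10L, geneSetSize = 30L),
    afm = list(
      gridShape = c(6L, 6L), spacing = 4e-6, modulusField = NULL,
      modulusPa = 10e3, forceNoiseFrac = 0, forceNoiseSdAbs = 0,
      contactOffsetRange = c(0.2e-6, 0.8e-6), maxIndentation = 4e-6,
      dz = 20e-9, springConstant = 0.1, halfAngleDeg = 35,
      poissonRatio = 0.5, stiffeningPerMeter = 0,
      treatedModulusPa = 3e3, nCellsPerGroup = 6L, cellCvLog = 0.3),
    dose = list(
      bottom = 0, top = 100, hill = 1, ec50 = 253,
      concentrations = 10^seq(log10(0.5), log10(50000), length.out = 8),
      noiseSd = 5, nReplicates = 4L, nVehicle = 4L, nPlates = 4L))
  cfg <- list(rngSeed = as.integer(rngSeed),
              faers = utils::modifyList(def$faers, faers),
              phospho = utils::modifyList(def$phospho, phospho),
              network = utils::modifyList(def$network, network),
              kinome = utils::modifyList(def$kinome, kinome),
              afm = utils::modifyList(def$afm, afm),
              dose = utils::modifyList(def$dose, dose))
  validateScenarioConfig(cfg)
  structure(cfg, class = "ScenarioConfig")
}

validateScenarioConfig <- function(cfg) {
  f <- cfg$faers
  if (f$nDrugs < 2L) stop("faers: at least two drugs are required")
  if (f$nGlomTerms < 1L || f$nHypTerms < 1L)
    stop("faers: ADR groups must be non-empty")
  if (f$trueRor <= 0 || f$groupBRor <= 0) stop("faers: RORs must be positive")
  p <- cfg$phospho
  if (p$nReplicates < 2L) stop("phospho: at least two replicates per condition")
  if (p$plantedFraction < 0 || p$plantedFraction >= 1)
    stop("phospho: plantedFraction must lie in [0, 1)")
  if (p$effectRatio <= 0) stop("phospho: effectRatio must be positive")
  if (p$effectRatio == 1 && p$plantedFraction > 0)
    stop("phospho: effectRatio = 1 with planted proteins is unidentifiable")
  n <- cfg$network
  if (n$plantedSeedSize >= n$nNodes)
    stop("network: planted seed set must be smaller than the node set")
  if (n$meanDegree >= n$nNodes - 1)
    stop("network: mean degree infeasible for the node count")
  k <- cfg$kinome
  if (!is.null(k$plantedKinase) && !is.null(k$plantedDrug) &&
      !k$plantedDrug %in% k$drugs)
    stop("kinome: planted drug must belong to the panel")
  a <- cfg$afm
  if (a$forceNoiseFrac < 0 || a$forceNoiseSdAbs < 0)
    stop("afm: noise parameters must be non-negative")
  if (!is.null(a$modulusField) && any(a$modulusField <= 0))
    stop("afm: the modulus field must be strictly positive")
  if (is.null(a$modulusField) && a$modulusPa <= 0)
    stop("afm: the modulus field must be strictly positive")
  d <- cfg$dose
  if (any(d$concentrations <= 0) || is.unsorted(d$concentrations,
                                                strictly = TRUE))
    stop("dose: concentrations must be positive and strictly increasing")
  invisible(cfg)
}

#' @rdname scenarioConfig
#' @param cfg a ScenarioConfig.
#' @return `nullScenario` returns the same configuration with every planted
#'   effect disabled (ROR 1, no planted proteins, background-density module,
#'   no planted kinase, homogeneous modulus field).
#' @export
nullScenario <- function(cfg) {
  cfg$faers$trueRor <- 1
  cfg$faers$groupBRor <- 1
  cfg$phospho$plantedFraction <- 0
  cfg$network$plantedDensity <- 1
  cfg$network$plantedIntermediates <- 0L
  cfg$kinome$plantedKinase <- NULL
  cfg$kinome$plantedDrug <- NULL
  cfg$afm$treatedModulusPa <- cfg$afm$modulusPa
  cfg
}

#' @rdname scenarioConfig
#' @param file YAML (or JSON) path.
#' @export
readScenarioConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(scenarioConfig, raw)
}

#' @rdname scenarioConfig
#' @export
writeScenarioConfig <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat("ScenarioConfig (seed", x$rngSeed, ")\n")
  cat(sprintf("  faers:   %d drugs, planted ROR %.3g for '%s'\n",
              x$faers$nDrugs, x$faers$trueRor, x$faers$plantedDrug))
  cat(sprintf("  phospho: %d proteins x 2x%d, planted fraction %.3g, ratio %.3g\n",
              x$phospho$nProteins, x$phospho$nReplicates,
              x$phospho$plantedFraction, x$phospho$effectRatio))
  cat(sprintf("  network: %d nodes, %d seeds at %.3gx density\n",
              x$network$nNodes, x$network$plantedSeedSize,
              x$network$plantedDensity))
  cat(sprintf("  kinome:  %d kinases x %d drugs\n", x$kinome$nKinases,
              length(x$kinome$drugs)))
  cat(sprintf("  afm:     %dx%d grid, %.3g kPa field\n", x$afm$gridShape[1],
              x$afm$gridShape[2], x$afm$modulusPa / 1e3))
  cat(sprintf("  dose:    EC50 %.4g nM, %d concentrations\n", x$dose$ec50,
              length(x$dose$concentrations)))
  invisible(x)
}

# stage -> RNG substream index
.streams <- c(faers = 1L, phospho = 2L, network = 3L, kinome = 4L,
              afm = 5L, dose = 6L)

#' Generate a synthetic adverse-event frequency table
#'
#' Draws Poisson report counts for every (drug, term) cell.  Background
#' drugs share a latent per-drug "vascular co-risk" multiplier acting on
#' both the glomerular and hypertension term groups (so the class follows a
#' common log-log co-risk trend), plus a per-drug report-volume multiplier
#' that cancels out of every ROR.  The planted drug's group-A (and group-B)
#' rate multipliers are solved so that the *expected-count* reporting odds
#' ratios equal `trueRor` (and `groupBRor`) exactly.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `table` (a \linkS4class{FrequencyTable}) and `truth`
#'   (planted drug, group, and the two planted RORs).
#' @export
genFaers <- function(cfg) {
  f <- cfg$faers
  withStream(cfg$rngSeed, .streams["faers"], {
    drugs <- sprintf("drug%02d", seq_len(f$nDrugs))
    if (!f$plantedDrug %in% drugs)
      stop("planted drug must be one of ", drugs[1], "..",
           drugs[f$nDrugs])
    glom <- sprintf("glom_term%02d", seq_len(f$nGlomTerms))
    hyp <- sprintf("hyp_term%02d", seq_len(f$nHypTerms))
    other <- sprintf("other_term%02d", seq_len(f$nOtherTerms))
    termGroups <- c(stats::setNames(rep("glomerular", length(glom)), glom),
                    stats::setNames(rep("hypertension", length(hyp)), hyp))
    terms <- c(glom, hyp, other)
    vol <- exp(stats::rnorm(f$nDrugs, 0, f$volumeSdLog))
    co <- exp(stats::rnorm(f$nDrugs, 0, f$coRiskSdLog))
    pIdx <- match(f$plantedDrug, drugs)
    co[pIdx] <- 1
    # per-(drug, term) rate multipliers before planting
    mult <- matrix(1, f$nDrugs, length(terms),
                   dimnames = list(drugs, terms))
    mult[, c(glom, hyp)] <- co
    lam <- f$baselineRate * vol * mult  # recycles vol down columns
    # Solve the two planted group multipliers jointly so both expected-count
    # RORs are exact.  The equations couple: scaling the planted drug's
    # group-B terms changes the "all other ADR" denominator of its group-A
    # ROR and vice versa.  Writing gA/hB for the planted drug's new group
    # totals and aO for its unaffected remainder, the targets demand
    #   gA = RA (hB + aO),  hB = RB (gA + aO)
    # with RA, RB the target odds against the pooled comparator; this linear
    # system has the positive solution below whenever RA * RB < 1.
    inA <- terms %in% glom
    inB <- terms %in% hyp
    aG <- sum(lam[pIdx, inA]); aH <- sum(lam[pIdx, inB])
    aO <- sum(lam[pIdx, !inA & !inB])
    RA <- f$trueRor * sum(lam[-pIdx, inA]) / sum(lam[-pIdx, !inA])
    RB <- f$groupBRor * sum(lam[-pIdx, inB]) / sum(lam[-pIdx, !inB])
    if (RA * RB >= 1)
      stop("faers: the requested ROR pair is infeasible ",
           "(the two planted odds multiply to one or more)")
    gA <- RA * aO * (1 + RB) / (1 - RA * RB)
    hB <- RB * (gA + aO)
    lam[pIdx, glom] <- lam[pIdx, glom] * gA / aG
    lam[pIdx, hyp] <- lam[pIdx, hyp] * hB / aH
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam),
                     dimnames = dimnames(lam))
    rec <- data.frame(drug = rep(drugs, times = length(terms)),
                      adr_term = rep(terms, each = length(drugs)),
                      count = as.vector(counts))
    list(table = FrequencyTable(rec, termGroups = termGroups,
                                drugClass = drugs),
         truth = list(plantedDrug = f$plantedDrug,
                      plantedGroup = f$plantedGroup,
                      trueRor = f$trueRor, groupBRor = f$groupBRor))
  })
}

#' Generate a synthetic spectral-count matrix
#'
#' Poisson counts at `baselineMean` for every protein and replicate; a
#' planted fraction of proteins has treated-condition mean
#' `baselineMean * effectRatio` (default 0.165, the 20-to-3.3 contrast).  An
#' optional negative-binomial overdispersion knob is available
#' (`dispersion`; NULL keeps pure Poisson).
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `matrix` (a \linkS4class{SpectralCountMatrix}) and
#'   `truth` (character vector of planted protein identifiers).
#' @export
genSpectralCounts <- function(cfg) {
  p <- cfg$phospho
  withStream(cfg$rngSeed, .streams["phospho"], {
    nPlanted <- round(p$plantedFraction * p$nProteins)
    proteins <- sprintf("P%04d", seq_len(p$nProteins))
    planted <- proteins[seq_len(nPlanted)]
    draw <- function(n, mu) {
      if (is.null(p$dispersion)) stats::rpois(n, mu)
      else stats::rnbinom(n, size = 1 / p$dispersion, mu = mu)
    }
    nr <- p$nReplicates
    ctrl <- matrix(draw(p$nProteins * nr, p$baselineMean), p$nProteins)
    mu <- rep(p$baselineMean, p$nProteins)
    mu[seq_len(nPlanted)] <- p$baselineMean * p$effectRatio
    trt <- matrix(draw(p$nProteins * nr, rep(mu, nr)), p$nProteins)
    m <- cbind(ctrl, trt)
    rownames(m) <- proteins
    colnames(m) <- c(sprintf("ctrl_%d", seq_len(nr)),
                     sprintf("trt_%d", seq_len(nr)))
    list(matrix = SpectralCountMatrix(
           m, rep(c("control", "treated"), each = nr)),
         truth = planted)
  })
}

#' Generate a synthetic evidence-weighted interactome
#'
#' Erdos-Renyi background at the requested mean degree with integer evidence
#' drawn from `evidenceProbs` (support 1..length(evidenceProbs)).  The
#' planted seed set receives additional within-set edges at
#' `plantedDensity` times the background edge probability, plus
#' `plantedIntermediates` shared neighbor nodes each wired to 2-4 random
#' seeds; all planted edges carry evidence of at least 2 so they survive the
#' default evidence filter.  `plantedDensity = 1` with no planted
#' intermediates leaves the seed set statistically indistinguishable from a
#' random draw.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `interactome`, `seeds` (the planted set), and
#'   `universe` (all node identifiers, the detected-protein analog).
#' @export
genInteractome <- function(cfg) {
  nw <- cfg$network
  withStream(cfg$rngSeed, .streams["network"], {
    n <- nw$nNodes
    nodes <- sprintf("G%04d", seq_len(n))
    pEdge <- nw$meanDegree / (n - 1)
    nPairs <- n * (n - 1) / 2
    nEdges <- stats::rbinom(1, nPairs, pEdge)
    # sample unordered pairs uniformly (collisions deduplicated downstream)
    i <- sample.int(n, nEdges, replace = TRUE)
    j <- sample.int(n - 1, nEdges, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    ev <- sample.int(length(nw$evidenceProbs), nEdges, replace = TRUE,
                     prob = nw$evidenceProbs)
    a <- nodes[pmin(i, j)]; b <- nodes[pmax(i, j)]
    seeds <- sample(nodes, nw$plantedSeedSize)
    if (nw$plantedDensity > 1) {
      extraP <- min(1, (nw$plantedDensity - 1) * pEdge)
      sPairs <- utils::combn(seeds, 2)
      pick <- stats::runif(ncol(sPairs)) < extraP
      if (any(pick)) {
        evx <- sample(2:max(2, length(nw$evidenceProbs)), sum(pick),
                      replace = TRUE)
        a <- c(a, pmin(sPairs[1, pick], sPairs[2, pick]))
        b <- c(b, pmax(sPairs[1, pick], sPairs[2, pick]))
        ev <- c(ev, evx)
      }
    }
    if (nw$plantedIntermediates > 0) {
      pool <- setdiff(nodes, seeds)
      inter <- sample(pool, nw$plantedIntermediates)
      for (v in inter) {
        deg <- sample(2:4, 1)
        tgt <- sample(seeds, deg)
        a <- c(a, pmin(v, tgt)); b <- c(b, pmax(v, tgt))
        ev <- c(ev, sample(2:max(2, length(nw$evidenceProbs)), deg,
                           replace = TRUE))
      }
    }
    g <- Interactome(data.frame(node_a = a, node_b = b, evidence = ev))
    list(interactome = g, seeds = seeds, universe = nodes)
  })
}

#' Generate a synthetic kinome residual-activity panel
#'
#' Background kinase-drug residual activities are drawn from a truncated
#' normal well above the inhibition threshold (so no background kinase is
#' ever called inhibited); a configurable number of promiscuous kinases are
#' strongly inhibited by two to four drugs each; the planted kinase is
#' inhibited (residual 20-40 percent) under the planted drug only, and is a member
#' of the emitted actin gene set.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `matrix` (a \linkS4class{KinomeMatrix}), `geneSet` (the
#'   actin set containing the planted kinase), and `truth` (named pair, or
#'   NULL for a null scenario).
#' @export
genKinome <- function(cfg) {
  k <- cfg$kinome
  withStream(cfg$rngSeed, .streams["kinome"], {
    kin <- sprintf("K%03d", seq_len(k$nKinases))
    m <- matrix(rtruncnorm(k$nKinases * length(k$drugs), k$backgroundMean,
                           k$backgroundSd, k$backgroundMin, 120),
                k$nKinases, dimnames = list(kin, k$drugs))
    prom <- character()
    if (k$nPromiscuous > 0) {
      prom <- sample(setdiff(kin, k$plantedKinase), k$nPromiscuous)
      for (ki in prom) {
        dd <- sample(k$drugs, sample(2:4, 1))
        m[ki, dd] <- stats::runif(length(dd), 10, 45)
      }
    }
    planted <- NULL
    if (!is.null(k$plantedKinase) && !is.null(k$plantedDrug)) {
      if (!k$plantedKinase %in% kin)
        stop("planted kinase must belong to the panel")
      m[k$plantedKinase, ] <- rtruncnorm(length(k$drugs), k$backgroundMean,
                                         k$backgroundSd, k$backgroundMin, 120)
      m[k$plantedKinase, k$plantedDrug] <- stats::runif(1, 20, 40)
      planted <- stats::setNames(k$plantedDrug, k$plantedKinase)
    }
    members <- unique(c(k$plantedKinase,
                        sample(setdiff(kin, k$plantedKinase),
                               k$geneSetSize - !is.null(k$plantedKinase)),
                        sprintf("NONPANEL%02d", 1:5)))
    list(matrix = KinomeMatrix(m),
         geneSet = GeneSet("actin", members),
         truth = planted)
  })
}

#' Generate a grid of synthetic AFM approach curves
#'
#' Each pixel's curve is a zero-force baseline up to a per-curve contact
#' offset, followed by the pyramidal Hertz force law for the pixel's true
#' modulus (optionally with a depth-stiffening artifact
#' \eqn{E(\delta) = E_0 (1 + \gamma\delta)}), plus multiplicative and
#' additive Gaussian force noise.  Curves are emitted already converted to
#' (position, force); deflection-piezo conversion is out of scope.
#'
#' @param cfg a [scenarioConfig()]; the field is `afm$modulusField` (Pa
#'   matrix matching `gridShape`) or the homogeneous `afm$modulusPa`.
#' @return list with `curves` (row-major list of \linkS4class{ForceCurve}),
#'   `field` (true moduli, Pa), `nRows`, `nCols`, `spacing`.
#' @export
genForceCurves <- function(cfg) {
  a <- cfg$afm
  withStream(cfg$rngSeed, .streams["afm"], {
    nR <- a$gridShape[1]; nC <- a$gridShape[2]
    field <- if (is.null(a$modulusField))
      matrix(a$modulusPa, nR, nC) else a$modulusField
    stopifnot(all(dim(field) == c(nR, nC)))
    probe <- AfmProbe(a$springConstant, deg2rad(a$halfAngleDeg),
                      a$poissonRatio)
    curves <- vector("list", nR * nC)
    idx <- 1L
    for (r in seq_len(nR)) for (cc in seq_len(nC)) {
      z0 <- stats::runif(1, a$contactOffsetRange[1], a$contactOffsetRange[2])
      z <- seq(0, z0 + a$maxIndentation, by = a$dz)
      delta <- pmax(0, z - z0)
      E <- field[r, cc] * (1 + a$stiffeningPerMeter * delta)
      f <- hertzForce(delta, E, probe)
      if (a$forceNoiseFrac > 0 || a$forceNoiseSdAbs > 0)
        f <- f * (1 + stats::rnorm(length(f), 0, a$forceNoiseFrac)) +
          stats::rnorm(length(f), 0, a$forceNoiseSdAbs)
      curves[[idx]] <- ForceCurve(z, f, probe)
      idx <- idx + 1L
    }
    list(curves = curves, field = field, nRows = nR, nCols = nC,
         spacing = a$spacing)
  })
}

#' Generate a synthetic viability plate
#'
#' Replicate viabilities from the four-parameter logistic law with
#' multiplicative Gaussian noise (`noiseSd` percent relative error, the
#' usual repeatability figure for absorbance readouts), emitted on the raw
#' instrument scale together with vehicle-control wells so that the analysis
#' side must normalize.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with `plate` (data.frame `concentration`, `replicate`,
#'   `response`; concentration 0 marks vehicle wells) and `truth` (the 4PL
#'   parameters).
#' @export
genDoseResponse <- function(cfg) {
  d <- cfg$dose
  withStream(cfg$rngSeed, .streams["dose"], {
    conc <- rep(d$concentrations, each = d$nReplicates)
    v <- fourPL(conc, d$bottom, d$top, d$hill, log10(d$ec50))
    resp <- v * (1 + stats::rnorm(length(v), 0, d$noiseSd / 100)) / 100
    veh <- (1 + stats::rnorm(d$nVehicle, 0, d$noiseSd / 100))
    plate <- rbind(
      data.frame(concentration = 0, replicate = seq_len(d$nVehicle),
                 response = veh),
      data.frame(concentration = conc,
                 replicate = rep(seq_len(d$nReplicates),
                                 times = length(d$concentrations)),
                 response = resp))
    list(plate = plate,
         truth = list(bottom = d$bottom, top = d$top, hill = d$hill,
                      ec50 = d$ec50))
  })
}
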