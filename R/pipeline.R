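#' Run the full analysis chain on a synthetic scenario
#'
#' Generates every synthetic input from the scenario configuration and
#' executes the stages in dependency order: dual-ADR risk profiling,
#' differential phosphoproteomics, subnetwork specificity, kinome
#' filtering, elastography group comparison, and EC50 estimation.  Stage
#' errors are recorded in the report (with the dependent findings left
#' empty), not rethrown.
#'
#' Headline calls are deliberately stricter than the per-module defaults,
#' because the report makes one claim per stage rather than one test per
#' drug/protein/kinase: a dual-risk outlier must both exceed the
#' standardized-residual threshold *and* carry a group-A ROR whose lower
#' confidence limit exceeds 1 (the usual pharmacovigilance signal
#' criterion); the network-specificity and elasticity calls use
#' `headlineAlpha` (default 0.01); the differential-phosphoprotein headline
#' counts BH rejections, while the ranked seed list uses the raw-p selection.
#'
#' @param cfg a [scenarioConfig()].
#' @param outDir optional directory; when given, every stage writes its
#'   input/output files there and the report is emitted as JSON plus a
#'   Markdown summary.
#' @param stages character subset of
#'   `c("ror", "phospho", "network", "kinome", "afm", "dose")`.
#' @param flagThreshold standardized-residual threshold for the dual-risk
#'   profile (default 2).
#' @param headlineAlpha significance level for the report's headline claims
#'   (default 0.01).
#' @param nIterations Monte Carlo iterations for the network null.
#' @return A `PipelineReport` (list with `findings`, `stages`, `errors`,
#'   `provenance`).
#' @examples
#' \donttest{
#' rep <- runPipeline(scenarioConfig(rngSeed = 7,
#'   network = list(nNodes = 400, plantedSeedSize = 30)),
#'   nIterations = 99)
#' rep$findings$outlier_drugs
#' }
#' @export
runPipeline <- function(cfg, outDir = NULL,
                        stages = c("ror", "phospho", "network", "kinome",
                                   "afm", "dose"),
                        flagThreshold = 2, headlineAlpha = 0.01,
                        nIterations = 1000) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  findings <- list(); stageOut <- list(); errors <- list()
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      NULL
    } else {
      stageOut[[name]] <<- res
      res
    }
  }

  if ("ror" %in% stages) runStage("ror", function() {
    gen <- genFaers(cfg)
    prof <- dualRiskProfile(gen$table, "glomerular", "hypertension",
                            flagThreshold = flagThreshold)
    flagged <- prof$drug[prof$outlier & prof$std_residual > 0 &
                           prof$ci_low_a > 1]
    findings$outlier_drugs <<- flagged
    if (!is.null(outDir)) {
      writeFrequencyTable(gen$table, file.path(outDir, "faers_counts.csv"),
                          file.path(outDir, "faers_term_groups.csv"))
      utils::write.csv(prof, file.path(outDir, "dual_risk_profile.csv"),
                       row.names = FALSE)
    }
    list(profile = prof, truth = gen$truth)
  })

  if ("phospho" %in% stages) runStage("phospho", function() {
    gen <- genSpectralCounts(cfg)
    filt <- filterMinSupport(gen$matrix)
    res <- differentialTest(filt)
    sel <- selectDownregulated(res)
    findings$n_bh_down <<- sum(res$direction == "down")
    findings$n_selected <<- nrow(sel)
    findings$selected_proteins <<- sel$protein
    if (!is.null(outDir)) {
      writeSpectralCounts(gen$matrix,
                          file.path(outDir, "spectral_counts.tsv"),
                          file.path(outDir, "spectral_conditions.csv"))
      utils::write.table(res, file.path(outDir, "differential_results.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      writeLines(sel$protein, file.path(outDir, "seed_proteins.txt"))
    }
    list(results = res, selected = sel, truth = gen$truth)
  })

  if ("network" %in% stages) runStage("network", function() {
    gen <- genInteractome(cfg)
    sub <- expandSubnetwork(gen$interactome, gen$seeds)
    null <- monteCarloNull(gen$interactome, gen$universe,
                           length(gen$seeds), sub,
                           nIterations = nIterations,
                           seed = cfg$rngSeed + 104729L)
    findings$network_empirical_p <<- empiricalP(null)
    findings$network_specific <<- empiricalP(null) <= headlineAlpha
    if (!is.null(outDir)) {
      writeEdgeList(gen$interactome, file.path(outDir, "interactome.tsv"))
      writeEdgeList(Interactome(sub@edges),
                    file.path(outDir, "subnetwork_edges.tsv"))
      jsonlite::write_json(sub@metrics,
                           file.path(outDir, "subnetwork_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(sample = nullSamples(null)),
                       file.path(outDir, "network_null.csv"),
                       row.names = FALSE)
    }
    list(subnetwork = sub, null = null)
  })

  if ("kinome" %in% stages) runStage("kinome", function() {
    gen <- genKinome(cfg)
    chain <- filterGeneSet(filterActive(gen$matrix), gen$geneSet)
    uniq <- if (nrow(residualActivity(chain))) uniqueInhibition(chain)
            else stats::setNames(character(), character())
    findings$unique_inhibition <<- as.list(uniq)
    findings$mean_residual <<-
      if (nrow(residualActivity(chain))) as.list(meanResidual(chain))
      else list()
    if (!is.null(outDir)) {
      writeKinomeMatrix(gen$matrix, file.path(outDir, "kinome_panel.csv"))
      writeKinomeMatrix(chain, file.path(outDir, "kinome_filtered.csv"))
      jsonlite::write_json(list(unique_inhibition = as.list(uniq),
                                mean_residual = findings$mean_residual),
                           file.path(outDir, "kinome_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(filtered = chain, unique = uniq, truth = gen$truth)
  })

  if ("afm" %in% stages) runStage("afm", function() {
    a <- cfg$afm
    groups <- c(control = a$modulusPa, treated = a$treatedModulusPa)
    cellE <- withStream(cfg$rngSeed, .streams["afm"], {
      lapply(names(groups), function(gname) {
        exp(stats::rnorm(a$nCellsPerGroup, log(groups[[gname]]),
                         a$cellCvLog))
      })
    })
    names(cellE) <- names(groups)
    medians <- list()
    for (gname in names(groups)) {
      vals <- numeric(a$nCellsPerGroup)
      for (i in seq_len(a$nCellsPerGroup)) {
        ci <- cfg
        ci$rngSeed <- cfg$rngSeed + 7919L * i +
          1000003L * match(gname, names(groups))
        ci$afm$modulusPa <- cellE[[gname]][i]
        gen <- genForceCurves(ci)
        map <- suppressWarnings(
          assembleMap(gen$curves, gen$nRows, gen$nCols, gen$spacing))
        vals[i] <- stats::median(mapMatrix(map), na.rm = TRUE)
      }
      medians[[gname]] <- vals
    }
    cmp <- compareGroupElasticity(unlist(medians),
                                  rep(names(medians),
                                      lengths(medians)))
    reduced <- cmp$anova_p < headlineAlpha &&
      mean(medians$treated) < mean(medians$control)
    findings$elasticity_anova_p <<- cmp$anova_p
    findings$stiffness_reduced <<- reduced
    findings$median_E_control <<- stats::median(medians$control)
    findings$median_E_treated <<- stats::median(medians$treated)
    if (!is.null(outDir))
      utils::write.csv(data.frame(group = rep(names(medians),
                                              lengths(medians)),
                                  E_median = unlist(medians)),
                       file.path(outDir, "elasticity_per_cell.csv"),
                       row.names = FALSE)
    list(medians = medians, comparison = cmp)
  })

  if ("dose" %in% stages) runStage("dose", function() {
    d <- cfg$dose
    fits <- lapply(seq_len(d$nPlates), function(i) {
      ci <- cfg
      ci$rngSeed <- cfg$rngSeed + 7919L * i
      gen <- genDoseResponse(ci)
      fit4PL(normalizeViability(gen$plate))
    })
    summ <- summarizeEc50(fits)
    findings$ec50_geo_mean <<- summ$geo_mean
    findings$ec50_geo_sd <<- summ$geo_sd
    if (!is.null(outDir)) {
      gen <- genDoseResponse(cfg)
      utils::write.csv(gen$plate, file.path(outDir, "viability_plate.csv"),
                       row.names = FALSE)
      jsonlite::write_json(summ, file.path(outDir, "ec50_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(fits = fits, summary = summ)
  })

  report <- structure(
    list(findings = findings, stages = stageOut, errors = errors,
         provenance = list(
           seed = cfg$rngSeed,
           config = unclass(cfg),
           package_version = as.character(utils::packageVersion("nephrosig")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "PipelineReport")
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' @rdname runPipeline
#' @param report a PipelineReport.
#' @param dir output directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- unclass(report)
  ser$stages <- NULL  # S4 stage objects live in their own files
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  f <- report$findings
  lines <- c("# Pipeline report", "",
             sprintf("- seed: %d", report$provenance$seed),
             sprintf("- package: nephrosig %s",
                     report$provenance$package_version), "",
             "## Headline findings", "",
             sprintf("- dual-risk outlier drugs: %s",
                     if (length(f$outlier_drugs))
                       paste(f$outlier_drugs, collapse = ", ") else "none"),
             sprintf("- BH-significant down-regulated proteins: %s",
                     f$n_bh_down %||% "not run"),
             sprintf("- selected seed proteins: %s",
                     f$n_selected %||% "not run"),
             sprintf("- network specificity: empirical p = %s (specific: %s)",
                     fmtOr(f$network_empirical_p), f$network_specific %||% "not run"),
             sprintf("- uniquely inhibited kinases: %s",
                     if (length(f$unique_inhibition))
                       paste(sprintf("%s by %s", names(f$unique_inhibition),
                                     unlist(f$unique_inhibition)),
                             collapse = ", ") else "none"),
             sprintf("- stiffness reduced in treated group: %s (ANOVA p = %s)",
                     f$stiffness_reduced %||% "not run",
                     fmtOr(f$elasticity_anova_p)),
             sprintf("- EC50 geometric mean: %s nM (geo SD %s)",
                     fmtOr(f$ec50_geo_mean), fmtOr(f$ec50_geo_sd)))
  if (length(report$errors))
    lines <- c(lines, "", "## Stage errors", "",
               sprintf("- %s: %s", names(report$errors),
                       unlist(report$errors)))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(file.path(dir, "report.json"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
fmtOr <- function(x) if (is.null(x)) "not run" else sprintf("%.4g", x)

#' @export
print.PipelineReport <- function(x, ...) {
  f <- x$findings
  cat("PipelineReport (seed", x$provenance$seed, ")\n")
  cat("  outlier drugs:",
      if (length(f$outlier_drugs)) paste(f$outlier_drugs, collapse = ", ")
      else "none", "\n")
  if (!is.null(f$n_selected))
    cat("  selected proteins:", f$n_selected,
        "(BH down:", f$n_bh_down, ")\n")
  if (!is.null(f$network_empirical_p))
    cat(sprintf("  network empirical p: %.4g\n", f$network_empirical_p))
  if (!is.null(f$unique_inhibition))
    cat("  unique inhibition:",
        if (length(f$unique_inhibition))
          paste(sprintf("%s by %s", names(f$unique_inhibition),
                        unlist(f$unique_inhibition)), collapse = ", ")
        else "none", "\n")
  if (!is.null(f$elasticity_anova_p))
    cat(sprintf("  elasticity ANOVA p: %.4g (reduced: %s)\n",
                f$elasticity_anova_p, f$stiffness_reduced))
  if (!is.null(f$ec50_geo_mean))
    cat(sprintf("  EC50: %.4g nM (geo SD %.3g)\n", f$ec50_geo_mean,
                f$ec50_geo_sd))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
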