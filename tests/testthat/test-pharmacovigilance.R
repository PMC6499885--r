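makeTable <- function() {
  FrequencyTable(
    data.frame(drug = rep(c("a", "b"), each = 2),
               adr_term = rep(c("t1", "t2"), 2),
               count = c(5, 95, 50, 950)),
    termGroups = c(t1 = "glomerular"))
}

test_that("contingency cells are direct sums over the term group", {
  cc <- buildContingency(makeTable(), "a", "glomerular")
  expect_equal(cc@fDt, 5)
  expect_equal(cc@fDn, 95)
  expect_equal(cc@fNt, 50)
  expect_equal(cc@fNn, 950)
  expect_error(buildContingency(makeTable(), "zzz", "glomerular"),
               "not in the drug class")
  expect_error(buildContingency(makeTable(), "a", "renal"), "maps no terms")
})

test_that("contingency sums agree with a brute-force tally on synthetic tables", {
  gen <- genFaers(scenarioConfig(rngSeed = 21))
  rec <- records(gen$table)
  terms <- names(termGroups(gen$table))[termGroups(gen$table) == "glomerular"]
  for (d in c("drug01", "drug05")) {
    cc <- buildContingency(gen$table, d, "glomerular")
    tally <- c(sum(rec$count[rec$drug == d & rec$adr_term %in% terms]),
               sum(rec$count[rec$drug == d & !rec$adr_term %in% terms]),
               sum(rec$count[rec$drug != d & rec$adr_term %in% terms]),
               sum(rec$count[rec$drug != d & !rec$adr_term %in% terms]))
    expect_equal(c(cc@fDt, cc@fDn, cc@fNt, cc@fNn), tally)
  }
})

test_that("ROR, SE and CI follow the disproportionality formulas", {
  r <- computeRor(ContingencyCounts(5, 95, 50, 950))
  expect_equal(r@ror, 1)
  expect_lt(r@ciLow, 1); expect_gt(r@ciHigh, 1)

  r2 <- computeRor(ContingencyCounts(10, 990, 100, 98900))
  expect_equal(r2@ror, 9.98989898989899, tolerance = 1e-12)
  expect_equal(r2@ciLow, 5.19921912236156, tolerance = 1e-10)
  expect_equal(r2@ciHigh, 19.1948212759795, tolerance = 1e-10)
  expect_false(r2@corrected)
})

test_that("zero cells get the Haldane-Anscombe correction or a named error", {
  r <- computeRor(ContingencyCounts(0, 100, 50, 9950))
  expect_true(r@corrected)
  expect_equal(r@ror, 0.980296537116398, tolerance = 1e-12)
  expect_error(computeRor(ContingencyCounts(0, 100, 50, 9950),
                          correction = "none"), "fDt")
})

test_that("ROR matches an independent direct evaluation on random tables", {
  set.seed(101)
  for (i in 1:200) {
    cc <- randomContingency()
    o <- oracleRor(cc@fDt, cc@fDn, cc@fNt, cc@fNn)
    r <- computeRor(cc)
    expect_equal(r@ror, o$ror, tolerance = 1e-12)
    expect_equal(r@seLogRor, o$se, tolerance = 1e-12)
    expect_equal(r@ciLow, o$lo, tolerance = 1e-12)
    expect_equal(r@ciHigh, o$hi, tolerance = 1e-12)
  }
})

test_that("ROR is invariant to uniform cell scaling and inverts on swap", {
  set.seed(7)
  for (i in 1:20) {
    cc <- randomContingency()
    scaled <- ContingencyCounts(cc@fDt * 3, cc@fDn * 3, cc@fNt * 3, cc@fNn * 3)
    expect_equal(computeRor(scaled)@ror, computeRor(cc)@ror,
                 tolerance = 1e-12)
    swapped <- ContingencyCounts(cc@fNt, cc@fNn, cc@fDt, cc@fDn)
    expect_equal(computeRor(cc)@ror * computeRor(swapped)@ror, 1,
                 tolerance = 1e-12)
  }
})

test_that("drug ranking orders by ROR with alphabetical ties", {
  rec <- expand.grid(drug = c("b", "a", "c"), adr_term = c("t1", "t2"),
                     stringsAsFactors = FALSE)
  rec$count <- rep(c(10, 90), each = 3)
  tab <- FrequencyTable(rec, termGroups = c(t1 = "g"))
  rk <- rankDrugs(tab, "g")
  expect_equal(rk$ror, rep(1, 3))
  expect_equal(rk$drug, c("a", "b", "c"))
})

test_that("a planted high-ROR drug ranks first", {
  hits <- vapply(1:20, function(s) {
    gen <- genFaers(scenarioConfig(rngSeed = 300 + s))
    rankDrugs(gen$table, "glomerular")$drug[1] == "drug01"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a drug with zero group reports carries a corrected result only", {
  rec <- expand.grid(drug = c("a", "b", "c"), adr_term = c("t1", "t2"),
                     stringsAsFactors = FALSE)
  rec$count <- c(0, 10, 12, 100, 90, 95)
  tab <- FrequencyTable(rec, termGroups = c(t1 = "g"))
  rk <- rankDrugs(tab, "g")
  expect_true(rk$corrected[rk$drug == "a"])
  expect_false(any(rk$corrected[rk$drug != "a"]))
})

test_that("dual-risk residuals vanish on an exact log-log line", {
  drugs <- sprintf("d%02d", 1:6)
  rr <- exp(seq(-1, 1, length.out = 6))
  rec <- data.frame()
  # two groups with per-drug rates on a common trend; a third term block
  # keeps the denominators large so sampled RORs are nearly exact
  n <- 1e6
  for (i in seq_along(drugs)) {
    rec <- rbind(rec,
      data.frame(drug = drugs[i], adr_term = c("g1", "h1", "o1"),
                 count = round(c(rr[i] * 1000, rr[i] * 2000, n))))
  }
  tab <- FrequencyTable(rec, termGroups = c(g1 = "ga", h1 = "gb"))
  prof <- dualRiskProfile(tab, "ga", "gb")
  expect_false(any(prof$outlier))
  expect_lt(max(abs(prof$residual)), 0.01)
})

test_that("a drug displaced in one group only is the one flagged", {
  drugs <- sprintf("d%02d", 1:8)
  rr <- exp(seq(-0.6, 0.6, length.out = 8))
  rec <- data.frame()
  for (i in seq_along(drugs)) {
    gl <- if (i == 3) rr[i] * 1000 * 8 else rr[i] * 1000
    rec <- rbind(rec,
      data.frame(drug = drugs[i], adr_term = c("g1", "h1", "o1"),
                 count = round(c(gl, rr[i] * 2000, 1e6))))
  }
  tab <- FrequencyTable(rec, termGroups = c(g1 = "ga", h1 = "gb"))
  prof <- dualRiskProfile(tab, "ga", "gb")
  expect_identical(prof$drug[prof$outlier], "d03")
})

test_that("the dual-risk trend line requires at least four usable drugs", {
  rec <- expand.grid(drug = c("a", "b", "c"), adr_term = c("t1", "t2", "t3"),
                     stringsAsFactors = FALSE)
  rec$count <- 50
  tab <- FrequencyTable(rec, termGroups = c(t1 = "ga", t2 = "gb"))
  expect_error(dualRiskProfile(tab, "ga", "gb"), "at least 4 drugs")
})

test_that("planted dual-risk scenarios flag the planted drug end to end", {
  hits <- vapply(1:20, function(s) {
    gen <- genFaers(scenarioConfig(rngSeed = 500 + s))
    prof <- dualRiskProfile(gen$table, "glomerular", "hypertension")
    isTRUE(prof$outlier[prof$drug == "drug01"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
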