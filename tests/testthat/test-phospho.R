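smallMatrix <- function(counts, nr = 3) {
  SpectralCountMatrix(counts, rep(c("control", "treated"), each = nr))
}

test_that("minimum-support filter applies the per-condition sum rule", {
  m <- rbind(A = c(3, 2, 2, 0, 1, 0),   # treated sum 1 < 2 -> dropped
             B = c(2, 0, 0, 2, 0, 0),   # both sums exactly 2 -> kept
             C = c(5, 5, 5, 5, 5, 5))
  filt <- filterMinSupport(smallMatrix(m))
  expect_setequal(rownames(spectralCounts(filt)), c("B", "C"))
})

test_that("sum-mode filter equals a brute-force double-sum scan", {
  set.seed(11)
  m <- matrix(rpois(500 * 6, 1.2), 500,
              dimnames = list(sprintf("P%03d", 1:500), NULL))
  filt <- filterMinSupport(smallMatrix(m))
  keep <- apply(m, 1, function(x) sum(x[1:3]) >= 2 && sum(x[4:6]) >= 2)
  expect_identical(rownames(spectralCounts(filt)), names(keep)[keep])
})

test_that("per-replicate support mode requires every replicate to qualify", {
  m <- rbind(A = c(2, 2, 2, 2, 2, 1), B = c(2, 2, 2, 2, 2, 2))
  filt <- filterMinSupport(smallMatrix(m), mode = "per-replicate")
  expect_identical(rownames(spectralCounts(filt)), "B")
  expect_warning(filterMinSupport(smallMatrix(m * 0)), "no protein passes")
})

test_that("per-protein tests agree with stats::t.test row by row", {
  set.seed(12)
  m <- matrix(rpois(50 * 8, 15), 50)
  x <- smallMatrix(m, nr = 4)
  for (ve in c(TRUE, FALSE)) {
    res <- differentialTest(x, varEqual = ve)
    for (i in c(1, 7, 23, 50)) {
      tt <- t.test(m[i, 1:4], m[i, 5:8], var.equal = ve)
      expect_equal(res$t_statistic[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
      expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-8)
    }
  }
})

test_that("degenerate rows follow the documented conventions", {
  m <- rbind(same = c(4, 4, 4, 4, 4, 4), diff = c(4, 4, 4, 7, 7, 7))
  res <- differentialTest(smallMatrix(m))
  expect_equal(res$t_statistic[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$p_value[2], 0)  # zero variance, unequal means
})

test_that("the published paxillin-scale contrast gives t of about 11.48", {
  s <- tFromSummary(18.7, 1.2, 3, 3.3, 0.6, 3)
  expect_equal(s$t, 11.4784822844989, tolerance = 1e-10)
  expect_lt(s$p, 0.01)
})

test_that("null count matrices yield uniform p-values", {
  set.seed(13)
  cfg <- scenarioConfig(rngSeed = 14,
                        phospho = list(nProteins = 600L, plantedFraction = 0))
  gen <- genSpectralCounts(cfg)
  res <- differentialTest(gen$matrix)
  expect_gt(suppressWarnings(ks.test(res$p_value, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches p.adjust examples and rejects bad input", {
  expect_equal(bhAdjust(0.01)$q_values, 0.01)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04))$q_values, rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5))$q_values, rep(0.2, 5))
  expect_error(bhAdjust(c(0.1, NA)), "NA")
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH q-values equal the brute-force step-up definition", {
  set.seed(15)
  for (i in 1:200) {
    p <- runif(sample(3:80, 1))
    expect_identical(bhAdjust(p)$q_values, bruteBH(p))
  }
})

test_that("down-regulated selection ranks by p then |t| then identifier", {
  res <- data.frame(protein = c("b", "a", "c", "d"),
                    mean_control = c(10, 10, 10, 10),
                    mean_treated = c(2, 2, 2, 20),
                    t_statistic = c(3, 5, 3, -4),
                    p_value = c(0.01, 0.01, 0.01, 0.001),
                    stringsAsFactors = FALSE)
  sel <- selectDownregulated(res, topN = 3)
  expect_equal(sel$protein, c("a", "b", "c"))  # d is up-regulated
  expect_warning(selectDownregulated(res, topN = 10), "only 3")
})

test_that("planted down-regulation is recovered at the study scale", {
  gen <- genSpectralCounts(scenarioConfig(rngSeed = 16))
  res <- differentialTest(filterMinSupport(gen$matrix))
  sel <- selectDownregulated(res)
  expect_equal(nrow(sel), 76)
  expect_gte(mean(gen$truth %in% sel$protein), 0.8)
})

test_that("filtering then testing equals testing then masking", {
  set.seed(17)
  m <- matrix(rpois(300 * 6, 3), 300,
              dimnames = list(sprintf("P%03d", 1:300), NULL))
  x <- smallMatrix(m)
  filtered <- differentialTest(filterMinSupport(x))
  full <- differentialTest(x)
  masked <- full[full$protein %in% filtered$protein, ]
  expect_equal(filtered$t_statistic, masked$t_statistic)
  expect_equal(filtered$p_value, masked$p_value)
})
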