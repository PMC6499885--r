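test_that("the pyramidal Hertz force law evaluates the Bilodeau constant", {
  expect_equal(hertzForce(1e-6, 1000, AfmProbe()) * 1e9,
               0.660161998008032, tolerance = 1e-12)
  expect_equal(hertzForce(-1e-7, 1000, AfmProbe()), 0)
  # linearity in E: doubling the modulus doubles the force
  expect_equal(hertzForce(2e-6, 2000, AfmProbe()),
               2 * hertzForce(2e-6, 1000, AfmProbe()))
})

test_that("noiseless curves invert exactly: contact, modulus, profile", {
  set.seed(80)
  for (z0 in c(0.25e-6, 0.5e-6, 0.77e-6)) {
    cv <- referenceCurve(z0, 8e3)
    r <- analyzeForceCurve(cv)
    dz <- cv@z[2] - cv@z[1]
    expect_lt(abs(r@contactPoint - z0), dz)          # within one spacing
    expect_lt(abs(r@eFit / 8e3 - 1), 1e-3)
    expect_gt(r@fitR2, 0.9999)
    # pointwise profile constant and consistent with the fit
    expect_lt(diff(range(r@pointwiseE)) / 8e3, 1e-3)
    expect_lt(abs(r@eMedian / r@eFit - 1), 1e-3)
    expect_equal(r@eMedian, median(r@pointwiseE))
    expect_false(r@substrateFlag)
  }
})

test_that("a pure-baseline curve raises a no-contact error", {
  z <- seq(0, 4.5e-6, by = 20e-9)
  expect_error(detectContactPoint(ForceCurve(z, rep(0, length(z)))),
               "no contact")
})

test_that("force units propagate linearly to moduli", {
  cv <- referenceCurve(0.4e-6, 5e3)
  cv10 <- ForceCurve(cv@z, cv@force * 10, cv@probe)
  r <- analyzeForceCurve(cv); r10 <- analyzeForceCurve(cv10)
  expect_equal(r10@eFit / r@eFit, 10, tolerance = 1e-6)
  expect_equal(r10@eMedian / r@eMedian, 10, tolerance = 1e-6)
})

test_that("modulus recovery stays within 10 percent under 5 percent noise", {
  set.seed(81)
  errs <- vapply(1:30, function(i) {
    cv <- referenceCurve(runif(1, 0.2e-6, 0.8e-6), 1e4, noiseFrac = 0.05)
    abs(analyzeForceCurve(cv)@eFit / 1e4 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("depth-stiffening artifacts are flagged, clean curves are not", {
  set.seed(82)
  flags <- vapply(1:5, function(i) {
    cv <- referenceCurve(runif(1, 0.2e-6, 0.8e-6), 1e4, gamma = 1e6)
    analyzeForceCurve(cv)@substrateFlag
  }, logical(1))
  expect_true(all(flags))
  clean <- vapply(1:5, function(i) {
    cv <- referenceCurve(runif(1, 0.2e-6, 0.8e-6), 1e4, noiseFrac = 0.05)
    analyzeForceCurve(cv)@substrateFlag
  }, logical(1))
  expect_false(any(clean))
})

test_that("maps preserve grid order, flag missing pixels, reject mismatches", {
  gen <- genForceCurves(scenarioConfig(rngSeed = 83,
    afm = list(gridShape = c(2L, 3L))))
  map <- assembleMap(gen$curves, 2, 3, gen$spacing)
  expect_equal(dim(mapMatrix(map)), c(2, 3))
  expect_lt(max(abs(mapMatrix(map) / 1e4 - 1)), 1e-3)
  expect_error(assembleMap(gen$curves, 2, 2), "does not match")
  # a flat curve cannot be analyzed -> missing pixel, not an error
  broken <- gen$curves
  broken[[3]] <- ForceCurve(broken[[3]]@z, rep(0, length(broken[[3]]@z)),
                            broken[[3]]@probe)
  expect_warning(map2 <- assembleMap(broken, 2, 3, gen$spacing), "missing")
  expect_true(is.na(mapMatrix(map2)[1, 3]))
})

test_that("a planted stiff ridge stands out against the background", {
  field <- matrix(5e3, 6, 6)
  field[3, ] <- 2e4
  gen <- genForceCurves(scenarioConfig(rngSeed = 84,
    afm = list(gridShape = c(6L, 6L), modulusField = field,
               forceNoiseFrac = 0.05)))
  m <- mapMatrix(assembleMap(gen$curves, 6, 6, gen$spacing))
  expect_true(all(m[3, ] > quantile(m[-3, ], 0.95)))
  expect_equal(unname(which.max(rowMeans(m))), 3)
})

test_that("group comparison detects softer treated cells and not null ones", {
  set.seed(85)
  ctrl <- exp(rnorm(20, log(1e4), 0.3))
  trt <- exp(rnorm(20, log(3e3), 0.3))
  cmp <- compareGroupElasticity(c(ctrl, trt),
                                rep(c("control", "treated"), each = 20))
  expect_lt(cmp$anova_p, 0.01)
  expect_lt(cmp$tukey$`p adj`[1], 0.01)
  same <- compareGroupElasticity(c(ctrl, ctrl),
                                 rep(c("a", "b"), each = 20))
  expect_gt(same$anova_p, 0.5)
  expect_error(compareGroupElasticity(ctrl, rep("a", 20)), "two groups")
  expect_error(compareGroupElasticity(c(1, 2, 3, 4),
                                      c("a", "a", "a", "b")), "three cells")
})
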