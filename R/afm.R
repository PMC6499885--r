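#' @rdname ForceCurve
#' @param springConstant cantilever spring constant, N/m.
#' @param halfAngle pyramidal tip half-angle, radians (use [deg2rad()] for
#'   degrees; default 35 degrees).
#' @param poissonRatio sample Poisson ratio (0.5 = incompressible).
#' @export
AfmProbe <- function(springConstant = 0.1, halfAngle = deg2rad(35),
                     poissonRatio = 0.5) {
  new("AfmProbe", springConstant = springConstant, halfAngle = halfAngle,
      poissonRatio = poissonRatio)
}

#' @rdname ForceCurve
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Construct a ForceCurve
#'
#' @param z tip-sample positions in meters, non-decreasing into the cell.
#' @param force measured forces in Newtons.
#' @param probe an \linkS4class{AfmProbe}.
#' @return A \linkS4class{ForceCurve}.
#' @export
ForceCurve <- function(z, force, probe = AfmProbe()) {
  new("ForceCurve", z = as.numeric(z), force = as.numeric(force),
      probe = probe)
}

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve: %d samples, z %.3g-%.3g um, max force %.3g nN (k = %.3g N/m)\n",
              length(object@z), min(object@z) * 1e6, max(object@z) * 1e6,
              max(object@force) * 1e9, object@probe@springConstant))
})

# Geometry coefficient of the four-sided pyramidal indenter:
# F = tan(theta)/sqrt(2) * E/(1 - nu^2) * delta^2.
pyramidCoefficient <- function(probe)
  tan(probe@halfAngle) / sqrt(2) / (1 - probe@poissonRatio^2)

#' Pyramidal Hertzian force law
#'
#' Forward contact-mechanics model for a four-sided pyramidal indenter:
#' \deqn{F(\delta) = \frac{\tan\theta}{\sqrt 2}\,\frac{E}{1-\nu^2}\,\delta^2}
#' with indentation depth \eqn{\delta} (m), elastic modulus `E` (Pa), tip
#' half-angle \eqn{\theta} and Poisson ratio \eqn{\nu} from the probe.
#'
#' @param delta indentation depth(s) in meters; negative depths give zero
#'   force.
#' @param E elastic modulus in Pa.
#' @param probe an \linkS4class{AfmProbe}.
#' @return force(s) in Newtons.
#' @examples
#' hertzForce(1e-6, 1000, AfmProbe()) * 1e9  # ~0.66 nN
#' @export
hertzForce <- function(delta, E, probe = AfmProbe())
  ifelse(delta > 0, pyramidCoefficient(probe) * E * delta^2, 0)

#' Detect the contact point of an approach curve
#'
#' Three-stage detection.  (1) Coarse grid search: every sample is tried as
#' the contact point, with the pre-candidate mean as force baseline and a
#' least-squares pyramidal Hertz fit to the whole post-candidate segment;
#' the candidate with the smallest total squared residual wins.  (2) Kink
#' localization: near the coarse optimum, the last sample whose force still
#' sits inside the baseline noise band marks the transition out of the
#' baseline regime.  (3) Continuous refinement between the neighboring
#' samples of that kink, minimizing the mean squared residual of a local
#' two-regime fit (flat baseline before, Hertz parabola after) within a
#' small symmetric window.  The refinement is capped at one sample past the
#' kink, so slow super-quadratic force growth at depth (a substrate
#' artifact) cannot drag the contact point inward -- the contact point is a
#' geometric feature of the touch, not a free parameter of the deep fit.
#'
#' A curve with no detectable contact (forces never rising above the
#' baseline noise band) is an error.
#'
#' @param curve a \linkS4class{ForceCurve} including a pre-contact baseline.
#' @param minBaseline minimum number of pre-contact samples (default 5).
#' @param minPost minimum number of post-contact samples (default 10).
#' @param fitWindow half-width (m) of the symmetric window used by the local
#'   refinement (default 250 nm).
#' @return the contact position z0 in meters, with attributes `index` (the
#'   nearest sample) and `baseline` (N).
#' @export
detectContactPoint <- function(curve, minBaseline = 5, minPost = 10,
                               fitWindow = 2.5e-7) {
  z <- curve@z; f <- curve@force; n <- length(z)
  cand <- seq.int(minBaseline, n - minPost)
  if (!length(cand)) stop("no candidate contact point leaves ", minPost,
                          " post-contact samples")
  nb <- max(3L, floor(n / 4))
  baseSd <- stats::sd(f[seq_len(nb)])
  if (max(f) <= mean(f[seq_len(nb)]) + 10 * baseSd)
    stop("no contact detected: forces never leave the baseline noise band")
  # stage 1: coarse grid search over the whole post-candidate segment
  rss <- vapply(cand, function(i) {
    b <- mean(f[1:i])
    post <- (i + 1):n
    d2 <- (z[post] - z[i])^2
    fp <- f[post] - b
    cE <- max(0, sum(fp * d2) / sum(d2 * d2))
    sum((f[1:i] - b)^2) + sum((fp - cE * d2)^2)
  }, numeric(1))
  i1 <- cand[which.min(rss)]
  # stage 2: kink localization by baseline walk -- extend the baseline
  # sample by sample until the force breaks out of its noise band
  floorAbs <- 1e-6 * (max(f) - min(f))
  iK <- i1
  j <- minBaseline
  while (j < n - minPost) {
    b <- mean(f[1:j]); s <- stats::sd(f[1:j])
    if (f[j + 1L] > b + max(5 * s, floorAbs)) break
    j <- j + 1L
  }
  if (j > minBaseline && j < n - minPost) iK <- j
  # stage 3: continuous refinement, capped one sample past the kink
  objective <- function(z0) {
    pre <- which(z >= z0 - fitWindow & z <= z0)
    post <- which(z > z0 & z <= z0 + fitWindow)
    if (length(pre) < 2L || length(post) < 2L) return(.Machine$double.xmax)
    b <- mean(f[pre])
    d2 <- (z[post] - z0)^2
    fp <- f[post] - b
    cE <- max(0, sum(fp * d2) / sum(d2 * d2))
    (sum((f[pre] - b)^2) + sum((fp - cE * d2)^2)) /
      (length(pre) + length(post))
  }
  lo <- z[max(iK - 2L, 1L)]; hi <- z[min(iK + 1L, n)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-13)
  gridIdx <- seq.int(max(iK - 2L, 1L), min(iK + 1L, n))
  gridMse <- vapply(z[gridIdx], objective, numeric(1))
  z0 <- if (opt$objective <= min(gridMse)) opt$minimum
        else z[gridIdx[which.min(gridMse)]]
  structure(z0, index = iK, baseline = mean(f[z <= z0]))
}

#' Fit the pyramidal Hertz model beyond a known contact point
#'
#' Least-squares fit of \eqn{F = (\tan\theta/\sqrt2)\,E/(1-\nu^2)\,\delta^2}
#' over the post-contact segment (\eqn{\delta = z - z_0 > 0}), after removing
#' the pre-contact baseline force.  The modulus is constrained non-negative
#' (the model is linear in E, so the constrained optimum is the clamped
#' unconstrained one).
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param z0 contact position (m), e.g. from [detectContactPoint()].
#' @return list with `E_fit` (Pa), `fit_r2`, and `baseline` (N).
#' @export
hertzFit <- function(curve, z0) {
  z <- curve@z; f <- curve@force
  pre <- z <= z0
  b <- if (any(pre)) mean(f[pre]) else 0
  post <- which(z > z0)
  if (length(post) < 2L) stop("degenerate post-contact range")
  d2 <- (z[post] - z0)^2
  if (max(d2) == 0) stop("degenerate post-contact range")
  fp <- f[post] - b
  coef <- pyramidCoefficient(curve@probe)
  cE <- max(0, sum(fp * d2) / sum(d2 * d2))
  fitted <- cE * d2
  tss <- sum((fp - mean(fp))^2)
  r2 <- if (tss > 0) 1 - sum((fp - fitted)^2) / tss else 1
  list(E_fit = cE / coef, fit_r2 = r2, baseline = b)
}

#' Depth-dependent pointwise apparent modulus
#'
#' Inverts the pyramidal Hertz law sample by sample,
#' \eqn{E(\delta_i) = F_i (1-\nu^2) \sqrt2 / (\tan\theta\, \delta_i^2)}, for
#' depths beyond `deltaMin`, and summarizes the profile by its median (the
#' homogenized cellular elasticity).  A rising depth trend marks substrate
#' stiffening: the least-squares slope of \eqn{E(\delta)} against
#' \eqn{\delta}, normalized by the median, is compared to
#' `relSlopePerMicron`.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param z0 contact position (m).
#' @param deltaMin minimum depth entering the profile (m, default 100 nm;
#'   shallow samples are dominated by contact-point error).
#' @param relSlopePerMicron relative stiffening threshold per micron of depth
#'   (default 0.2, i.e. a rise of 20 percent per micron flags the curve).
#' @return list with `delta` (m), `E` (Pa), `E_median` (Pa),
#'   `substrate_flag`, and `rel_slope_per_micron`.
#' @export
pointwiseModulus <- function(curve, z0, deltaMin = 100e-9,
                             relSlopePerMicron = 0.2) {
  z <- curve@z; f <- curve@force
  pre <- z <= z0
  b <- if (any(pre)) mean(f[pre]) else 0
  delta <- z - z0
  keep <- delta >= deltaMin
  if (!any(keep)) stop("no samples at depth >= deltaMin")
  delta <- delta[keep]
  E <- (f[keep] - b) / (pyramidCoefficient(curve@probe) * delta^2)
  eMed <- stats::median(E)
  relSlope <- if (length(delta) > 2 && stats::var(delta) > 0 && eMed > 0)
    unname(stats::coef(stats::lm(E ~ delta))[2]) / eMed * 1e-6
  else 0
  list(delta = delta, E = E, E_median = eMed,
       substrate_flag = relSlope > relSlopePerMicron,
       rel_slope_per_micron = relSlope)
}

#' Analyze one force curve end to end
#'
#' Contact-point detection, Hertz fit, and pointwise-modulus profile combined
#' into one \linkS4class{ElasticityResult}.
#'
#' @inheritParams pointwiseModulus
#' @inheritParams detectContactPoint
#' @return An \linkS4class{ElasticityResult}.
#' @export
analyzeForceCurve <- function(curve, deltaMin = 100e-9,
                              relSlopePerMicron = 0.2,
                              minBaseline = 5, minPost = 10) {
  z0 <- detectContactPoint(curve, minBaseline, minPost)
  fit <- hertzFit(curve, as.numeric(z0))
  pw <- pointwiseModulus(curve, as.numeric(z0), deltaMin, relSlopePerMicron)
  new("ElasticityResult", contactPoint = as.numeric(z0), eFit = fit$E_fit,
      fitR2 = fit$fit_r2, pointwiseDelta = pw$delta, pointwiseE = pw$E,
      eMedian = pw$E_median, substrateFlag = pw$substrate_flag,
      substrateSlope = pw$rel_slope_per_micron)
}

setMethod("show", "ElasticityResult", function(object) {
  cat(sprintf("ElasticityResult: z0 = %.3g um, E_fit = %.4g Pa (r2 = %.4f), E_median = %.4g Pa%s\n",
              object@contactPoint * 1e6, object@eFit, object@fitR2,
              object@eMedian,
              if (object@substrateFlag) "  [substrate artifact]" else ""))
})

#' Assemble an elastography map from a grid of curves
#'
#' Analyzes each curve of a row-major grid; curves that fail (no contact,
#' degenerate fits) become missing pixels with a warning, never interpolated.
#'
#' @param curves list of \linkS4class{ForceCurve}s in row-major grid order.
#' @param nRows,nCols grid shape; `nRows * nCols` must equal the curve count.
#' @param spacing pixel pitch in meters.
#' @param ... passed to [analyzeForceCurve()].
#' @return An \linkS4class{ElastographyMap}.
#' @export
assembleMap <- function(curves, nRows, nCols, spacing = 4e-6, ...) {
  if (length(curves) != nRows * nCols)
    stop("grid shape ", nRows, "x", nCols, " does not match ",
         length(curves), " curves")
  results <- lapply(curves, function(cv)
    tryCatch(analyzeForceCurve(cv, ...), error = function(e) NULL))
  nFail <- sum(vapply(results, is.null, logical(1)))
  if (nFail) warning(nFail, " pixel(s) could not be analyzed and are missing")
  new("ElastographyMap", nRows = as.integer(nRows), nCols = as.integer(nCols),
      spacing = spacing, results = results)
}

#' @rdname assembleMap
#' @param x an ElastographyMap.
#' @param value which per-pixel value to extract (`"eMedian"`, `"eFit"`,
#'   `"contactPoint"`, `"fitR2"`).
#' @return `mapMatrix` returns a numeric `nRows x nCols` matrix with NA for
#'   missing pixels.
#' @export
mapMatrix <- function(x, value = c("eMedian", "eFit", "contactPoint",
                                   "fitR2")) {
  value <- match.arg(value)
  v <- vapply(x@results, function(r)
    if (is.null(r)) NA_real_ else slot(r, value), numeric(1))
  matrix(v, nrow = x@nRows, ncol = x@nCols, byrow = TRUE)
}

setMethod("show", "ElastographyMap", function(object) {
  m <- mapMatrix(object)
  cat(sprintf("ElastographyMap: %d x %d pixels at %.3g um pitch; median E = %.4g Pa (%d missing)\n",
              object@nRows, object@nCols, object@spacing * 1e6,
              stats::median(m, na.rm = TRUE), sum(is.na(m))))
})

#' Compare cellular elasticity across treatment groups
#'
#' One-way ANOVA on per-cell median moduli with Tukey HSD post-hoc pairwise
#' comparisons.
#'
#' @param values numeric vector of per-cell `E_median` values (Pa).
#' @param group factor or character vector of treatment labels (at least two
#'   groups with at least three cells each).
#' @return list with `anova_F`, `anova_p`, and `tukey` (data.frame of
#'   pairwise differences and adjusted p-values).
#' @export
compareGroupElasticity <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("at least two groups are required")
  if (any(table(group) < 3L)) stop("each group needs at least three cells")
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), tk,
                          row.names = NULL, check.names = FALSE))
}

#' Read / write force-curve grids
#'
#' Each curve is a two-column whitespace-delimited text file (`z` in um,
#' `force` in nN) named `curve_<index>.txt`; a JSON sidecar carries the probe
#' metadata (spring constant N/m, half-angle degrees, Poisson ratio) and the
#' grid geometry (rows, cols, spacing um).
#'
#' @param dir directory holding the curve files and `meta.json`.
#' @return `readForceCurves`: list with `curves` (list of
#'   \linkS4class{ForceCurve}) and `meta`.
#' @export
readForceCurves <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  probe <- AfmProbe(springConstant = meta$spring_constant,
                    halfAngle = deg2rad(meta$half_angle_deg),
                    poissonRatio = meta$poisson_ratio)
  files <- file.path(dir, sprintf("curve_%04d.txt", seq_len(meta$n_curves)))
  curves <- lapply(files, function(fp) {
    tab <- utils::read.table(fp, header = TRUE)
    ForceCurve(tab$z_um * 1e-6, tab$force_nN * 1e-9, probe)
  })
  list(curves = curves, meta = meta)
}

#' @rdname readForceCurves
#' @param curves list of ForceCurves sharing one probe.
#' @param nRows,nCols,spacing grid geometry (spacing in meters).
#' @export
writeForceCurves <- function(curves, dir, nRows, nCols, spacing = 4e-6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probe <- curves[[1]]@probe
  meta <- list(spring_constant = probe@springConstant,
               half_angle_deg = probe@halfAngle * 180 / pi,
               poisson_ratio = probe@poissonRatio,
               n_curves = length(curves), rows = nRows, cols = nCols,
               spacing_um = spacing * 1e6)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (i in seq_along(curves))
    utils::write.table(
      data.frame(z_um = curves[[i]]@z * 1e6,
                 force_nN = curves[[i]]@force * 1e9),
      file.path(dir, sprintf("curve_%04d.txt", i)),
      row.names = FALSE, quote = FALSE)
  invisible(dir)
}
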