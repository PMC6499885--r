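#' Normalize a viability plate to vehicle control
#'
#' Divides every response by the mean of the vehicle (zero-dose) wells and
#' expresses the result in percent.
#'
#' @param data data.frame with columns `concentration` (nM; 0 marks vehicle
#'   wells) and `response` (raw viability signal).
#' @return the same data.frame with `response` replaced by percent-of-vehicle
#'   viability and the vehicle rows retained.
#' @export
normalizeViability <- function(data) {
  veh <- data$response[data$concentration == 0]
  if (!length(veh)) stop("no vehicle (zero-concentration) wells present")
  vm <- mean(veh)
  if (vm <= 0) stop("vehicle mean must be positive")
  data$response <- data$response / vm * 100
  data
}

fourPL <- function(conc, bottom, top, hill, logEc50)
  bottom + (top - bottom) / (1 + (conc / 10^logEc50)^hill)

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares on
#' \deqn{V(c) = bottom + \frac{top - bottom}{1 + (c / EC50)^{hill}}}
#' parameterized in \eqn{\log_{10} EC50} (bounded within two decades of the
#' tested range) and initialized from the data quartiles.  Optionally the top
#' asymptote can be fixed (e.g. at 100 percent of vehicle).
#'
#' @param data data.frame with `concentration` (nM, > 0 rows used for the
#'   fit) and `response` (percent viability); at least four distinct
#'   concentrations.
#' @param fixTop fix the top asymptote at this value instead of fitting it
#'   (NULL = fit, the default).
#' @return A \linkS4class{FourPLFit}; non-convergence is reported in the
#'   `converged` slot, not thrown.
#' @examples
#' conc <- 10^seq(0, 4, length.out = 8)
#' d <- data.frame(concentration = conc,
#'                 response = 100 / (1 + (conc / 100)))
#' fit4PL(d)
#' @export
fit4PL <- function(data, fixTop = NULL) {
  d <- data[data$concentration > 0, , drop = FALSE]
  conc <- d$concentration; resp <- d$response
  if (length(unique(conc)) < 4L)
    stop("a 4PL fit needs at least four distinct concentrations")
  lo <- log10(min(conc) / 100); hi <- log10(max(conc) * 100)
  means <- tapply(resp, conc, mean)
  cs <- as.numeric(names(means))
  startTop <- max(means); startBottom <- min(means)
  half <- (startTop + startBottom) / 2
  startLog <- log10(cs[which.min(abs(means - half))])
  fit <- NULL
  for (startHill in c(1, 0.5, 2)) {
    st <- if (is.null(fixTop))
      list(bottom = startBottom, top = startTop, hill = startHill,
           logEc50 = startLog)
    else list(bottom = startBottom, hill = startHill, logEc50 = startLog)
    fml <- if (is.null(fixTop))
      resp ~ fourPL(conc, bottom, top, hill, logEc50)
    else stats::as.formula(
      sprintf("resp ~ fourPL(conc, bottom, %.15g, hill, logEc50)", fixTop))
    lower <- if (is.null(fixTop)) c(-Inf, -Inf, 1e-3, lo) else c(-Inf, 1e-3, lo)
    upper <- if (is.null(fixTop)) c(Inf, Inf, 50, hi) else c(Inf, 50, hi)
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(new("FourPLFit", bottom = NA_real_,
               top = if (is.null(fixTop)) NA_real_ else fixTop,
               hillSlope = NA_real_, ec50 = NA_real_,
               se = c(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                      ec50 = NA_real_),
               converged = FALSE, extrapolated = NA,
               concRange = range(conc)))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) stats::setNames(rep(NA_real_,
                                                          length(cf)),
                                                      names(cf)))
  ec50 <- 10^cf[["logEc50"]]
  # delta method: se(EC50) = ln(10) * EC50 * se(logEc50)
  seEc50 <- log(10) * ec50 * unname(ses["logEc50"])
  top <- if (is.null(fixTop)) cf[["top"]] else fixTop
  canonicalSwap <- top < cf[["bottom"]]
  bottom <- if (canonicalSwap) top else cf[["bottom"]]
  topOut <- if (canonicalSwap) cf[["bottom"]] else top
  new("FourPLFit",
      bottom = bottom, top = topOut, hillSlope = cf[["hill"]], ec50 = ec50,
      se = c(bottom = unname(ses["bottom"]),
             top = if (is.null(fixTop)) unname(ses["top"]) else 0,
             hill = unname(ses["hill"]), ec50 = seEc50),
      converged = isTRUE(fit$convInfo$isConv),
      extrapolated = ec50 < min(conc) || ec50 > max(conc),
      concRange = range(conc))
}

setMethod("show", "FourPLFit", function(object) {
  if (!object@converged) { cat("FourPLFit: did not converge\n"); return(invisible()) }
  cat(sprintf("FourPLFit: EC50 = %.4g nM (hill %.3g, top %.4g, bottom %.4g)%s\n",
              object@ec50, object@hillSlope, object@top, object@bottom,
              if (object@extrapolated) "  [EC50 outside tested range]" else ""))
})

#' @rdname fit4PL
#' @param x a FourPLFit.
#' @export
ec50 <- function(x) x@ec50

#' @rdname fit4PL
#' @export
isExtrapolated <- function(x) x@extrapolated

#' Geometric summary of replicate EC50s
#'
#' Geometric mean \eqn{\exp(\overline{\log EC50})} and geometric SD
#' \eqn{\exp(s_{\log EC50})} (sample standard deviation of the logs),
#' the conventional summary for log-normally distributed potencies.
#'
#' @param ec50s numeric vector of positive EC50s from at least two converged
#'   fits (a list of \linkS4class{FourPLFit}s is also accepted; only the
#'   converged ones contribute).
#' @return list with `geo_mean`, `geo_sd`, and `n`.
#' @export
summarizeEc50 <- function(ec50s) {
  if (is.list(ec50s))
    ec50s <- vapply(Filter(function(f) isTRUE(f@converged), ec50s),
                    ec50, numeric(1))
  if (length(ec50s) < 2L) stop("at least two converged fits are required")
  if (any(ec50s <= 0)) stop("EC50s must be positive")
  lg <- log(ec50s)
  list(geo_mean = exp(mean(lg)), geo_sd = exp(stats::sd(lg)),
       n = length(ec50s))
}

#' Read a viability plate CSV
#'
#' Expected columns: `concentration` (nM, 0 for vehicle wells) and a
#' response column (default `response`); extra response columns (e.g.
#' morphometric readouts) can be selected with `responseCol`.
#'
#' @param file CSV path.
#' @param responseCol name of the response column.
#' @export
readPlate <- function(file, responseCol = "response") {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  data.frame(concentration = tab$concentration,
             response = tab[[responseCol]])
}
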