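#' Minimum-support filter for spectral counts
#'
#' Retains proteins with enough spectral support in *both* conditions.  With
#' `mode = "sum"` (default) a protein is kept when its summed counts are at
#' least `minCount` in the control condition and at least `minCount` in the
#' treated condition; with `mode = "per-replicate"` every replicate of both
#' conditions must individually reach `minCount`.
#'
#' @param x a \linkS4class{SpectralCountMatrix}.
#' @param minCount minimum spectral support per condition (default 2).
#' @param mode `"sum"` or `"per-replicate"`.
#' @return The filtered \linkS4class{SpectralCountMatrix}; empty results
#'   produce a warning, not an error.
#' @export
filterMinSupport <- function(x, minCount = 2, mode = c("sum", "per-replicate")) {
  mode <- match.arg(mode)
  m <- spectralCounts(x)
  ctrl <- m[, condition(x) == "control", drop = FALSE]
  trt <- m[, condition(x) == "treated", drop = FALSE]
  keep <- if (mode == "sum")
    rowSums(ctrl) >= minCount & rowSums(trt) >= minCount
  else
    apply(ctrl >= minCount, 1, all) & apply(trt >= minCount, 1, all)
  if (!any(keep)) warning("no protein passes the minimum-support filter")
  x[keep, ]
}

# Row-wise two-sample t statistics on a counts matrix.  Vectorized because the
# calibration studies test hundreds of matrices with thousands of proteins;
# equivalence with stats::t.test is asserted in the test suite.
rowTTest <- function(ctrl, trt, varEqual = TRUE) {
  nx <- ncol(ctrl); ny <- ncol(trt)
  mx <- rowMeans(ctrl); my <- rowMeans(trt)
  vx <- rowSums((ctrl - mx)^2) / (nx - 1)
  vy <- rowSums((trt - my)^2) / (ny - 1)
  if (varEqual) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # both groups constant: equal means -> no evidence (p = 1); unequal means
  # with zero variance -> infinite t, p = 0
  degenerate <- se2 == 0
  t[degenerate & mx == my] <- 0
  p[degenerate & mx == my] <- 1
  t[degenerate & mx != my] <- sign(mx - my)[degenerate & mx != my] * Inf
  p[degenerate & mx != my] <- 0
  list(meanControl = mx, meanTreated = my,
       semControl = sqrt(vx / nx), semTreated = sqrt(vy / ny),
       t = t, df = df, p = p)
}

#' Per-protein differential spectral-count test
#'
#' Two-sample unpaired t-test of treated versus control counts per protein
#' (pooled-variance Student t by default; Welch via `varEqual = FALSE`),
#' followed by Benjamini-Hochberg adjustment across all tested proteins.
#'
#' @param x a (typically support-filtered) \linkS4class{SpectralCountMatrix}.
#' @param varEqual use the pooled-variance Student t (default); `FALSE`
#'   selects the Welch test.  At the two-to-four replicates typical of
#'   spectral counting the pooled test preserves the error degrees of
#'   freedom, which the Welch-Satterthwaite approximation halves.
#' @param alpha rejection level applied to BH q-values for the `direction`
#'   call.
#' @return data.frame with one row per protein: condition means and SEMs,
#'   `t_statistic`, `df`, `p_value`, `q_value`, and `direction`
#'   (`"down"`/`"up"` when q <= alpha and the treated mean is below/above
#'   the control mean, else `"none"`).
#' @export
differentialTest <- function(x, varEqual = TRUE, alpha = 0.05) {
  m <- spectralCounts(x)
  ctrl <- m[, condition(x) == "control", drop = FALSE]
  trt <- m[, condition(x) == "treated", drop = FALSE]
  if (ncol(ctrl) < 2L || ncol(trt) < 2L)
    stop("at least two replicates per condition are required")
  r <- rowTTest(ctrl, trt, varEqual = varEqual)
  q <- bhAdjust(r$p)$q_values
  rejected <- q <= alpha
  direction <- ifelse(!rejected, "none",
                      ifelse(r$meanTreated < r$meanControl, "down", "up"))
  direction[rejected & r$meanTreated == r$meanControl] <- "none"
  data.frame(protein = rownames(m),
             mean_control = r$meanControl, sem_control = r$semControl,
             mean_treated = r$meanTreated, sem_treated = r$semTreated,
             t_statistic = r$t, df = r$df, p_value = r$p, q_value = q,
             direction = direction, stringsAsFactors = FALSE)
}

#' t statistic from summary statistics
#'
#' Convenience entry point for published contrasts reported as mean and SEM
#' per group: \eqn{t = (m_1 - m_2) / \sqrt{SEM_1^2 + SEM_2^2}}.
#'
#' @param mean1,sem1,n1 first group summary.
#' @param mean2,sem2,n2 second group summary.
#' @return list with `t`, Welch-Satterthwaite `df`, and two-sided `p`.
#' @export
tFromSummary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  t <- (mean1 - mean2) / sqrt(sem1^2 + sem2^2)
  df <- (sem1^2 + sem2^2)^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up q-values (via [stats::p.adjust()]) and the rejection set
#' at `q <= alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1]; NAs are rejected.
#' @param alpha FDR level.
#' @return list with `q_values` (same order as `p`) and `rejected` (logical).
#' @export
bhAdjust <- function(p, alpha = 0.05) {
  if (anyNA(p)) stop("NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' Select the top down-regulated proteins
#'
#' Proteins whose treated mean is below the control mean and whose *raw*
#' p-value is below `alpha`, ranked by p ascending (ties broken by |t|
#' descending, then identifier) and truncated to `topN`.  BH q-values are
#' carried along for reporting.  This ranked list is the seed set for the
#' subnetwork-specificity stage.
#'
#' @param results output of [differentialTest()].
#' @param alpha raw p-value threshold (default 0.05).
#' @param topN maximum number of proteins returned (default 76).
#' @return data.frame subset of `results`, ranked; fewer than `topN`
#'   qualifying rows produce a warning.
#' @export
selectDownregulated <- function(results, alpha = 0.05, topN = 76) {
  down <- results[results$mean_treated < results$mean_control &
                    results$p_value < alpha, , drop = FALSE]
  ord <- order(down$p_value, -abs(down$t_statistic), down$protein)
  down <- down[ord, , drop = FALSE]
  if (nrow(down) < topN)
    warning("only ", nrow(down), " proteins qualify (requested ", topN, ")")
  utils::head(down, topN)
}
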