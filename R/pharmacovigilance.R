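#' Build the 2x2 contingency counts for one drug and one ADR group
#'
#' Sums report counts into the four disproportionality cells: target-group
#' reports for the index drug (`fDt`), all other reports for the index drug
#' (`fDn`), and the same two sums pooled over every other drug of the class
#' (`fNt`, `fNn`).  The comparator is deliberately within-class: all other
#' drugs of `drugClass(table)`, never the whole database.
#'
#' @param table a \linkS4class{FrequencyTable}.
#' @param drug index drug identifier; must belong to the drug class.
#' @param adrGroup group label to use as the ADR of interest; must map at
#'   least one term.
#' @return A \linkS4class{ContingencyCounts}.
#' @export
buildContingency <- function(table, drug, adrGroup) {
  stopifnot(is(table, "FrequencyTable"))
  if (!drug %in% drugClass(table))
    stop("drug '", drug, "' is not in the drug class")
  terms <- names(termGroups(table))[termGroups(table) == adrGroup]
  if (!length(terms))
    stop("ADR group '", adrGroup, "' maps no terms")
  rec <- records(table)
  rec <- rec[rec$drug %in% drugClass(table), , drop = FALSE]
  inGroup <- rec$adr_term %in% terms
  isDrug <- rec$drug == drug
  new("ContingencyCounts",
      fDt = sum(rec$count[isDrug & inGroup]),
      fDn = sum(rec$count[isDrug & !inGroup]),
      fNt = sum(rec$count[!isDrug & inGroup]),
      fNn = sum(rec$count[!isDrug & !inGroup]))
}

#' Reporting odds ratio with log-scale confidence interval
#'
#' Computes the reporting odds ratio
#' \deqn{ROR = \frac{f_{dt}/f_{dn}}{f_{nt}/f_{nn}},}
#' the standard error of its log,
#' \deqn{SE_{\log ROR} = \sqrt{1/f_{dt} + 1/f_{dn} + 1/f_{nt} + 1/f_{nn}},}
#' and the log-transformed confidence interval
#' \eqn{\exp(\log ROR \pm z \cdot SE)}.
#'
#' Zero cells make the ratio or its standard error undefined; with
#' `correction = "haldane"` (default) 0.5 is added to all four cells whenever
#' any cell is zero, and the result is flagged `corrected`.  With
#' `correction = "none"` a zero cell is an error naming the offending cell.
#'
#' @param counts a \linkS4class{ContingencyCounts}.
#' @param z normal quantile for the interval (1.96 for 95 percent).
#' @param correction zero-cell policy, `"haldane"` or `"none"`.
#' @return A \linkS4class{RorResult}.
#' @examples
#' computeRor(ContingencyCounts(10, 990, 100, 98900))
#' @export
computeRor <- function(counts, z = 1.96, correction = c("haldane", "none")) {
  stopifnot(is(counts, "ContingencyCounts"))
  correction <- match.arg(correction)
  cells <- c(fDt = counts@fDt, fDn = counts@fDn,
             fNt = counts@fNt, fNn = counts@fNn)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "none")
      stop("zero cell(s) ", paste(names(cells)[cells == 0], collapse = ", "),
           " make the ROR undefined (correction disabled)")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  logRor <- log(cells["fDt"]) - log(cells["fDn"]) -
    log(cells["fNt"]) + log(cells["fNn"])
  se <- sqrt(sum(1 / cells))
  new("RorResult",
      ror = unname(exp(logRor)), logRor = unname(logRor), seLogRor = se,
      ciLow = unname(exp(logRor - z * se)),
      ciHigh = unname(exp(logRor + z * se)),
      z = z, corrected = corrected)
}

#' @rdname buildContingency
#' @param fDt,fDn,fNt,fNn the four cells.
#' @export
ContingencyCounts <- function(fDt, fDn, fNt, fNn)
  new("ContingencyCounts", fDt = fDt, fDn = fDn, fNt = fNt, fNn = fNn)

setMethod("show", "ContingencyCounts", function(object) {
  m <- matrix(c(object@fDt, object@fDn, object@fNt, object@fNn), 2,
              byrow = TRUE,
              dimnames = list(c("index drug", "other drugs"),
                              c("target ADR", "other ADR")))
  cat("ContingencyCounts\n"); print(m)
})

setMethod("show", "RorResult", function(object) {
  cat(sprintf("ROR = %.4g  [%.4g, %.4g] (z = %.3g)%s\n",
              object@ror, object@ciLow, object@ciHigh, object@z,
              if (object@corrected) "  [zero-cell corrected]" else ""))
})

#' Flatten one or more RorResults to a data.frame
#' @param x a RorResult or a list of them (possibly named by drug).
#' @export
rorTable <- function(x) {
  if (is(x, "RorResult")) x <- list(x)
  do.call(rbind, lapply(seq_along(x), function(i) {
    r <- x[[i]]
    data.frame(drug = if (!is.null(names(x))) names(x)[i] else NA_character_,
               ror = r@ror, log_ror = r@logRor, se_log_ror = r@seLogRor,
               ci_low = r@ciLow, ci_high = r@ciHigh, corrected = r@corrected,
               stringsAsFactors = FALSE)
  }))
}

#' Rank the drugs of a class by reporting odds ratio for an ADR group
#'
#' Computes one ROR per class drug (each drug in turn as the index drug,
#' the remaining class pooled as comparator) and sorts by ROR descending,
#' ties broken by drug identifier.  Per-drug computation errors are recorded
#' in an `error` column, not fatal.
#'
#' @inheritParams buildContingency
#' @inheritParams computeRor
#' @return data.frame with one row per drug: `drug`, `ror`, `ci_low`,
#'   `ci_high`, `se_log_ror`, `corrected`, `error`.
#' @export
rankDrugs <- function(table, adrGroup, z = 1.96,
                      correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  drugs <- sort(drugClass(table))
  if (length(drugs) < 2L) stop("ranking needs at least two class drugs")
  rows <- lapply(drugs, function(d) {
    res <- tryCatch(
      computeRor(buildContingency(table, d, adrGroup), z, correction),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(drug = d, ror = NA_real_, log_ror = NA_real_,
                 se_log_ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 corrected = NA, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      cbind(drug = d, rorTable(res)[-1], error = NA_character_)
  })
  out <- do.call(rbind, rows)
  out[order(-out$ror, out$drug, na.last = TRUE), , drop = FALSE]
}

#' Dual-ADR risk profile with outlier flagging
#'
#' For every class drug, computes the ROR for two ADR groups, fits an
#' ordinary least-squares line of `log(ror_a)` on `log(ror_b)` across drugs
#' (the class-wide co-risk trend), and standardizes each drug's vertical
#' residual by the residual standard deviation.  A drug whose absolute
#' standardized residual exceeds `flagThreshold` departs from the trend and
#' is flagged as a dual-risk outlier -- e.g. a drug with high glomerular risk
#' but unremarkable hypertension risk.
#'
#' @inheritParams buildContingency
#' @param groupA,groupB the two ADR group labels (A is the response axis).
#' @param flagThreshold standardized-residual magnitude above which a drug is
#'   flagged (default 2).
#' @inheritParams computeRor
#' @return data.frame with one row per usable drug: `drug`, `ror_a`, `ror_b`,
#'   their CIs, `residual` (log scale), `std_residual`, `outlier`.
#' @export
dualRiskProfile <- function(table, groupA, groupB, flagThreshold = 2,
                            z = 1.96, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  a <- rankDrugs(table, groupA, z, correction)
  b <- rankDrugs(table, groupB, z, correction)
  m <- merge(a, b, by = "drug", suffixes = c("_a", "_b"))
  ok <- !is.na(m$ror_a) & !is.na(m$ror_b)
  if (sum(ok) < 4L)
    stop("need at least 4 drugs with computable RORs for the trend line")
  m <- m[ok, , drop = FALSE]
  fit <- stats::lm(log(ror_a) ~ log(ror_b), data = m)
  res <- stats::residuals(fit)
  sdRes <- stats::sd(res)
  std <- if (sdRes > 0) res / sdRes else res * 0
  out <- data.frame(drug = m$drug,
                    ror_a = m$ror_a, ci_low_a = m$ci_low_a,
                    ci_high_a = m$ci_high_a,
                    ror_b = m$ror_b, ci_low_b = m$ci_low_b,
                    ci_high_b = m$ci_high_b,
                    residual = unname(res), std_residual = unname(std),
                    outlier = abs(std) > flagThreshold,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$std_residual)), , drop = FALSE]
}
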