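## Risk attribution and cohort analysis: risk classification, clinical
## significance, sensitivity, attribution rates, summary tables and
## between-strategy tests.

.gleasonRank <- function(g) match(g, .gleasonLevels)

#' Classify a biopsy session's risk
#'
#' High risk when MCCL >= 6 mm and/or >= 50% positive cores (both
#' boundaries inclusive); low otherwise. Vectorised.
#'
#' @param mccl maximum cancer core length, mm
#' @param pctPositive percentage of positive cores
#' @param criteria a [RiskCriteria-class]
#' @return character vector, \code{"high"} or \code{"low"}
#' @export
classifyRisk <- function(mccl, pctPositive, criteria = riskCriteria()) {
  stopifnot(all(mccl >= 0), all(pctPositive >= 0))
  ifelse(mccl >= criteria@mcclThreshold |
           pctPositive >= criteria@pctPositiveThreshold, "high", "low")
}

#' Is a case clinically significant?
#'
#' TRUE when any true lesion has volume >= 0.5 ml and/or Gleason grade
#' >= 7 (boundaries inclusive). False-positive targets never count.
#'
#' @param model a [ProstateModel-class]
#' @param sc a [SignificanceCriteria-class]
#' @return logical flag
#' @export
caseIsSignificant <- function(model, sc = significanceCriteria()) {
  stopifnot(is(model, "ProstateModel"))
  les <- model@lesions
  les <- les[!les$isFalseTarget, , drop = FALSE]
  if (!nrow(les)) return(FALSE)
  any(les$volume >= sc@volumeThreshold |
        .gleasonRank(les$gleason) >= .gleasonRank(sc@gleasonThreshold))
}

## cancer-bearing models of a cohort restricted to a stratum
.stratumModels <- function(cohort, stratum, sc) {
  ids <- vapply(cohort, function(m) m@id, character(1))
  cancer <- vapply(cohort, function(m) any(!m@lesions$isFalseTarget), logical(1))
  sig <- vapply(cohort, caseIsSignificant, logical(1), sc = sc)
  keep <- switch(stratum,
                 all = cancer,
                 significant = cancer & sig,
                 insignificant = cancer & !sig,
                 stop("unknown stratum: ", stratum))
  ids[keep]
}

#' Detection sensitivity of a strategy
#'
#' The fraction of cancer-bearing models in the stratum that are
#' detected, averaging per-repetition detection (a session detects when
#' at least one core is positive). Benign-target models are excluded
#' from the denominator, as are models absent from \code{results}
#' (e.g. no eligible imaging target, reverting to TRUS-only analysis).
#'
#' @param results session table from [runStrategy()]/[runCohort()]
#'   (one strategy)
#' @param cohort the model list the results were computed on
#' @param stratum \code{"all"}, \code{"significant"} or
#'   \code{"insignificant"}
#' @param sc a [SignificanceCriteria-class]
#' @return sensitivity in [0, 1]
#' @export
strategySensitivity <- function(results, cohort, stratum = "all",
                                sc = significanceCriteria()) {
  ids <- intersect(.stratumModels(cohort, stratum, sc),
                   unique(results$modelId))
  if (!length(ids)) stop("empty stratum: sensitivity undefined")
  perModel <- vapply(ids, function(id)
    mean(results$detected[results$modelId == id]), numeric(1))
  mean(perModel)
}

#' High-risk attribution rate among significant cases
#'
#' A case is attributed high risk when the across-repetition proportion
#' of high-risk sessions exceeds \code{aggregationThreshold} (majority
#' rule by default). The per-case proportions are also returned so any
#' other aggregation can be applied post hoc.
#'
#' @param results session table (one strategy)
#' @param cohort the model list
#' @param criteria a [RiskCriteria-class] (already applied per session)
#' @param sc a [SignificanceCriteria-class]
#' @param stratum case stratum (default \code{"significant"})
#' @param aggregationThreshold proportion of repetitions above which a
#'   case is called high risk (default 0.5)
#' @return the attribution rate, with the per-case high-risk
#'   proportions as attribute \code{"perCase"}
#' @export
attributionRate <- function(results, cohort, criteria = riskCriteria(),
                            sc = significanceCriteria(),
                            stratum = "significant",
                            aggregationThreshold = 0.5) {
  ids <- intersect(.stratumModels(cohort, stratum, sc),
                   unique(results$modelId))
  if (!length(ids)) stop("empty stratum: attribution rate undefined")
  perCase <- vapply(ids, function(id)
    mean(results$riskClass[results$modelId == id] == "high"), numeric(1))
  rate <- mean(perCase > aggregationThreshold)
  attr(rate, "perCase") <- perCase
  rate
}

#' Cohort summary by stratum and strategy
#'
#' Per stratum (all / significant / insignificant cancer) and strategy:
#' mean, SD, median and 90th percentile of the per-case MCCL and
#' percentage of positive cores (case value = mean over repetitions),
#' the detection sensitivity, and the high-risk attribution fraction.
#' Percentiles use the inclusive linear-interpolation convention
#' (\code{stats::quantile} type 7).
#'
#' @param results session table from [runCohort()]
#' @param cohort the model list
#' @param strata strata to tabulate
#' @param criteria a [RiskCriteria-class]
#' @param sc a [SignificanceCriteria-class]
#' @return a data.frame, one row per stratum x strategy
#' @export
summarizeCohort <- function(results, cohort,
                            strata = c("all", "significant", "insignificant"),
                            criteria = riskCriteria(),
                            sc = significanceCriteria()) {
  stopifnot(nrow(results) > 0)
  rows <- list()
  for (stratum in strata) {
    sids <- .stratumModels(cohort, stratum, sc)
    for (s in unique(results$strategy)) {
      rs <- results[results$strategy == s & results$modelId %in% sids, ]
      ids <- unique(rs$modelId)
      if (!length(ids)) next
      mccl <- vapply(ids, function(id) mean(rs$mccl[rs$modelId == id]), numeric(1))
      pct <- vapply(ids, function(id) mean(rs$pctPositive[rs$modelId == id]), numeric(1))
      det <- vapply(ids, function(id) mean(rs$detected[rs$modelId == id]), numeric(1))
      high <- vapply(ids, function(id)
        mean(rs$riskClass[rs$modelId == id] == "high"), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, strategy = s, nCases = length(ids),
        mcclMean = mean(mccl), mcclSd = if (length(mccl) > 1) sd(mccl) else 0,
        mcclMedian = median(mccl),
        mcclP90 = unname(quantile(mccl, 0.9, type = 7)),
        pctPosMean = mean(pct), pctPosSd = if (length(pct) > 1) sd(pct) else 0,
        pctPosMedian = median(pct),
        pctPosP90 = unname(quantile(pct, 0.9, type = 7)),
        sensitivity = mean(det),
        highRiskFraction = mean(high > 0.5),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two strategies
#'
#' Pairs per-case means (over repetitions) of the chosen metric by
#' model, then reports a paired Student t test, a two-sample
#' Kolmogorov-Smirnov test on the matched value sets, and a KS test of
#' the paired differences against their sign-flipped mirror (a symmetry
#' reading of a "paired KS" test). Significance level alpha = 0.05;
#' p-values are reported raw.
#'
#' @param resA,resB session tables for the two strategies (same cohort)
#' @param metric \code{"mccl"} or \code{"pctPositive"}
#' @return list with \code{n}, \code{meanA}, \code{meanB},
#'   \code{meanDifference}, \code{tStatistic}, \code{tP},
#'   \code{ksStatistic}, \code{ksP}, \code{ksPairedStatistic},
#'   \code{ksPairedP}
#' @export
compareStrategies <- function(resA, resB, metric = c("mccl", "pctPositive")) {
  metric <- match.arg(metric)
  ids <- intersect(unique(resA$modelId), unique(resB$modelId))
  if (length(ids) < 3L) stop("fewer than 3 paired cases: tests refused")
  a <- vapply(ids, function(id)
    mean(resA[[metric]][resA$modelId == id]), numeric(1))
  b <- vapply(ids, function(id)
    mean(resB[[metric]][resB$modelId == id]), numeric(1))
  d <- b - a
  if (sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    tStat <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
    tP <- if (abs(mean(d)) < 1e-12) 1 else 0
  } else {
    tt <- t.test(b, a, paired = TRUE)
    tStat <- unname(tt$statistic)
    tP <- tt$p.value
  }
  ks <- suppressWarnings(ks.test(a, b))
  ksPaired <- suppressWarnings(ks.test(d, -d))
  list(n = length(ids), meanA = mean(a), meanB = mean(b),
       meanDifference = mean(d), tStatistic = tStat, tP = tP,
       ksStatistic = unname(ks$statistic), ksP = ks$p.value,
       ksPairedStatistic = unname(ksPaired$statistic),
       ksPairedP = ksPaired$p.value)
}
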