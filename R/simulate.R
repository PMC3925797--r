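## Monte-Carlo biopsy engine: targeting-error sampling, core
## realization, per-strategy repetition runs and the error sweep.

#' Sample total targeting-error displacements
#'
#' Each displacement has zero-mean normal components in the three
#' orthogonal directions. In \code{"combined"} mode (default) the
#' per-axis variance is \code{totalSd^2 / 3}, so the per-axis variances
#' sum to the set total variance. In \code{"components"} mode deflection
#' and (for targeted cores) registration draws are summed and rescaled
#' to the same set total; non-targeted cores receive the deflection
#' component alone.
#'
#' @param em an [ErrorModel-class]
#' @param n number of displacement vectors
#' @param targeted is the core image-targeted? (governs the
#'   registration component in \code{"components"} mode)
#' @return an n x 3 matrix of displacements, mm
#' @export
sampleError <- function(em, n = 1, targeted = TRUE) {
  stopifnot(is(em, "ErrorModel"))
  axisSd <- if (em@varianceAccounting == "summed")
    em@totalSd / sqrt(3) else em@totalSd
  if (em@mode == "combined") {
    if (em@totalSd == 0) return(matrix(0, n, 3))
    return(matrix(rnorm(3 * n, 0, axisSd), n, 3))
  }
  withReg <- targeted || em@applyRegistrationTo == "all"
  e <- matrix(rnorm(3 * n, 0, em@deflectionSd), n, 3)
  if (withReg) {
    e <- e + matrix(rnorm(3 * n, 0, em@registrationSd), n, 3)
    addVar <- em@deflectionSd^2 + em@registrationSd^2
    if (addVar > 0) e <- e * (axisSd / sqrt(addVar))
  }
  e
}

#' Sample the needle-deflection error component alone
#'
#' @param em an [ErrorModel-class]
#' @param n number of vectors
#' @return an n x 3 matrix with per-axis SD \code{em@deflectionSd}
#' @export
sampleDeflection <- function(em, n = 1) {
  stopifnot(is(em, "ErrorModel"))
  matrix(rnorm(3 * n, 0, em@deflectionSd), n, 3)
}

#' Apply a targeting-error displacement to a core
#'
#' Pure translation: the realized midpoint is the planned midpoint plus
#' the error vector; direction and effective length are unchanged.
#'
#' @param core a [BiopsyCore-class]
#' @param err numeric(3) displacement, mm
#' @return the realized [BiopsyCore-class]
#' @export
realizeCore <- function(core, err) {
  stopifnot(is(core, "BiopsyCore"), length(err) == 3L)
  initialize(core, realizedMidpoint = core@plannedMidpoint + as.numeric(err))
}

.strategyIndex <- function(strategy) {
  match(strategy, c("TRUS12", paste0("TARGETED_", 1:5)), nomatch = 99L)
}

.sessionFrame <- function(modelId, strategy, reps, nCores, lenMat,
                          positivityThreshold, criteria) {
  pos <- lenMat > positivityThreshold
  nPos <- rowSums(pos)
  mccl <- apply(lenMat, 1L, max)
  pct <- 100 * nPos / nCores
  data.frame(modelId = modelId, strategy = strategy, rep = seq_len(reps),
             nCores = nCores, nPositive = nPos, mccl = mccl,
             pctPositive = pct, detected = nPos >= 1L,
             riskClass = classifyRisk(mccl, pct, criteria),
             stringsAsFactors = FALSE)
}

#' Run one biopsy strategy on one model
#'
#' Performs \code{reps} Monte-Carlo repetitions. Every planned core is
#' perturbed by an independent targeting-error draw; TRUS plans are
#' re-drawn each repetition (anatomic jitter), targeted plans are fixed
#' at planning time with error applied at realization. Deterministic
#' given \code{seed} (an independent substream per model x strategy).
#'
#' For a targeted strategy on a model without an eligible target the
#' model reverts to TRUS-only analysis and \code{NULL} is returned.
#'
#' @param model a [ProstateModel-class]
#' @param strategy \code{"TRUS12"} or \code{"TARGETED_k"} (k = 1..5)
#' @param em an [ErrorModel-class]
#' @param reps repetitions (default 500)
#' @param seed master seed
#' @param modelIndex integer index of the model within its cohort (used
#'   for the substream; defaults to a hash of the model id)
#' @param trusScheme parameters from [defaultTrusScheme()]
#' @param grid a [TemplateGrid-class]
#' @param effectiveLength sampling-notch length, mm (default 17)
#' @param targetThreshold minimum target volume, ml
#' @param positivityThreshold minimum cancer length (mm) for a positive core
#' @param criteria a [RiskCriteria-class] for per-session risk class
#' @return a data.frame with one row per repetition: \code{modelId},
#'   \code{strategy}, \code{rep}, \code{nCores}, \code{nPositive},
#'   \code{mccl}, \code{pctPositive}, \code{detected}, \code{riskClass}
#' @export
runStrategy <- function(model, strategy, em = errorModel(), reps = 500,
                        seed = 1, modelIndex = NULL,
                        trusScheme = defaultTrusScheme(),
                        grid = templateGrid(), effectiveLength = 17,
                        targetThreshold = 0.2, positivityThreshold = 0,
                        criteria = riskCriteria()) {
  stopifnot(is(model, "ProstateModel"), reps >= 1)
  k <- .strategyCores(strategy)
  if (is.na(k)) stop("unknown strategy: ", strategy)
  if (is.null(modelIndex))
    modelIndex <- sum(utf8ToInt(model@id)) %% 100000L
  set.seed(.subSeed(seed, .strategyIndex(strategy), modelIndex))
  les <- model@lesions
  halfLen <- effectiveLength / 2
  if (strategy == "TRUS12") {
    base <- planTrus12(model, trusScheme, effectiveLength, jitter = FALSE)
    bm <- as.matrix(base@cores[, c("midX", "midY", "midZ")])
    mids0 <- bm[rep(seq_len(12L), reps), , drop = FALSE]
    if (trusScheme$jitterSd > 0)
      mids0 <- mids0 + matrix(rnorm(length(mids0), 0, trusScheme$jitterSd),
                              nrow(mids0), 3)
    dirs <- mids0 - matrix(model@anusRef, nrow(mids0), 3, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    mids <- mids0 + sampleError(em, nrow(mids0), targeted = FALSE)
    sc <- .scoreCores(mids, dirs, halfLen, les)
    lenMat <- matrix(sc$length, reps, 12L, byrow = TRUE)
    return(.sessionFrame(model@id, strategy, reps, 12L, lenMat,
                         positivityThreshold, criteria))
  }
  if (!length(eligibleTargets(model, targetThreshold))) return(NULL)
  plan <- planTargeted(model, k, grid, effectiveLength, targetThreshold)
  pm <- as.matrix(plan@cores[, c("midX", "midY", "midZ")])
  dm <- as.matrix(plan@cores[, c("dirX", "dirY", "dirZ")])
  mids <- pm[rep(seq_len(k), reps), , drop = FALSE] +
    sampleError(em, k * reps, targeted = TRUE)
  dirs <- dm[rep(seq_len(k), reps), , drop = FALSE]
  sc <- .scoreCores(mids, dirs, halfLen, les)
  lenMat <- matrix(sc$length, reps, k, byrow = TRUE)
  .sessionFrame(model@id, strategy, reps, k, lenMat,
                positivityThreshold, criteria)
}

#' Run several strategies over a cohort
#'
#' @param cohort a list of [ProstateModel-class] (see [buildCohort()])
#' @param strategies character vector of strategy labels
#' @param em an [ErrorModel-class]
#' @param reps repetitions per model per strategy
#' @param seed master seed
#' @param ... passed to [runStrategy()]
#' @return the row-bound session table over all models and strategies
#' @export
runCohort <- function(cohort, strategies = c("TRUS12", "TARGETED_3", "TARGETED_4"),
                      em = errorModel(), reps = 500, seed = 1, ...) {
  out <- vector("list", length(cohort) * length(strategies))
  n <- 0L
  for (s in strategies) {
    for (i in seq_along(cohort)) {
      r <- runStrategy(cohort[[i]], s, em = em, reps = reps, seed = seed,
                       modelIndex = i, ...)
      if (!is.null(r)) { n <- n + 1L; out[[n]] <- r }
    }
  }
  do.call(rbind, out[seq_len(n)])
}

#' Sensitivity as a function of applied targeting error
#'
#' Re-runs each strategy at each total-error level and reports the
#' cohort-averaged all-cancer sensitivity, the layout of the
#' sensitivity-versus-error curve.
#'
#' @param cohort a list of [ProstateModel-class]
#' @param strategies strategy labels
#' @param totals total targeting errors to apply, mm
#' @param em template [ErrorModel-class]; its \code{totalSd} is replaced
#'   by each sweep value
#' @param reps repetitions per model per strategy
#' @param seed master seed
#' @param ... passed to [runStrategy()]
#' @return data.frame with columns \code{strategy},
#'   \code{totalErrorMm}, \code{sensitivity}
#' @export
errorSweep <- function(cohort, strategies = c("TRUS12", "TARGETED_4"),
                       totals = 1:10, em = errorModel(), reps = 100,
                       seed = 1, ...) {
  stopifnot(all(totals > 0))
  rows <- list()
  for (tot in totals) {
    emT <- initialize(em, totalSd = tot)
    res <- runCohort(cohort, strategies, em = emT, reps = reps,
                     seed = .subSeed(seed, round(100 * tot)), ...)
    for (s in strategies) {
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s, totalErrorMm = tot,
        sensitivity = strategySensitivity(res[res$strategy == s, ],
                                          cohort, "all"))
    }
  }
  do.call(rbind, rows)
}
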