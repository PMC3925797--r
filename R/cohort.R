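## Synthetic cohort generation: glands and lesions with the population
## structure of a step-sectioned radical-prostatectomy series.

## Fixed gland shape ratios (lateral : antero-posterior : base-apex).
## A prostate is wider than tall and slightly shorter base-apex than
## laterally; the ratios only set the aspect, the sampled volume sets
## the scale.
.glandShape <- c(1, 0.75, 0.9)

## 26 unit directions (cube faces, edges, corners) used to probe lesion
## surface containment inside the capsule.
.surfaceDirs <- local({
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g / sqrt(rowSums(g^2))
})

#' Default synthetic cohort specification
#'
#' Defaults emulate the reference whole-mount cohort: gland volume
#' median 50.2 ml (range 26.8-127.7), median 5 lesions per gland (range
#' 1-21), index lesion volume median 1.215 ml, non-index median 0.019
#' ml, anterior placement probability 415/665, Gleason mix 57/35/8%
#' over {<=6, 7, >=8}, and a 34% false-positive imaging-target rate.
#' Lognormal parameters are calibrated so the truncated distributions
#' reproduce the published medians and ranges.
#'
#' @param nProstates number of cancer-bearing glands (default 107)
#' @param falsePositiveRate fraction of targeted sessions aimed at a
#'   benign target (default 0.34)
#' @param seed RNG seed
#' @return a [CohortSpec-class] object
#' @export
defaultCohortSpec <- function(nProstates = 107, falsePositiveRate = 0.34,
                              seed = 20140301) {
  new("CohortSpec",
      nProstates = nProstates,
      glandVolume = list(meanlog = log(50.2), sdlog = 0.35, min = 26.8, max = 127.7),
      lesionCount = list(size = 4, mu = 4.8, max = 21),
      indexVolume = list(meanlog = log(1.215), sdlog = 0.943, min = 0.015, max = 13.242),
      nonindexVolume = list(meanlog = log(0.019), sdlog = 1.710, min = 0.001, max = 1.842),
      zoneProbs = c(anterior = 415 / 665, posterior = 250 / 665),
      gleasonProbs = c("<=6" = 0.57, "7" = 0.35, ">=8" = 0.08),
      falsePositiveRate = falsePositiveRate,
      seed = seed)
}

#' Gland ellipsoid semi-axes for a target volume
#'
#' @param volumeMl gland volume in ml
#' @param shape aspect ratios (lateral, antero-posterior, base-apex)
#' @return numeric(3) semi-axes in mm
#' @export
glandSemiAxesForVolume <- function(volumeMl, shape = .glandShape) {
  s <- (3000 * volumeMl / (4 * pi * prod(shape)))^(1 / 3)
  s * shape
}

#' Build a one-row lesion table entry
#'
#' Semi-axes are derived from the volume and aspect ratios so the
#' ellipsoid volume equals \code{volume} exactly.
#'
#' @param id lesion identifier
#' @param volume ml
#' @param centre numeric(3), mm
#' @param aspect ratios of the three semi-axes (scaled to the volume)
#' @param theta rotation about the base-apex axis, radians
#' @param gleason Gleason category
#' @param zone "anterior" or "posterior"
#' @param isIndex,isFalseTarget flags
#' @return a one-row data.frame suitable for [prostateModel()]
#' @export
makeLesion <- function(id, volume, centre = c(0, 0, 0), aspect = c(1, 1, 1),
                       theta = 0, gleason = "<=6", zone = NULL,
                       isIndex = FALSE, isFalseTarget = FALSE) {
  s <- (3000 * volume / (4 * pi * prod(aspect)))^(1 / 3)
  ax <- s * aspect
  if (is.null(zone)) zone <- if (centre[2] >= 0) "anterior" else "posterior"
  data.frame(id = as.character(id), volume = volume, gleason = gleason,
             zone = zone, cx = centre[1], cy = centre[2], cz = centre[3],
             ax = ax[1], ay = ax[2], az = ax[3], theta = theta,
             isIndex = isIndex, isFalseTarget = isFalseTarget,
             stringsAsFactors = FALSE)
}

.emptyLesions <- function() {
  makeLesion("x", 1)[0, ]
}

#' Construct a ProstateModel
#'
#' @param id model identifier
#' @param glandVolumeMl gland volume (ml); ignored when
#'   \code{glandSemiAxes} is given
#' @param lesions lesion data.frame (rows from [makeLesion()])
#' @param glandSemiAxes numeric(3) semi-axes, mm
#' @param centre gland centre, mm
#' @param anusRef anatomic anus reference for TRUS trajectories, mm;
#'   default 25 mm posterior and 40 mm beyond the apex
#' @return a [ProstateModel-class] object
#' @export
prostateModel <- function(id, glandVolumeMl = 50, lesions = .emptyLesions(),
                          glandSemiAxes = NULL, centre = c(0, 0, 0),
                          anusRef = NULL) {
  if (is.null(glandSemiAxes)) glandSemiAxes <- glandSemiAxesForVolume(glandVolumeMl)
  if (is.null(anusRef)) anusRef <- centre + c(0, -25, -(glandSemiAxes[3] + 40))
  new("ProstateModel", id = as.character(id), glandCentre = centre,
      glandSemiAxes = glandSemiAxes, lesions = lesions,
      anusRef = anusRef, baseApexAxis = c(0, 0, 1))
}

## Points on the lesion ellipsoid surface (world coordinates).
.lesionSurfacePoints <- function(les) {
  u <- .surfaceDirs
  p <- cbind(u[, 1] * les$ax, u[, 2] * les$ay, u[, 3] * les$az)
  ct <- cos(les$theta); st <- sin(les$theta)
  cbind(ct * p[, 1] - st * p[, 2] + les$cx,
        st * p[, 1] + ct * p[, 2] + les$cy,
        p[, 3] + les$cz)
}

## TRUE when every surface probe point lies inside the gland ellipsoid,
## allowing `tol` mm of protrusion.
.lesionInsideGland <- function(les, centre, semiAxes, tol = 0.5) {
  p <- .lesionSurfacePoints(les)
  s <- sweep(sweep(p, 2, centre), 2, semiAxes, "/")
  r <- sqrt(rowSums(s^2))
  all(r <= 1 + tol / mean(semiAxes))
}

## Place one lesion of given volume and zone inside the gland by
## rejection sampling; the aspect is blended toward a sphere in later
## rounds so feasible volumes always place.
.placeLesion <- function(id, volume, zone, gleason, centre, semiAxes,
                         maxAttempts = 200L) {
  for (round in 0:2) {
    blend <- c(1, 0.5, 0)[round + 1]
    ## Step-section morphology: foci spread within the transverse plane
    ## and are flattened along the base-apex axis. Axial semi-axis is a
    ## fraction f of the volume-equivalent radius; in-plane aspect q.
    f <- runif(1, 0.4, 0.7)
    q <- runif(1, 0.6, 1)
    aspect0 <- c(1 / sqrt(q * f), sqrt(q / f), f)
    aspect <- aspect0 * blend + (1 - blend)
    theta <- runif(1, 0, pi) * blend
    for (i in seq_len(maxAttempts)) {
      w <- rnorm(3)
      w <- w / sqrt(sum(w^2)) * runif(1)^(1 / 3)
      if (zone == "anterior") w[2] <- abs(w[2]) else w[2] <- -abs(w[2])
      cand <- centre + w * semiAxes
      les <- makeLesion(id, volume, centre = cand, aspect = aspect,
                        theta = theta, gleason = gleason, zone = zone)
      if (.lesionInsideGland(les, centre, semiAxes)) return(les)
    }
  }
  stop("lesion placement failed: spec infeasible (lesion of ", round(volume, 3),
       " ml cannot be placed inside a ", round(4 / 3 * pi * prod(semiAxes) / 1000, 1),
       " ml gland)")
}

.sampleLesionCount <- function(lc) {
  for (i in 1:100) {
    n <- 1L + stats::rnbinom(1L, size = lc$size, mu = lc$mu)
    if (n <= lc$max) return(n)
  }
  as.integer(lc$max)
}

#' Sample one synthetic prostate model
#'
#' Draws a gland volume, a lesion count, an index-lesion volume and
#' non-index volumes from the spec's distributions, places each lesion
#' inside the capsule by rejection sampling (anterior/posterior zone by
#' the sign of the centre's antero-posterior coordinate relative to the
#' urethra-level coronal plane), and flags the largest lesion as index.
#' Uses the current RNG state; seed via \code{set.seed()} or
#' [buildCohort()] for determinism.
#'
#' The index lesion volume is additionally capped at 30% of the gland
#' volume so that capsule containment is always feasible.
#'
#' @param spec a [CohortSpec-class]
#' @param modelId identifier for the returned model
#' @return a [ProstateModel-class]
#' @export
sampleProstate <- function(spec, modelId = "P1") {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  gv <- .rlnormTrunc(1, spec@glandVolume$meanlog, spec@glandVolume$sdlog,
                     spec@glandVolume$min, spec@glandVolume$max)
  semiAxes <- glandSemiAxesForVolume(gv)
  centre <- c(0, 0, 0)
  n <- .sampleLesionCount(spec@lesionCount)
  iv <- spec@indexVolume
  ivMax <- min(iv$max, 0.30 * gv)
  if (ivMax < iv$min)
    stop("infeasible spec: index lesion volume range [", iv$min, ", ", iv$max,
         "] ml exceeds the containment cap for a ", round(gv, 1), " ml gland")
  indexVol <- .rlnormTrunc(1, iv$meanlog, iv$sdlog, iv$min, ivMax)
  nv <- spec@nonindexVolume
  glandGleason <- sample(.gleasonLevels, 1L, prob = spec@gleasonProbs)
  for (attempt in 1:50) {
    nonVols <- if (n > 1L) .rlnormTrunc(n - 1L, nv$meanlog, nv$sdlog, nv$min, nv$max)
               else numeric(0)
    vols <- c(indexVol, nonVols)
    if (sum(vols) <= 0.6 * gv) break
    if (attempt == 50) stop("lesion volumes exceed gland volume: spec infeasible")
  }
  zones <- sample(c("anterior", "posterior"), n, replace = TRUE,
                  prob = spec@zoneProbs[c("anterior", "posterior")])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gl <- if (i == 1L) glandGleason else "<=6"
    rows[[i]] <- .placeLesion(paste0("L", i), vols[i], zones[i], gl,
                              centre, semiAxes)
  }
  les <- do.call(rbind, rows)
  les$isIndex <- seq_len(n) == which.max(les$volume)
  prostateModel(modelId, lesions = les, glandSemiAxes = semiAxes,
                centre = centre)
}

## A benign-target model: a gland whose only "lesion" is an imaging
## false positive (carries zero cancer but is a valid target >= the
## targeting threshold).
.sampleBenignTargetModel <- function(spec, modelId, targetThreshold = 0.2) {
  gv <- .rlnormTrunc(1, spec@glandVolume$meanlog, spec@glandVolume$sdlog,
                     spec@glandVolume$min, spec@glandVolume$max)
  semiAxes <- glandSemiAxesForVolume(gv)
  iv <- spec@indexVolume
  vol <- .rlnormTrunc(1, iv$meanlog, iv$sdlog, max(iv$min, targetThreshold),
                      min(iv$max, 0.30 * gv))
  zone <- sample(c("anterior", "posterior"), 1L,
                 prob = spec@zoneProbs[c("anterior", "posterior")])
  les <- .placeLesion("FT1", vol, zone, "<=6", c(0, 0, 0), semiAxes)
  les$isFalseTarget <- TRUE
  les$isIndex <- FALSE
  prostateModel(modelId, lesions = les, glandSemiAxes = semiAxes)
}

#' Build a synthetic cohort
#'
#' Generates \code{nProstates} cancer-bearing models, then appends
#' benign-target models (glands whose only imaging target is a
#' false-positive region) so that the expected fraction of
#' targeted-biopsy sessions directed at a benign target equals
#' \code{falsePositiveRate}: with \eqn{n_t} targetable cancer models,
#' \eqn{m = round(r/(1-r) \cdot n_t)} benign models are appended. With
#' \code{falsePositiveRate = 1} every generated model is a benign-target
#' model. Fully deterministic given \code{spec@seed} (independent
#' per-model substreams).
#'
#' @param spec a [CohortSpec-class]
#' @param targetThreshold minimum lesion volume (ml) that constitutes an
#'   imaging target (default 0.2)
#' @return a list of [ProstateModel-class] objects; cancer models first,
#'   benign-target models (ids \code{FP...}) last
#' @export
buildCohort <- function(spec, targetThreshold = 0.2) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- as.integer(spec@nProstates)
  r <- spec@falsePositiveRate
  if (r >= 1) {
    models <- vector("list", n)
    for (i in seq_len(n)) {
      set.seed(.subSeed(spec@seed, 2L, i))
      models[[i]] <- .sampleBenignTargetModel(
        spec, sprintf("FP%03d", i), targetThreshold)
    }
    return(models)
  }
  models <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.subSeed(spec@seed, 1L, i))
    models[[i]] <- sampleProstate(spec, sprintf("P%03d", i))
  }
  nTargetable <- sum(vapply(models, function(m)
    any(lesions(m)$volume >= targetThreshold), logical(1)))
  m <- round(r / (1 - r) * nTargetable)
  if (m > 0) {
    benign <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(.subSeed(spec@seed, 2L, i))
      benign[[i]] <- .sampleBenignTargetModel(
        spec, sprintf("FP%03d", i), targetThreshold)
    }
    models <- c(models, benign)
  }
  models
}
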