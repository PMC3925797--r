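## Cancer core length geometry: segment-ellipsoid chords (analytic) and
## voxel-mask sampling, with interval union across overlapping lesions.

## Parametric intersection of M needle segments with one lesion
## ellipsoid. midpoints, dirs: M x 3; halfLen scalar or length M.
## Returns an M x 2 matrix of clipped [t1, t2] (t along dir from the
## midpoint); NA rows miss.
.lesionIntervals <- function(midpoints, dirs, halfLen, les) {
  halfLen <- .expandHalf(halfLen, nrow(midpoints))
  ct <- cos(les$theta); st <- sin(les$theta)
  px <- midpoints[, 1] - les$cx
  py <- midpoints[, 2] - les$cy
  pz <- midpoints[, 3] - les$cz
  ## world -> lesion frame (rotate by -theta about z), then scale
  qx <- (ct * px + st * py) / les$ax
  qy <- (-st * px + ct * py) / les$ay
  qz <- pz / les$az
  dx <- (ct * dirs[, 1] + st * dirs[, 2]) / les$ax
  dy <- (-st * dirs[, 1] + ct * dirs[, 2]) / les$ay
  dz <- dirs[, 3] / les$az
  A <- dx * dx + dy * dy + dz * dz
  B <- 2 * (qx * dx + qy * dy + qz * dz)
  C <- qx * qx + qy * qy + qz * qz - 1
  disc <- B * B - 4 * A * C
  out <- matrix(NA_real_, nrow(midpoints), 2)
  hit <- disc > 0 & A > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- (-B[hit] - sq) / (2 * A[hit])
    t2 <- (-B[hit] + sq) / (2 * A[hit])
    lo <- pmax(t1, -halfLen[hit])
    hi <- pmin(t2, halfLen[hit])
    keep <- hi > lo
    idx <- which(hit)[keep]
    out[idx, 1] <- lo[keep]
    out[idx, 2] <- hi[keep]
  }
  out
}

.expandHalf <- function(halfLen, m) if (length(halfLen) == 1L) rep(halfLen, m) else halfLen

## Cancer lengths (union over true lesions) for M cores at once.
## Returns list(length, longestRun) of numeric(M).
.scoreCores <- function(midpoints, dirs, halfLen, lesionTable) {
  m <- nrow(midpoints)
  halfLen <- .expandHalf(halfLen, m)
  trueLes <- lesionTable[!lesionTable$isFalseTarget, , drop = FALSE]
  total <- numeric(m)
  longest <- numeric(m)
  if (!nrow(trueLes)) return(list(length = total, longestRun = longest))
  nl <- nrow(trueLes)
  lo <- matrix(NA_real_, m, nl)
  hi <- matrix(NA_real_, m, nl)
  for (j in seq_len(nl)) {
    iv <- .lesionIntervals(midpoints, dirs, halfLen, trueLes[j, ])
    lo[, j] <- iv[, 1]
    hi[, j] <- iv[, 2]
  }
  nHits <- rowSums(!is.na(lo))
  one <- nHits == 1L
  if (any(one)) {
    j1 <- max.col(!is.na(lo[one, , drop = FALSE]), ties.method = "first")
    len1 <- hi[cbind(which(one), j1)] - lo[cbind(which(one), j1)]
    total[one] <- len1
    longest[one] <- len1
  }
  for (i in which(nHits > 1L)) {
    iv <- cbind(lo[i, ], hi[i, ])
    iv <- iv[!is.na(iv[, 1]), , drop = FALSE]
    total[i] <- .unionLength(iv)
    ## longest contiguous merged run
    o <- order(iv[, 1])
    a <- iv[o, 1]; b <- iv[o, 2]
    best <- 0; curA <- a[1]; curB <- b[1]
    for (k in seq_along(a)[-1]) {
      if (a[k] > curB) { best <- max(best, curB - curA); curA <- a[k]; curB <- b[k] }
      else curB <- max(curB, b[k])
    }
    longest[i] <- max(best, curB - curA)
  }
  list(length = total, longestRun = longest)
}

#' Exact chord length of a biopsy core through an ellipsoidal lesion
#'
#' Solves the quadratic along the needle ray and clips the intersection
#' to the effective sampling segment. Disjoint geometry returns 0.
#'
#' @param core a [BiopsyCore-class]
#' @param lesion a one-row lesion data.frame (see [makeLesion()])
#' @return intersection length in mm
#' @export
chordLengthEllipsoid <- function(core, lesion) {
  stopifnot(is(core, "BiopsyCore"))
  iv <- .lesionIntervals(matrix(core@realizedMidpoint, 1),
                         matrix(core@direction, 1),
                         core@effectiveLength / 2, lesion[1, ])
  if (is.na(iv[1, 1])) 0 else iv[1, 2] - iv[1, 1]
}

## -------- core scoring against a full model ------------------------------

#' Cancer length of one core against a model
#'
#' The cancer length is the length of the sampled segment intersected
#' with the union of the true lesions (false-positive targets contribute
#' zero), so overlapping lesions are not double counted. Both the total
#' within-union length (primary) and the longest contiguous run are
#' reported, together with per-lesion lengths. A core that misses the
#' gland entirely is valid and flagged.
#'
#' @param core a [BiopsyCore-class]
#' @param model a [ProstateModel-class] (analytic) or
#'   [VoxelModel-class] (mask sampling at a step of half the voxel
#'   spacing)
#' @param positivityThreshold minimum cancer length (mm) for the core to
#'   count as positive (default 0: any intersection)
#' @return a list with elements \code{cancerLength}, \code{longestRun},
#'   \code{perLesion} (named, true lesions only), \code{positive},
#'   \code{glandMiss}
#' @export
setGeneric("coreCancerLength", function(core, model, positivityThreshold = 0)
  standardGeneric("coreCancerLength"))

#' @rdname coreCancerLength
#' @export
setMethod("coreCancerLength", signature("BiopsyCore", "ProstateModel"),
  function(core, model, positivityThreshold = 0) {
    les <- model@lesions
    mid <- matrix(core@realizedMidpoint, 1)
    dir <- matrix(core@direction, 1)
    h <- core@effectiveLength / 2
    perLesion <- numeric(0)
    trueLes <- les[!les$isFalseTarget, , drop = FALSE]
    if (nrow(trueLes)) {
      perLesion <- vapply(seq_len(nrow(trueLes)), function(j) {
        iv <- .lesionIntervals(mid, dir, h, trueLes[j, ])
        if (is.na(iv[1, 1])) 0 else iv[1, 2] - iv[1, 1]
      }, numeric(1))
      names(perLesion) <- trueLes$id
    }
    sc <- .scoreCores(mid, dir, h, les)
    list(cancerLength = sc$length, longestRun = sc$longestRun,
         perLesion = perLesion,
         positive = sc$length > positivityThreshold,
         glandMiss = segmentInGlandLength(core, model) <= 0)
  })

## Sample points along the effective segment at `step` spacing
## (midpoint rule); returns n x 3 matrix and the step used.
.segmentSamples <- function(core, step) {
  h <- core@effectiveLength / 2
  t <- seq(-h + step / 2, h - step / 2, by = step)
  list(points = cbind(core@realizedMidpoint[1] + t * core@direction[1],
                      core@realizedMidpoint[2] + t * core@direction[2],
                      core@realizedMidpoint[3] + t * core@direction[3]),
       step = step)
}

## Trilinear interpolation of a binary mask at arbitrary points: treats
## the mask as indicator samples at voxel centres, giving a fractional
## occupancy in [0, 1]. Sub-voxel boundary localisation for length
## integration (a nearest-voxel lookup quantises every surface crossing
## by up to half a voxel).
.maskOccupancy <- function(points, origin, spacing, mask) {
  d <- dim(mask)
  u <- (points[, 1] - origin[1]) / spacing
  v <- (points[, 2] - origin[2]) / spacing
  w <- (points[, 3] - origin[3]) / spacing
  i0 <- floor(u); j0 <- floor(v); k0 <- floor(w)
  fu <- u - i0; fv <- v - j0; fw <- w - k0
  val <- numeric(nrow(points))
  at <- function(ii, jj, kk) {
    ok <- ii >= 0L & ii <= d[1] - 1L & jj >= 0L & jj <= d[2] - 1L &
      kk >= 0L & kk <= d[3] - 1L
    out <- numeric(length(ii))
    out[ok] <- mask[cbind(ii[ok] + 1L, jj[ok] + 1L, kk[ok] + 1L)]
    out
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wx <- if (di == 0) 1 - fu else fu
    wy <- if (dj == 0) 1 - fv else fv
    wz <- if (dk == 0) 1 - fw else fw
    val <- val + wx * wy * wz * at(i0 + di, j0 + dj, k0 + dk)
  }
  val
}

#' @rdname coreCancerLength
#' @export
setMethod("coreCancerLength", signature("BiopsyCore", "VoxelModel"),
  function(core, model, positivityThreshold = 0) {
    smp <- .segmentSamples(core, model@spacing / 2)
    ids <- names(model@lesionMasks)
    false <- rep(FALSE, length(ids))
    if (nrow(model@lesionMeta) && "isFalseTarget" %in% names(model@lesionMeta))
      false <- model@lesionMeta$isFalseTarget[match(ids, model@lesionMeta$id)] %in% TRUE
    occAny <- numeric(nrow(smp$points))
    perLesion <- numeric(0)
    for (j in seq_along(ids)) {
      if (false[j]) next
      occ <- .maskOccupancy(smp$points, model@origin, model@spacing,
                            model@lesionMasks[[j]])
      perLesion[ids[j]] <- sum(occ) * smp$step
      occAny <- pmax(occAny, occ)
    }
    inAny <- occAny >= 0.5
    runs <- rle(inAny)
    longest <- if (any(inAny)) max(runs$lengths[runs$values]) * smp$step else 0
    len <- sum(occAny) * smp$step
    list(cancerLength = len, longestRun = longest, perLesion = perLesion,
         positive = len > positivityThreshold,
         glandMiss = segmentInGlandLength(core, model) <= 0)
  })

#' Length of a core's effective segment inside the gland
#'
#' Quality-control metric for scheme plausibility: analytic chord
#' through the gland ellipsoid for analytic models, mask sampling for
#' voxel models.
#'
#' @param core a [BiopsyCore-class]
#' @param model a [ProstateModel-class] or [VoxelModel-class]
#' @return length in mm
#' @export
setGeneric("segmentInGlandLength", function(core, model)
  standardGeneric("segmentInGlandLength"))

#' @rdname segmentInGlandLength
#' @export
setMethod("segmentInGlandLength", signature("BiopsyCore", "ProstateModel"),
  function(core, model) {
    gland <- data.frame(cx = model@glandCentre[1], cy = model@glandCentre[2],
                        cz = model@glandCentre[3], ax = model@glandSemiAxes[1],
                        ay = model@glandSemiAxes[2], az = model@glandSemiAxes[3],
                        theta = 0)
    iv <- .lesionIntervals(matrix(core@realizedMidpoint, 1),
                           matrix(core@direction, 1),
                           core@effectiveLength / 2, gland)
    if (is.na(iv[1, 1])) 0 else iv[1, 2] - iv[1, 1]
  })

#' @rdname segmentInGlandLength
#' @export
setMethod("segmentInGlandLength", signature("BiopsyCore", "VoxelModel"),
  function(core, model) {
    smp <- .segmentSamples(core, model@spacing / 2)
    sum(.maskOccupancy(smp$points, model@origin, model@spacing,
                       model@glandMask)) * smp$step
  })
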