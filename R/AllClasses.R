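#' @import methods
#' @importFrom stats rnorm rlnorm rnbinom runif quantile sd median t.test ks.test var
NULL

## Gleason grade categories used throughout (per-lesion histologic grade)
.gleasonLevels <- c("<=6", "7", ">=8")

## Columns of the per-model lesion table. Geometry is an ellipsoid:
## centre (cx,cy,cz) mm, semi-axes (ax,ay,az) mm, rotation theta (radians)
## about the base-apex (z) axis.
.lesionCols <- c("id", "volume", "gleason", "zone", "cx", "cy", "cz",
                 "ax", "ay", "az", "theta", "isIndex", "isFalseTarget")

#' CohortSpec: parameters of the synthetic prostate cohort
#'
#' Describes the population the synthetic-cohort generator draws from:
#' gland volume, lesions per gland, index and non-index lesion volume
#' distributions (all truncated lognormal / shifted negative binomial),
#' anterior/posterior placement probabilities, Gleason mix, and the
#' fraction of targeted-biopsy sessions directed at a benign
#' (false-positive imaging) target.
#'
#' Volume distributions are lists with elements \code{meanlog},
#' \code{sdlog}, \code{min}, \code{max} (ml); the lesion-count
#' distribution is \code{list(size, mu, max)} for a count drawn as
#' 1 + negative binomial, truncated above at \code{max}.
#'
#' @slot nProstates number of cancer-bearing glands to generate
#' @slot glandVolume truncated-lognormal parameters for gland volume (ml)
#' @slot lesionCount shifted negative-binomial parameters for lesions/gland
#' @slot indexVolume truncated-lognormal parameters for index lesion volume (ml)
#' @slot nonindexVolume truncated-lognormal parameters for non-index lesion volume (ml)
#' @slot zoneProbs named probabilities for \code{anterior}/\code{posterior} placement
#' @slot gleasonProbs named probabilities over Gleason categories \code{<=6}, \code{7}, \code{>=8}
#' @slot falsePositiveRate fraction in [0,1] of targeted sessions aimed at a benign target
#' @slot seed RNG seed used by [buildCohort()]
#' @seealso [defaultCohortSpec()], [sampleProstate()], [buildCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nProstates = "numeric",
    glandVolume = "list",
    lesionCount = "list",
    indexVolume = "list",
    nonindexVolume = "list",
    zoneProbs = "numeric",
    gleasonProbs = "numeric",
    falsePositiveRate = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nProstates) != 1L || object@nProstates < 1)
    msg <- c(msg, "nProstates must be a single count >= 1")
  for (nm in c("glandVolume", "indexVolume", "nonindexVolume")) {
    d <- slot(object, nm)
    if (!all(c("meanlog", "sdlog", "min", "max") %in% names(d)))
      msg <- c(msg, sprintf("%s needs meanlog, sdlog, min, max", nm))
    else if (d$min <= 0 || d$max < d$min)
      msg <- c(msg, sprintf("%s range must satisfy 0 < min <= max", nm))
  }
  if (!all(c("size", "mu", "max") %in% names(object@lesionCount)))
    msg <- c(msg, "lesionCount needs size, mu, max")
  if (!setequal(names(object@zoneProbs), c("anterior", "posterior")) ||
      any(object@zoneProbs < 0) || any(object@zoneProbs > 1) ||
      abs(sum(object@zoneProbs) - 1) > 1e-8)
    msg <- c(msg, "zoneProbs must be probabilities over {anterior, posterior} summing to 1")
  if (!setequal(names(object@gleasonProbs), .gleasonLevels) ||
      any(object@gleasonProbs < 0) || any(object@gleasonProbs > 1) ||
      abs(sum(object@gleasonProbs) - 1) > 1e-8)
    msg <- c(msg, "gleasonProbs must be probabilities over {<=6, 7, >=8} summing to 1")
  if (object@falsePositiveRate < 0 || object@falsePositiveRate > 1)
    msg <- c(msg, "falsePositiveRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ProstateModel: a 3D gland with lesions
#'
#' The gland is an ellipsoid (semi-axes in mm: lateral, antero-posterior,
#' base-apex) centred at \code{glandCentre}; +z points from apex to base.
#' Lesions are ellipsoids described by one row each of the \code{lesions}
#' data.frame (see [lesions()]). The urethra is modelled as the line
#' x = y = 0 through the gland; \code{anusRef} anchors TRUS needle
#' trajectories.
#'
#' @slot id model identifier
#' @slot glandCentre numeric(3), mm
#' @slot glandSemiAxes numeric(3), mm (x = lateral, y = antero-posterior, z = base-apex)
#' @slot lesions data.frame, one row per lesion
#' @slot anusRef numeric(3), mm; anatomic reference for TRUS trajectories
#' @slot baseApexAxis unit numeric(3); +z by construction
#' @export
setClass("ProstateModel",
  representation(
    id = "character",
    glandCentre = "numeric",
    glandSemiAxes = "numeric",
    lesions = "data.frame",
    anusRef = "numeric",
    baseApexAxis = "numeric"
  )
)

setValidity("ProstateModel", function(object) {
  msg <- character()
  if (length(object@glandCentre) != 3L) msg <- c(msg, "glandCentre must be length 3")
  if (length(object@glandSemiAxes) != 3L || any(object@glandSemiAxes <= 0))
    msg <- c(msg, "glandSemiAxes must be 3 positive lengths (mm)")
  les <- object@lesions
  if (nrow(les)) {
    if (!all(.lesionCols %in% names(les)))
      msg <- c(msg, "lesions table is missing required columns")
    else {
      if (any(les$volume <= 0)) msg <- c(msg, "lesion volumes must be positive")
      ell <- 4 / 3 * pi * les$ax * les$ay * les$az / 1000
      if (any(abs(ell - les$volume) > 1e-6 * les$volume))
        msg <- c(msg, "lesion volume must equal its ellipsoid volume (1e-6 rel. tol.)")
      true <- !les$isFalseTarget
      if (sum(true) > 0 && sum(les$isIndex[true]) != 1L)
        msg <- c(msg, "exactly one true lesion must be flagged as index")
      if (any(les$isIndex & les$isFalseTarget))
        msg <- c(msg, "a false target cannot be the index lesion")
      if (sum(les$volume[true]) > glandVolume(object))
        msg <- c(msg, "total true-lesion volume exceeds gland volume")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ContourStack: step-section contours of a gland
#'
#' The histology-derived representation: one polygon set per 5-mm slice.
#' Axial positions are measured from the base toward the apex (slice
#' index times thickness), so they are strictly increasing in stack
#' order. Each slice is \code{list(position = mm, structures = named
#' list)} where each structure is an N x 2 matrix of (x, y) vertices in
#' mm, counter-clockwise, implicitly closed. Structure labels are
#' \code{"capsule"} or \code{"lesion:<id>"}.
#'
#' @slot sliceThickness slice spacing, mm
#' @slot slices ordered list of slices (base first)
#' @slot notes character; e.g. structures thinner than one slice that
#'   produced no contour
#' @export
setClass("ContourStack",
  representation(
    sliceThickness = "numeric",
    slices = "list",
    notes = "character"
  )
)

setValidity("ContourStack", function(object) {
  msg <- character()
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive length (mm)")
  pos <- vapply(object@slices, function(s) s$position, numeric(1))
  if (length(pos) >= 2L) {
    dp <- diff(pos)
    if (any(dp <= 0)) msg <- c(msg, "axial positions must be strictly increasing")
    else if (any(abs(dp - object@sliceThickness) > 1e-6))
      msg <- c(msg, "axial spacing must equal sliceThickness")
  }
  for (s in object@slices) {
    for (p in s$structures) {
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
        msg <- c(msg, "every contour must be an N x 2 matrix with N >= 3")
        break
      }
      if (.polygonSelfIntersects(p)) {
        msg <- c(msg, "contours must be simple (non-self-intersecting) polygons")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' VoxelModel: reconstructed gland on an isotropic voxel grid
#'
#' @slot origin numeric(3): centre of the first voxel, mm
#' @slot spacing isotropic voxel edge, mm
#' @slot glandMask 3D logical array
#' @slot lesionMasks named list of 3D logical arrays (same grid)
#' @slot lesionMeta data.frame carrying per-lesion metadata (gleason,
#'   isFalseTarget) when known; may be empty
#' @export
setClass("VoxelModel",
  representation(
    origin = "numeric",
    spacing = "numeric",
    glandMask = "array",
    lesionMasks = "list",
    lesionMeta = "data.frame"
  )
)

setValidity("VoxelModel", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive length (mm)")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
  d <- dim(object@glandMask)
  if (length(d) != 3L) msg <- c(msg, "glandMask must be a 3D array")
  for (m in object@lesionMasks)
    if (!identical(dim(m), d)) { msg <- c(msg, "lesion masks must share the gland grid"); break }
  if (length(msg)) msg else TRUE
})

#' BiopsyCore: one needle sampling segment
#'
#' The sampled segment is \code{realizedMidpoint +/- (effectiveLength/2) *
#' direction}; targeting error displaces the midpoint only (pure
#' translation, direction preserved).
#'
#' @slot entry numeric(3), mm
#' @slot direction unit numeric(3)
#' @slot effectiveLength sampling-notch length, mm
#' @slot plannedMidpoint numeric(3), mm
#' @slot realizedMidpoint numeric(3), mm (equals planned until an error is applied)
#' @export
setClass("BiopsyCore",
  representation(
    entry = "numeric",
    direction = "numeric",
    effectiveLength = "numeric",
    plannedMidpoint = "numeric",
    realizedMidpoint = "numeric"
  )
)

setValidity("BiopsyCore", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msg <- c(msg, "direction must be a unit vector (1e-9 tol.)")
  if (object@effectiveLength <= 0)
    msg <- c(msg, "effectiveLength must be positive")
  if (length(msg)) msg else TRUE
})

#' TemplateGrid: 5-mm transperineal brachytherapy template
#'
#' Grid coordinates are (column, row) in template convention: columns are
#' letters A, B, C, ... spaced \code{spacing} mm along x; rows are
#' numbers spaced \code{spacing} mm along y. The urethra is anchored at
#' column D, row 2.0, i.e. grid (D, 2.0) maps to the urethra position
#' (x = 0, y = 0). Needles travel along +z (the perineal/base-apex
#' axis).
#'
#' @slot spacing lattice spacing, mm (default 5)
#' @slot anchor numeric(2): (x, y) of the D2.0 grid position, mm
#' @slot direction unit numeric(3): needle direction
#' @export
setClass("TemplateGrid",
  representation(
    spacing = "numeric",
    anchor = "numeric",
    direction = "numeric"
  )
)

setValidity("TemplateGrid", function(object) {
  msg <- character()
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (length(object@anchor) != 2L) msg <- c(msg, "anchor must be length 2")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msg <- c(msg, "direction must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' BiopsyPlan: planned core placements for one strategy
#'
#' @slot strategy label: \code{"TRUS12"} or \code{"TARGETED_k"}, k = 1..5
#' @slot cores data.frame, one row per planned core: midpoint (midX..Z),
#'   direction (dirX..Z), effectiveLength, and for targeted plans the
#'   template coordinates (gridCol letter offset, gridRow)
#' @slot targetId id of the lesion the plan aims at (targeted plans)
#' @export
setClass("BiopsyPlan",
  representation(
    strategy = "character",
    cores = "data.frame",
    targetId = "character"
  )
)

setValidity("BiopsyPlan", function(object) {
  msg <- character()
  k <- .strategyCores(object@strategy)
  if (!is.na(k) && nrow(object@cores) != k)
    msg <- c(msg, sprintf("strategy %s requires %d cores, got %d",
                          object@strategy, k, nrow(object@cores)))
  need <- c("midX", "midY", "midZ", "dirX", "dirY", "dirZ", "effectiveLength")
  if (!all(need %in% names(object@cores)))
    msg <- c(msg, "cores table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' ErrorModel: needle targeting error
#'
#' All error components are zero-mean normal in three orthogonal
#' directions. In the default \code{"combined"} mode a single total
#' displacement is sampled with per-axis variance \code{totalSd^2 / 3},
#' so the summed per-axis variance equals \code{totalSd^2} (default 25
#' mm^2). In \code{"components"} mode a deflection draw (per-axis SD
#' \code{deflectionSd}) and -- for targeted cores, or all cores when
#' \code{applyRegistrationTo = "all"} -- a registration draw (per-axis
#' SD \code{registrationSd}) are summed and rescaled so the summed
#' per-axis variance again equals \code{totalSd^2}.
#'
#' @slot deflectionSd per-axis SD of needle deflection, mm (default 3)
#' @slot registrationSd per-axis SD of image-fusion registration error, mm (default 3)
#' @slot totalSd total displacement scale, mm: the sampled displacement's
#'   per-axis variances sum to \code{totalSd^2} (default 5)
#' @slot mode \code{"combined"} or \code{"components"}
#' @slot applyRegistrationTo \code{"targeted_only"} or \code{"all"}
#' @slot varianceAccounting how the set total variance
#'   \code{totalSd^2} is read: \code{"summed"} (default) spreads it
#'   over the three axes (per-axis variance \code{totalSd^2/3});
#'   \code{"per_axis"} applies it to each direction (per-axis SD
#'   \code{totalSd}), the reading under which a 3 mm-per-direction
#'   deflection and 3 mm registration error add to 18 mm^2 per
#'   direction against a set total of 25 mm^2
#' @export
setClass("ErrorModel",
  representation(
    deflectionSd = "numeric",
    registrationSd = "numeric",
    totalSd = "numeric",
    mode = "character",
    applyRegistrationTo = "character",
    varianceAccounting = "character"
  )
)

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (object@deflectionSd < 0 || object@registrationSd < 0 || object@totalSd < 0)
    msg <- c(msg, "all SDs must be >= 0")
  if (!object@mode %in% c("combined", "components"))
    msg <- c(msg, "mode must be 'combined' or 'components'")
  if (!object@applyRegistrationTo %in% c("targeted_only", "all"))
    msg <- c(msg, "applyRegistrationTo must be 'targeted_only' or 'all'")
  if (!object@varianceAccounting %in% c("summed", "per_axis"))
    msg <- c(msg, "varianceAccounting must be 'summed' or 'per_axis'")
  if (length(msg)) msg else TRUE
})

#' RiskCriteria: biopsy risk stratification rule
#'
#' A session is high risk when MCCL >= \code{mcclThreshold} mm and/or
#' the percentage of positive cores >= \code{pctPositiveThreshold}.
#'
#' @slot mcclThreshold mm (default 6)
#' @slot pctPositiveThreshold percent (default 50)
#' @export
setClass("RiskCriteria",
  representation(mcclThreshold = "numeric", pctPositiveThreshold = "numeric")
)

setValidity("RiskCriteria", function(object) {
  if (object@mcclThreshold < 0 || object@pctPositiveThreshold < 0)
    "thresholds must be >= 0" else TRUE
})

#' SignificanceCriteria: clinically significant disease definition
#'
#' A case is clinically significant when any true lesion has volume >=
#' \code{volumeThreshold} ml and/or Gleason grade >=
#' \code{gleasonThreshold}.
#'
#' @slot volumeThreshold ml (default 0.5)
#' @slot gleasonThreshold lowest significant Gleason category (default "7")
#' @export
setClass("SignificanceCriteria",
  representation(volumeThreshold = "numeric", gleasonThreshold = "character")
)

setValidity("SignificanceCriteria", function(object) {
  msg <- character()
  if (object@volumeThreshold <= 0) msg <- c(msg, "volumeThreshold must be positive")
  if (!object@gleasonThreshold %in% .gleasonLevels)
    msg <- c(msg, "gleasonThreshold must be one of <=6, 7, >=8")
  if (length(msg)) msg else TRUE
})

## ---- constructors -------------------------------------------------------

#' @describeIn RiskCriteria-class constructor
#' @param mcclThreshold mm
#' @param pctPositiveThreshold percent
#' @export
riskCriteria <- function(mcclThreshold = 6, pctPositiveThreshold = 50) {
  new("RiskCriteria", mcclThreshold = mcclThreshold,
      pctPositiveThreshold = pctPositiveThreshold)
}

#' @describeIn SignificanceCriteria-class constructor
#' @param volumeThreshold ml
#' @param gleasonThreshold lowest significant Gleason category
#' @export
significanceCriteria <- function(volumeThreshold = 0.5, gleasonThreshold = "7") {
  new("SignificanceCriteria", volumeThreshold = volumeThreshold,
      gleasonThreshold = gleasonThreshold)
}

#' @describeIn ErrorModel-class constructor
#' @param deflectionSd,registrationSd,totalSd mm
#' @param mode sampling mode
#' @param applyRegistrationTo which cores receive registration error
#'   (components mode)
#' @param varianceAccounting \code{"summed"} or \code{"per_axis"} (see
#'   slot documentation)
#' @export
errorModel <- function(deflectionSd = 3, registrationSd = 3, totalSd = 5,
                       mode = c("combined", "components"),
                       applyRegistrationTo = c("targeted_only", "all"),
                       varianceAccounting = c("summed", "per_axis")) {
  new("ErrorModel", deflectionSd = deflectionSd, registrationSd = registrationSd,
      totalSd = totalSd, mode = match.arg(mode),
      applyRegistrationTo = match.arg(applyRegistrationTo),
      varianceAccounting = match.arg(varianceAccounting))
}

#' @describeIn TemplateGrid-class constructor
#' @param spacing lattice spacing, mm
#' @param anchor (x, y) of the D2.0 position, mm
#' @param direction needle direction (unit vector)
#' @export
templateGrid <- function(spacing = 5, anchor = c(0, 0), direction = c(0, 0, 1)) {
  new("TemplateGrid", spacing = spacing, anchor = anchor,
      direction = direction / sqrt(sum(direction^2)))
}

#' @describeIn BiopsyCore-class constructor. The entry point is placed at
#'   the proximal end of the effective segment.
#' @param midpoint planned midpoint, mm
#' @param direction needle direction (normalised internally)
#' @param effectiveLength sampling-notch length, mm
#' @export
biopsyCore <- function(midpoint, direction, effectiveLength = 17) {
  d <- direction / sqrt(sum(direction^2))
  new("BiopsyCore", entry = midpoint - d * effectiveLength / 2,
      direction = d, effectiveLength = effectiveLength,
      plannedMidpoint = midpoint, realizedMidpoint = midpoint)
}

## ---- accessors & show ---------------------------------------------------

#' Gland volume in ml
#' @param object a ProstateModel or VoxelModel
#' @export
setGeneric("glandVolume", function(object) standardGeneric("glandVolume"))

#' @rdname glandVolume
#' @export
setMethod("glandVolume", "ProstateModel", function(object) {
  4 / 3 * pi * prod(object@glandSemiAxes) / 1000
})

#' @rdname glandVolume
#' @export
setMethod("glandVolume", "VoxelModel", function(object) {
  sum(object@glandMask) * object@spacing^3 / 1000
})

#' Lesion table of a model
#' @param object a ProstateModel
#' @export
setGeneric("lesions", function(object) standardGeneric("lesions"))

#' @rdname lesions
#' @export
setMethod("lesions", "ProstateModel", function(object) object@lesions)

#' Number of slices in a contour stack
#' @param object a ContourStack
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))

#' @rdname nSlices
#' @export
setMethod("nSlices", "ContourStack", function(object) length(object@slices))

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nProstates, "cancer-bearing glands\n")
  cat(sprintf("  gland volume lognormal(meanlog=%.3f, sdlog=%.3f) on [%.1f, %.1f] ml\n",
              object@glandVolume$meanlog, object@glandVolume$sdlog,
              object@glandVolume$min, object@glandVolume$max))
  cat(sprintf("  lesions/gland 1 + NB(size=%g, mu=%g), max %d\n",
              object@lesionCount$size, object@lesionCount$mu,
              as.integer(object@lesionCount$max)))
  cat(sprintf("  false-positive target rate %.2f, seed %d\n",
              object@falsePositiveRate, as.integer(object@seed)))
})

setMethod("show", "ProstateModel", function(object) {
  les <- object@lesions
  cat(sprintf("ProstateModel '%s': gland %.1f ml (semi-axes %.1f x %.1f x %.1f mm)\n",
              object@id, glandVolume(object), object@glandSemiAxes[1],
              object@glandSemiAxes[2], object@glandSemiAxes[3]))
  cat(sprintf("  %d lesion(s): %d true, %d benign target(s)\n",
              nrow(les), sum(!les$isFalseTarget), sum(les$isFalseTarget)))
})

setMethod("show", "ContourStack", function(object) {
  cat(sprintf("ContourStack: %d slice(s) at %.1f mm\n",
              length(object@slices), object@sliceThickness))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "VoxelModel", function(object) {
  d <- dim(object@glandMask)
  cat(sprintf("VoxelModel: %d x %d x %d voxels at %.2f mm, gland %.1f ml, %d lesion mask(s)\n",
              d[1], d[2], d[3], object@spacing, glandVolume(object),
              length(object@lesionMasks)))
})

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf("ErrorModel (%s): total SD %.1f mm (per-axis var %.2f mm^2); deflection %.1f, registration %.1f mm per axis\n",
              object@mode, object@totalSd, object@totalSd^2 / 3,
              object@deflectionSd, object@registrationSd))
})

setMethod("show", "BiopsyPlan", function(object) {
  cat(sprintf("BiopsyPlan %s: %d core(s)%s\n", object@strategy, nrow(object@cores),
              if (length(object@targetId)) paste0(", target ", object@targetId) else ""))
})
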