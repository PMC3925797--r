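## 3D reconstruction from step-section contours: rigid slice alignment,
## shape-based (signed-distance) inter-slice interpolation, and isotropic
## shrinkage correction.

#' Align contour slices to the midgland reference
#'
#' Rigidly translates each slice in-plane so that capsule centroids
#' chain-align to the midgland reference slice, taken as the slice whose
#' capsule area is maximal. Relative structure positions within a slice
#' are preserved (the whole slice shares one translation). Slices with
#' no capsule contour are flagged in \code{notes} and receive a
#' translation interpolated from the nearest contoured slices.
#'
#' @param stack a [ContourStack-class]
#' @return the aligned [ContourStack-class]
#' @export
alignSlices <- function(stack) {
  stopifnot(is(stack, "ContourStack"), length(stack@slices) >= 1L)
  slices <- stack@slices
  n <- length(slices)
  hasCapsule <- vapply(slices, function(s) "capsule" %in% names(s$structures),
                       logical(1))
  if (!any(hasCapsule)) stop("no slice carries a capsule contour")
  areas <- rep(-Inf, n)
  cents <- matrix(NA_real_, n, 2)
  for (i in which(hasCapsule)) {
    cap <- slices[[i]]$structures$capsule
    areas[i] <- abs(.polygonArea(cap))
    cents[i, ] <- .polygonCentroid(cap)
  }
  ref <- which.max(areas)
  shifts <- matrix(NA_real_, n, 2)
  shifts[hasCapsule, 1] <- cents[ref, 1] - cents[hasCapsule, 1]
  shifts[hasCapsule, 2] <- cents[ref, 2] - cents[hasCapsule, 2]
  notes <- stack@notes
  if (any(!hasCapsule)) {
    idx <- which(hasCapsule)
    for (i in which(!hasCapsule)) {
      shifts[i, 1] <- stats::approx(idx, shifts[idx, 1], i, rule = 2)$y
      shifts[i, 2] <- stats::approx(idx, shifts[idx, 2], i, rule = 2)$y
      notes <- c(notes, sprintf(
        "slice %d has no capsule contour: translation interpolated", i))
    }
  }
  for (i in seq_len(n)) {
    slices[[i]]$structures <- lapply(slices[[i]]$structures, function(p)
      cbind(p[, 1] + shifts[i, 1], p[, 2] + shifts[i, 2]))
  }
  new("ContourStack", sliceThickness = stack@sliceThickness,
      slices = slices, notes = notes)
}

## SDFs of one structure on the slice planes where it appears, plus
## phantom end slices one thickness beyond each end carrying
## (end SDF - thickness) so the shape tapers at ~45 degrees.
.structureSdfStack <- function(slices, label, px, py, thickness) {
  present <- which(vapply(slices, function(s) label %in% names(s$structures),
                          logical(1)))
  if (!length(present)) return(NULL)
  runs <- split(present, cumsum(c(1, diff(present) != 1L)))
  if (length(runs) > 1L)
    warning("structure '", label, "' present on non-adjacent slices; ",
            "treated as separate components")
  pieces <- lapply(runs, function(idx) {
    pos <- vapply(slices[idx], function(s) s$position, numeric(1))
    sdf <- lapply(slices[idx], function(s)
      .polygonSdf(cbind(px, py), s$structures[[label]]))
    list(pos = c(pos[1] - thickness, pos, pos[length(pos)] + thickness),
         sdf = c(list(sdf[[1]] - thickness), sdf,
                 list(sdf[[length(sdf)]] - thickness)))
  })
  pieces
}

#' Shape-based interpolation of a contour stack to a voxel model
#'
#' Per structure, a signed distance field (positive inside) is computed
#' on each slice where the structure appears and linearly interpolated
#' along the axial direction; the positive level set defines the voxel
#' mask, so masks at the original slice positions reproduce the input
#' polygons to within one voxel. Beyond a structure's first and last
#' contoured slice, the field is tapered over one slice thickness, which
#' closes the shape with an approximately 45-degree cap. A structure
#' present only on non-adjacent slices is interpolated as separate
#' components with a warning.
#'
#' @param stack an aligned [ContourStack-class]
#' @param spacing isotropic voxel edge, mm; must not exceed the slice
#'   thickness (default 0.5)
#' @return a [VoxelModel-class]
#' @export
interpolateShape <- function(stack, spacing = 0.5) {
  stopifnot(is(stack, "ContourStack"), spacing > 0,
            spacing <= stack@sliceThickness)
  slices <- stack@slices
  t <- stack@sliceThickness
  allPts <- do.call(rbind, unlist(lapply(slices, function(s) s$structures),
                                  recursive = FALSE))
  margin <- 2 * spacing + 1
  xs <- seq(min(allPts[, 1]) - margin, max(allPts[, 1]) + margin, by = spacing)
  ys <- seq(min(allPts[, 2]) - margin, max(allPts[, 2]) + margin, by = spacing)
  pos <- vapply(slices, function(s) s$position, numeric(1))
  zs <- seq(pos[1] - t, pos[length(pos)] + t, by = spacing)
  grid <- expand.grid(x = xs, y = ys)
  labels <- unique(unlist(lapply(slices, function(s) names(s$structures))))
  masks <- list()
  for (label in labels) {
    pieces <- .structureSdfStack(slices, label, grid$x, grid$y, t)
    mask <- array(FALSE, dim = c(length(xs), length(ys), length(zs)))
    for (pc in pieces) {
      for (k in seq_along(zs)) {
        z <- zs[k]
        if (z < pc$pos[1] || z > pc$pos[length(pc$pos)]) next
        j <- findInterval(z, pc$pos, rightmost.closed = TRUE)
        w <- (z - pc$pos[j]) / (pc$pos[j + 1] - pc$pos[j])
        sdf <- (1 - w) * pc$sdf[[j]] + w * pc$sdf[[j + 1]]
        mask[, , k] <- mask[, , k] | matrix(sdf > 0, length(xs), length(ys))
      }
    }
    masks[[label]] <- mask
  }
  lesionMasks <- masks[grep("^lesion:", names(masks))]
  names(lesionMasks) <- sub("^lesion:", "", names(lesionMasks))
  glandMask <- masks[["capsule"]]
  if (is.null(glandMask))
    glandMask <- array(FALSE, dim = c(length(xs), length(ys), length(zs)))
  new("VoxelModel", origin = c(xs[1], ys[1], zs[1]), spacing = spacing,
      glandMask = glandMask, lesionMasks = lesionMasks,
      lesionMeta = data.frame())
}

#' Reverse isotropic fixation shrinkage
#'
#' Scales all coordinates about the model origin by \code{factor}
#' (default 1.10, the fixation correction), so volumes scale by exactly
#' \code{factor^3} (1.331, i.e. a 33% volume increase at the default).
#'
#' @param model a [VoxelModel-class] or [ProstateModel-class]
#' @param factor linear scale factor; values below 1 shrink the model
#'   (permitted, with a warning, for round-trip use)
#' @return the rescaled model
#' @export
setGeneric("correctShrinkage", function(model, factor = 1.10)
  standardGeneric("correctShrinkage"))

.checkShrinkFactor <- function(factor) {
  if (factor <= 0) stop("shrinkage factor must be positive")
  if (factor < 1) warning("shrinkage factor below 1 shrinks the model")
}

#' @rdname correctShrinkage
#' @export
setMethod("correctShrinkage", "VoxelModel", function(model, factor = 1.10) {
  .checkShrinkFactor(factor)
  initialize(model, origin = model@origin * factor,
             spacing = model@spacing * factor)
})

#' @rdname correctShrinkage
#' @export
setMethod("correctShrinkage", "ProstateModel", function(model, factor = 1.10) {
  .checkShrinkFactor(factor)
  les <- model@lesions
  if (nrow(les)) {
    for (col in c("cx", "cy", "cz", "ax", "ay", "az")) les[[col]] <- les[[col]] * factor
    les$volume <- les$volume * factor^3
  }
  initialize(model, glandCentre = model@glandCentre * factor,
             glandSemiAxes = model@glandSemiAxes * factor,
             anusRef = model@anusRef * factor, lesions = les)
})

#' Lesion inventory of a model
#'
#' Volumes per lesion with the index flag (largest true lesion), ordered
#' by volume descending then id. For voxel models volumes are mask
#' voxel counts times the voxel volume.
#'
#' @param model a [VoxelModel-class] or [ProstateModel-class]
#' @return data.frame with columns \code{id}, \code{volumeMl},
#'   \code{isIndex}; empty for models without lesions
#' @export
setGeneric("lesionInventory", function(model) standardGeneric("lesionInventory"))

.orderInventory <- function(inv) {
  if (!nrow(inv)) return(inv)
  inv <- inv[order(-inv$volumeMl, inv$id), , drop = FALSE]
  rownames(inv) <- NULL
  inv
}

#' @rdname lesionInventory
#' @export
setMethod("lesionInventory", "VoxelModel", function(model) {
  ids <- names(model@lesionMasks)
  vols <- vapply(model@lesionMasks, function(m) sum(m) * model@spacing^3 / 1000,
                 numeric(1))
  false <- rep(FALSE, length(ids))
  if (nrow(model@lesionMeta) && "isFalseTarget" %in% names(model@lesionMeta))
    false <- model@lesionMeta$isFalseTarget[match(ids, model@lesionMeta$id)] %in% TRUE
  inv <- data.frame(id = ids, volumeMl = unname(vols), isIndex = FALSE,
                    stringsAsFactors = FALSE)
  trueIdx <- which(!false)
  if (length(trueIdx))
    inv$isIndex[trueIdx[which.max(inv$volumeMl[trueIdx])]] <- TRUE
  .orderInventory(inv)
})

#' @rdname lesionInventory
#' @export
setMethod("lesionInventory", "ProstateModel", function(model) {
  les <- model@lesions
  inv <- data.frame(id = les$id, volumeMl = les$volume, isIndex = les$isIndex,
                    stringsAsFactors = FALSE)
  .orderInventory(inv)
})
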