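## Emission of step-section contour stacks from analytic models.

## Cross-section of a lesion ellipsoid with the plane z = z0 (rotation
## about z only, so the section is an exact ellipse). NULL if disjoint.
.lesionSection <- function(les, z0, nVertices) {
  w <- (z0 - les$cz) / les$az
  if (abs(w) >= 1) return(NULL)
  s <- sqrt(1 - w^2)
  .ellipsePolygon(c(les$cx, les$cy), les$ax * s, les$ay * s,
                  theta = les$theta, n = nVertices)
}

#' Emit a step-section contour stack from a prostate model
#'
#' Slices the gland perpendicular to the base-apex axis at
#' \code{sliceThickness} spacing (slice planes centred on the gland, so
#' at least one slice is always produced), emitting the capsule
#' cross-section and the cross-section of every lesion the plane cuts.
#' Axial stack positions run from the base toward the apex. Lesions
#' thinner than one slice can fall between slice planes; these are
#' reported in the stack's \code{notes} and by a warning, never
#' silently dropped.
#'
#' @param model a [ProstateModel-class]
#' @param sliceThickness slice spacing, mm (default 5, the step-section
#'   protocol)
#' @param nVertices vertices per polygon contour
#' @return a [ContourStack-class]
#' @export
emitContourStack <- function(model, sliceThickness = 5, nVertices = 64L) {
  stopifnot(is(model, "ProstateModel"), sliceThickness > 0)
  ax <- model@glandSemiAxes
  gc <- model@glandCentre
  n <- max(1L, ceiling(2 * ax[3] / sliceThickness))
  ## model-frame slice planes, base (+z) first, centred on the gland
  zPlanes <- gc[3] + ((n - 1) / 2 - (seq_len(n) - 1)) * sliceThickness
  les <- model@lesions
  seen <- character(0)
  slices <- vector("list", n)
  for (i in seq_len(n)) {
    z0 <- zPlanes[i]
    s <- sqrt(max(0, 1 - ((z0 - gc[3]) / ax[3])^2))
    structures <- list(
      capsule = .ellipsePolygon(gc[1:2], ax[1] * s, ax[2] * s, n = nVertices))
    for (j in seq_len(nrow(les))) {
      poly <- .lesionSection(les[j, ], z0, nVertices)
      if (!is.null(poly)) {
        structures[[paste0("lesion:", les$id[j])]] <- poly
        seen <- union(seen, les$id[j])
      }
    }
    slices[[i]] <- list(position = (i - 1) * sliceThickness,
                        structures = structures)
  }
  missed <- setdiff(les$id, seen)
  notes <- character(0)
  if (length(missed)) {
    notes <- sprintf("lesion %s thinner than one slice: no contour emitted", missed)
    warning("lesion(s) not captured by any slice plane: ",
            paste(missed, collapse = ", "))
  }
  new("ContourStack", sliceThickness = sliceThickness, slices = slices,
      notes = notes)
}
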