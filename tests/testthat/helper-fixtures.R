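# Fixtures built in code: analytic shapes with known volumes/chords.

sphereVolumeMl <- function(r) 4 / 3 * pi * r^3 / 1000

# A spherical lesion of radius r (mm) at `centre`.
sphereLesion <- function(id, r, centre = c(0, 0, 0), ...) {
  makeLesion(id, sphereVolumeMl(r), centre = centre, aspect = c(1, 1, 1), ...)
}

# A spherical gland of radius r with one optional lesion table.
sphereGland <- function(r = 25, lesions = NULL, id = "fix") {
  if (is.null(lesions)) lesions <- makeLesion("x", 1)[0, ]
  prostateModel(id, glandSemiAxes = c(r, r, r), lesions = lesions)
}

# Direct analytic voxelization of a model (independent of the
# contour/interpolation path): voxel centre inside the ellipsoid test.
voxelizeModel <- function(model, spacing = 0.5, pad = 2) {
  ax <- model@glandSemiAxes
  gc <- model@glandCentre
  xs <- seq(gc[1] - ax[1] - pad, gc[1] + ax[1] + pad, by = spacing)
  ys <- seq(gc[2] - ax[2] - pad, gc[2] + ax[2] + pad, by = spacing)
  zs <- seq(gc[3] - ax[3] - pad, gc[3] + ax[3] + pad, by = spacing)
  g <- expand.grid(x = xs, y = ys, z = zs)
  insideEllipsoid <- function(cx, cy, cz, a, b, c, theta = 0) {
    px <- g$x - cx; py <- g$y - cy; pz <- g$z - cz
    qx <- cos(theta) * px + sin(theta) * py
    qy <- -sin(theta) * px + cos(theta) * py
    array((qx / a)^2 + (qy / b)^2 + (pz / c)^2 <= 1,
          dim = c(length(xs), length(ys), length(zs)))
  }
  gm <- insideEllipsoid(gc[1], gc[2], gc[3], ax[1], ax[2], ax[3])
  lm <- list()
  les <- model@lesions
  for (i in seq_len(nrow(les)))
    lm[[les$id[i]]] <- insideEllipsoid(les$cx[i], les$cy[i], les$cz[i],
                                       les$ax[i], les$ay[i], les$az[i],
                                       les$theta[i])
  meta <- if (nrow(les))
    data.frame(id = les$id, isFalseTarget = les$isFalseTarget) else data.frame()
  new("VoxelModel", origin = c(xs[1], ys[1], zs[1]), spacing = spacing,
      glandMask = gm, lesionMasks = lm, lesionMeta = meta)
}

# Dense point-sampling oracle for segment-in-ellipsoid length.
denseChordOracle <- function(core, les, step = 0.05) {
  h <- core@effectiveLength / 2
  t <- seq(-h + step / 2, h - step / 2, by = step)
  p <- cbind(core@realizedMidpoint[1] + t * core@direction[1],
             core@realizedMidpoint[2] + t * core@direction[2],
             core@realizedMidpoint[3] + t * core@direction[3])
  px <- p[, 1] - les$cx; py <- p[, 2] - les$cy; pz <- p[, 3] - les$cz
  qx <- cos(les$theta) * px + sin(les$theta) * py
  qy <- -sin(les$theta) * px + cos(les$theta) * py
  sum((qx / les$ax)^2 + (qy / les$ay)^2 + (pz / les$az)^2 <= 1) * step
}

# A degenerate spec: fixed gland volume, exactly one lesion of fixed
# volume (all distributions collapsed).
degenerateSpec <- function(glandMl = 50, lesionMl = 1, seed = 1) {
  spec <- defaultCohortSpec(nProstates = 1, falsePositiveRate = 0, seed = seed)
  spec@glandVolume <- list(meanlog = log(glandMl), sdlog = 0,
                           min = glandMl, max = glandMl)
  spec@lesionCount <- list(size = 1, mu = 0, max = 1)
  spec@indexVolume <- list(meanlog = log(lesionMl), sdlog = 0,
                           min = lesionMl, max = lesionMl)
  spec
}
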