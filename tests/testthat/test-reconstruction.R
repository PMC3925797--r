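test_that("an already centred stack aligns to itself", {
  st <- emitContourStack(sphereGland(r = 10), sliceThickness = 5)
  al <- alignSlices(st)
  for (i in seq_along(st@slices))
    expect_equal(al@slices[[i]]$structures$capsule,
                 unname(st@slices[[i]]$structures$capsule), tolerance = 1e-9)
})

test_that("a constructed in-plane offset is inverted exactly", {
  # r = 12 gives five slices with a unique maximal-area (midgland) slice
  st <- emitContourStack(sphereGland(r = 12), sliceThickness = 5)
  shifted <- st
  shifted@slices[[2]]$structures <- lapply(
    shifted@slices[[2]]$structures,
    function(p) cbind(p[, 1] + 3, p[, 2] - 2))
  al <- alignSlices(shifted)
  expect_equal(al@slices[[2]]$structures$capsule,
               unname(st@slices[[2]]$structures$capsule), tolerance = 1e-9)
})

test_that("jittered slices re-align to a collinear centroid axis", {
  set.seed(5)
  st <- emitContourStack(sphereGland(r = 12), sliceThickness = 5)
  jit <- st
  for (i in seq_along(jit@slices)) {
    dxy <- runif(2, -3, 3)
    jit@slices[[i]]$structures <- lapply(jit@slices[[i]]$structures,
      function(p) cbind(p[, 1] + dxy[1], p[, 2] + dxy[2]))
  }
  al <- alignSlices(jit)
  cents <- t(vapply(al@slices, function(s)
    BiopsySim:::.polygonCentroid(s$structures$capsule), numeric(2)))
  spread <- max(abs(sweep(cents, 2, cents[1, ])))
  expect_lt(spread, 0.1)
})

test_that("translation-invariant stacks interpolate to a cylinder", {
  circ <- BiopsySim:::.ellipsePolygon(c(0, 0), 10, 10, n = 64)
  st <- new("ContourStack", sliceThickness = 5,
            slices = list(list(position = 0, structures = list(capsule = circ)),
                          list(position = 5, structures = list(capsule = circ))),
            notes = character(0))
  vm <- interpolateShape(st, spacing = 1)
  zs <- vm@origin[3] + (seq_len(dim(vm@glandMask)[3]) - 1)
  atZ <- function(z) vm@glandMask[, , which.min(abs(zs - z))]
  expect_identical(atZ(2.5), atZ(0))
  expect_identical(atZ(2.5), atZ(5))
})

test_that("signed-distance blending halves a shrinking circle mid-slice", {
  cap <- BiopsySim:::.ellipsePolygon(c(0, 0), 14, 14, n = 64)
  big <- BiopsySim:::.ellipsePolygon(c(0, 0), 10, 10, n = 64)
  tiny <- BiopsySim:::.ellipsePolygon(c(0, 0), 0.5, 0.5, n = 64)
  st <- new("ContourStack", sliceThickness = 5,
            slices = list(
              list(position = 0, structures = list(capsule = cap, `lesion:L` = big)),
              list(position = 5, structures = list(capsule = cap, `lesion:L` = tiny))),
            notes = character(0))
  vm <- interpolateShape(st, spacing = 0.5)
  zs <- vm@origin[3] + (seq_len(dim(vm@glandMask)[3]) - 1) * 0.5
  mid <- vm@lesionMasks$L[, , which.min(abs(zs - 2.5))]
  rEq <- sqrt(sum(mid) * 0.5^2 / pi)
  expect_equal(rEq, (10 + 0.5) / 2, tolerance = 0.05)
})

test_that("a sliced sphere reconstructs its analytic volume within 5%", {
  st <- emitContourStack(sphereGland(r = 10), sliceThickness = 5)
  vm <- interpolateShape(alignSlices(st), spacing = 0.5)
  expect_lt(abs(glandVolume(vm) - 4.18879) / 4.18879, 0.05)
})

test_that("volume change under spacing refinement shrinks monotonically", {
  st <- emitContourStack(sphereGland(r = 10), sliceThickness = 5)
  v <- vapply(c(2.5, 1.25, 0.625), function(s)
    glandVolume(interpolateShape(st, spacing = s)), numeric(1))
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]))
})

test_that("shrinkage correction is exactly multiplicative and invertible", {
  les <- sphereLesion("L1", 5, centre = c(5, 0, 0), isIndex = TRUE)
  m <- sphereGland(r = 20, lesions = les)
  vm <- voxelizeModel(m, spacing = 1)
  up <- correctShrinkage(vm, 1.10)
  expect_equal(glandVolume(up) / glandVolume(vm), 1.331, tolerance = 1e-12)
  expect_equal(round(100 * (1.10^3 - 1)), 33)
  down <- suppressWarnings(correctShrinkage(up, 1 / 1.10))
  expect_equal(glandVolume(down), glandVolume(vm), tolerance = 1e-9)
  expect_equal(down@origin, vm@origin, tolerance = 1e-9)
  same <- correctShrinkage(vm, 1.0)
  expect_identical(same@spacing, vm@spacing)
  expect_error(correctShrinkage(vm, 0), "positive")
  expect_warning(correctShrinkage(vm, 0.9), "shrinks")
  # analytic model path scales volumes identically
  mUp <- correctShrinkage(m, 1.10)
  expect_equal(glandVolume(mUp) / glandVolume(m), 1.331, tolerance = 1e-12)
  expect_equal(lesions(mUp)$volume / lesions(m)$volume, 1.331,
               tolerance = 1e-12)
})

test_that("lesion inventory orders by volume and flags the index", {
  les <- rbind(sphereLesion("b", 6.2, centre = c(4, 0, 0), isIndex = TRUE),
               sphereLesion("a", 3.6, centre = c(-8, 0, 0)))
  m <- sphereGland(r = 20, lesions = les)
  inv <- lesionInventory(m)
  expect_equal(inv$id, c("b", "a"))
  expect_equal(inv$isIndex, c(TRUE, FALSE))
  vm <- voxelizeModel(m, spacing = 0.5)
  invV <- lesionInventory(vm)
  expect_equal(invV$id, c("b", "a"))
  expect_true(invV$isIndex[1])
  expect_equal(invV$volumeMl, inv$volumeMl, tolerance = 0.02)
})

test_that("a voxelized ellipsoid recovers its analytic volume within 2%", {
  les <- makeLesion("e", 4 / 3 * pi * 10 * 7 * 5 / 1000,
                    aspect = c(10, 7, 5), isIndex = TRUE)
  expect_equal(c(les$ax, les$ay, les$az), c(10, 7, 5), tolerance = 1e-9)
  vm <- voxelizeModel(sphereGland(r = 20, lesions = les), spacing = 0.5)
  analytic <- 4 / 3 * pi * 10 * 7 * 5 / 1000
  expect_lt(abs(lesionInventory(vm)$volumeMl[1] - analytic) / analytic, 0.02)
})

test_that("interpolated masks reproduce the input polygons at slice planes", {
  m <- sphereGland(r = 10)
  st <- emitContourStack(m, sliceThickness = 5)
  vm <- interpolateShape(st, spacing = 0.5)
  zs <- vm@origin[3] + (seq_len(dim(vm@glandMask)[3]) - 1) * 0.5
  for (s in st@slices) {
    k <- which.min(abs(zs - s$position))
    area <- sum(vm@glandMask[, , k]) * 0.5^2
    rPoly <- max(sqrt(rowSums(s$structures$capsule^2)))
    expect_equal(sqrt(area / pi), rPoly, tolerance = 0.06)
  }
})
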