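test_that("a diameter-aligned core through a sphere measures the diameter", {
  les <- sphereLesion("L", 5, isIndex = TRUE)
  core <- biopsyCore(c(0, 0, 0), c(1, 0, 0), effectiveLength = 17)
  expect_equal(chordLengthEllipsoid(core, les), 10, tolerance = 1e-12)
  # disjoint segment
  far <- biopsyCore(c(0, 30, 0), c(1, 0, 0))
  expect_equal(chordLengthEllipsoid(far, les), 0)
  # clipping: a short notch samples less than the full chord
  short <- biopsyCore(c(0, 0, 0), c(1, 0, 0), effectiveLength = 6)
  expect_equal(chordLengthEllipsoid(short, les), 6, tolerance = 1e-12)
})

test_that("analytic chords agree with dense point sampling on random cases", {
  set.seed(77)
  for (i in 1:100) {
    les <- makeLesion("L", runif(1, 0.2, 3), centre = runif(3, -5, 5),
                      aspect = runif(3, 0.5, 1.5), theta = runif(1, 0, pi),
                      isIndex = TRUE)
    core <- biopsyCore(runif(3, -10, 10),
                       rnorm(3), effectiveLength = runif(1, 10, 25))
    a <- chordLengthEllipsoid(core, les)
    b <- denseChordOracle(core, les, step = 0.05)
    expect_lt(abs(a - b), 0.1)
  }
})

test_that("overlapping lesions are counted once via the union", {
  lesA <- sphereLesion("A", 5, centre = c(0, 0, 0), isIndex = TRUE)
  lesB <- sphereLesion("B", 5, centre = c(4, 0, 0))
  m <- sphereGland(r = 25, lesions = rbind(lesA, lesB))
  core <- biopsyCore(c(2, 0, 0), c(1, 0, 0), effectiveLength = 40)
  res <- coreCancerLength(core, m)
  expect_equal(res$cancerLength, 14, tolerance = 1e-9)   # [-5, 9]
  expect_equal(unname(res$perLesion["A"]), 10, tolerance = 1e-9)
  expect_equal(unname(res$perLesion["B"]), 10, tolerance = 1e-9)
  expect_lt(res$cancerLength, sum(res$perLesion))
  expect_equal(res$longestRun, 14, tolerance = 1e-9)
  # brute force union by dense sampling
  h <- 20; step <- 0.01
  t <- seq(-h + step / 2, h - step / 2, by = step)
  p <- c(2, 0, 0)[1] + t
  inU <- (abs(p) < 5) | (abs(p - 4) < 5)
  expect_equal(res$cancerLength, sum(inU) * step, tolerance = 0.05)
})

test_that("a core through a false target alone is negative", {
  ft <- sphereLesion("FT", 5, isFalseTarget = TRUE)
  m <- sphereGland(r = 25, lesions = ft)
  core <- biopsyCore(c(0, 0, 0), c(1, 0, 0))
  res <- coreCancerLength(core, m)
  expect_equal(res$cancerLength, 0)
  expect_false(res$positive)
})

test_that("voxel and analytic scoring agree on ellipsoids", {
  set.seed(31)
  les <- makeLesion("L", 1.2, centre = c(3, -2, 1), aspect = c(1, 0.7, 0.5),
                    theta = 0.6, isIndex = TRUE)
  m <- sphereGland(r = 18, lesions = les)
  vm <- voxelizeModel(m, spacing = 0.5)
  ctr <- unname(unlist(les[1, c("cx", "cy", "cz")]))
  devs <- numeric(100)
  for (i in 1:100) {
    core <- biopsyCore(ctr + runif(3, -4, 4), rnorm(3))
    a <- coreCancerLength(core, m)$cancerLength
    v <- coreCancerLength(core, vm)$cancerLength
    devs[i] <- abs(a - v)
  }
  # a binarised mask localises each surface crossing to ~half a voxel,
  # so agreement is distributional: typical deviation well below one
  # voxel, worst case (grazing rays) within two voxels
  expect_lt(median(devs), 0.2)
  expect_lt(unname(quantile(devs, 0.9)), 0.5)
  expect_lt(max(devs), 1)
})

test_that("rigidly transforming core and model together preserves lengths", {
  les <- makeLesion("L", 1, centre = c(4, 1, -2), aspect = c(1, 0.8, 0.6),
                    theta = 0.3, isIndex = TRUE)
  core <- biopsyCore(c(3, 0, -1), c(0.2, 0.5, 1))
  base <- chordLengthEllipsoid(core, les)
  expect_gt(base, 0)
  # translation
  d <- c(7, -3, 2)
  lesT <- les
  lesT[, c("cx", "cy", "cz")] <- lesT[, c("cx", "cy", "cz")] + rbind(d)
  coreT <- biopsyCore(core@plannedMidpoint + d, core@direction)
  expect_equal(chordLengthEllipsoid(coreT, lesT), base, tolerance = 1e-9)
  # rotation about the z axis
  phi <- 0.9
  rot <- function(p) c(cos(phi) * p[1] - sin(phi) * p[2],
                       sin(phi) * p[1] + cos(phi) * p[2], p[3])
  lesR <- les
  lesR[, c("cx", "cy", "cz")] <- rbind(rot(unlist(les[, c("cx", "cy", "cz")])))
  lesR$theta <- les$theta + phi
  coreR <- biopsyCore(rot(core@plannedMidpoint), rot(core@direction))
  expect_equal(chordLengthEllipsoid(coreR, lesR), base, tolerance = 1e-9)
})

test_that("enlarging a lesion never decreases the cancer length", {
  set.seed(13)
  for (i in 1:30) {
    les <- makeLesion("L", runif(1, 0.3, 2), centre = runif(3, -3, 3),
                      aspect = runif(3, 0.5, 1), theta = runif(1, 0, pi),
                      isIndex = TRUE)
    big <- les
    big[, c("ax", "ay", "az")] <- big[, c("ax", "ay", "az")] * 1.5
    big$volume <- big$volume * 1.5^3
    core <- biopsyCore(runif(3, -8, 8), rnorm(3))
    expect_gte(chordLengthEllipsoid(core, big),
               chordLengthEllipsoid(core, les) - 1e-12)
  }
})

test_that("in-gland segment length matches the analytic chord", {
  m <- sphereGland(r = 15)
  through <- biopsyCore(c(0, 0, 0), c(0, 1, 0), effectiveLength = 40)
  expect_equal(segmentInGlandLength(through, m), 30, tolerance = 1e-9)
  outside <- biopsyCore(c(0, 40, 0), c(1, 0, 0))
  expect_equal(segmentInGlandLength(outside, m), 0)
  res <- coreCancerLength(outside, m)
  expect_true(res$glandMiss)
  vm <- voxelizeModel(m, spacing = 1)
  expect_equal(segmentInGlandLength(through, vm), 30, tolerance = 1)
})
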