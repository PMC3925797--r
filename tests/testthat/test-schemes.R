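test_that("the TRUS template is left-right symmetric and deterministic", {
  m <- sphereGland(r = 23)
  plan <- planTrus12(m, jitter = FALSE)
  expect_equal(nrow(plan@cores), 12L)
  mx <- sort(plan@cores$midX)
  expect_equal(mx, -rev(mx), tolerance = 1e-9)  # mirror in x
  expect_equal(plan@cores$midY, rep(plan@cores$midY[1], 12))
  set.seed(4); a <- planTrus12(m)
  set.seed(4); b <- planTrus12(m)
  expect_identical(a@cores, b@cores)
})

test_that("TRUS planning is blinded to the pathology", {
  les <- rbind(sphereLesion("L1", 6, centre = c(5, -3, 2), isIndex = TRUE),
               sphereLesion("L2", 3, centre = c(-6, 2, -5)))
  m1 <- sphereGland(r = 23, lesions = les)
  m2 <- sphereGland(r = 23, lesions = les[2:1, ][, ])  # permuted
  m2@lesions$isIndex <- c(FALSE, TRUE)
  m3 <- sphereGland(r = 23)                            # deleted
  plans <- lapply(list(m1, m2, m3), function(m) {
    set.seed(99)
    planTrus12(m)@cores
  })
  expect_identical(plans[[1]], plans[[2]])
  expect_identical(plans[[1]], plans[[3]])
})

test_that("TRUS cores traverse the gland in almost every slot", {
  m <- prostateModel("qc", glandVolumeMl = 50)
  set.seed(8)
  inGland <- matrix(0, 500, 12)
  for (r in 1:500) {
    p <- planTrus12(m)
    for (j in 1:12) {
      core <- biopsyCore(unlist(p@cores[j, c("midX", "midY", "midZ")]),
                         unlist(p@cores[j, c("dirX", "dirY", "dirZ")]))
      inGland[r, j] <- segmentInGlandLength(core, m)
    }
  }
  expect_gte(sum(colMeans(inGland) > 0), 11L)
})

test_that("target eligibility applies the 0.2 ml threshold inclusively", {
  les <- rbind(sphereLesion("small", (0.19 * 3000 / (4 * pi))^(1 / 3),
                            centre = c(6, 3, 0)),
               sphereLesion("edge", (0.20 * 3000 / (4 * pi))^(1 / 3),
                            centre = c(-6, -3, 0)),
               sphereLesion("big", (1.00 * 3000 / (4 * pi))^(1 / 3),
                            centre = c(0, -6, 5), isIndex = TRUE))
  les$volume <- c(0.19, 0.20, 1.00)  # exact volumes
  les[, c("ax", "ay", "az")] <- (3000 * les$volume / (4 * pi))^(1 / 3)
  m <- sphereGland(r = 22, lesions = les)
  expect_equal(eligibleTargets(m), c("big", "edge"))
  expect_length(eligibleTargets(m, threshold = 2), 0L)
  # a false target above threshold is a target
  ft <- sphereLesion("FT", 5, isFalseTarget = TRUE)
  expect_equal(eligibleTargets(sphereGland(r = 20, lesions = ft)), "FT")
})

test_that("targeted planning takes the deepest chord and the 5-mm neighbour", {
  r <- 6.2
  les <- sphereLesion("L", r, centre = c(0, 0, 0), isIndex = TRUE)
  les$volume <- sphereVolumeMl(r)
  m <- sphereGland(r = 22, lesions = les)
  p1 <- planTargeted(m, 1)
  expect_equal(p1@cores$plannedChord, 2 * r, tolerance = 1e-9)
  expect_equal(p1@cores$midX, 0, tolerance = 1e-12)
  expect_equal(p1@cores$midY, 0, tolerance = 1e-12)
  p2 <- planTargeted(m, 2)
  expect_equal(p2@cores$plannedChord[2], 2 * sqrt(r^2 - 5^2), tolerance = 1e-9)
  expect_equal(sqrt((p2@cores$midX[2])^2 + (p2@cores$midY[2])^2), 5,
               tolerance = 1e-9)
})

test_that("targeted cores sit exactly on the template lattice", {
  set.seed(12)
  grid <- templateGrid()
  for (i in 1:10) {
    les <- makeLesion("L", runif(1, 0.3, 2), centre = c(runif(2, -8, 8), runif(1, -5, 5)),
                      aspect = c(1, runif(1, 0.6, 1), runif(1, 0.4, 0.7)),
                      isIndex = TRUE)
    m <- sphereGland(r = 24, lesions = les)
    p <- suppressWarnings(planTargeted(m, 3, grid))
    offX <- (p@cores$midX - grid@anchor[1]) / grid@spacing
    offY <- (p@cores$midY - grid@anchor[2]) / grid@spacing
    expect_equal(offX, round(offX), tolerance = 1e-9)
    expect_equal(offY, round(offY), tolerance = 1e-9)
  }
})

test_that("greedy plans equal the exhaustive lattice optimum for k <= 2", {
  set.seed(2718)
  grid <- templateGrid()
  probeChord <- function(x, y, les) {
    core <- biopsyCore(c(x, y, les$cz), c(0, 0, 1), effectiveLength = 2e4)
    chordLengthEllipsoid(core, transform(les, isFalseTarget = FALSE))
  }
  for (i in 1:50) {
    les <- makeLesion("L", runif(1, 0.25, 3), centre = c(runif(2, -10, 10), 0),
                      aspect = c(1, runif(1, 0.6, 1), runif(1, 0.4, 0.9)),
                      theta = runif(1, 0, pi), isIndex = TRUE)
    m <- sphereGland(r = 26, lesions = les)
    # independent exhaustive oracle over a lattice window around the lesion
    xs <- seq(-25, 25, by = 5); ys <- seq(-25, 25, by = 5)
    cand <- expand.grid(x = xs, y = ys)
    stopifnot(nrow(cand) <= 200)
    chords <- mapply(probeChord, cand$x, cand$y, MoreArgs = list(les = les))
    chords <- pmin(chords, 17)
    best1 <- max(chords)
    o <- order(chords, decreasing = TRUE)
    best2 <- chords[o[1]] + chords[o[2]]
    p1 <- suppressWarnings(planTargeted(m, 1, grid))
    expect_equal(sum(p1@cores$plannedChord), best1, tolerance = 1e-9)
    if (sum(chords > 0) >= 2) {
      p2 <- suppressWarnings(planTargeted(m, 2, grid))
      expect_equal(sum(p2@cores$plannedChord), best2, tolerance = 1e-9)
      # greedy total never below the single-core total
      expect_gte(sum(p2@cores$plannedChord), sum(p1@cores$plannedChord))
    }
  }
})

test_that("requesting more cores than lattice hits stacks on the best", {
  les <- makeLesion("L", 0.2, centre = c(1.3, 1.3, 0), aspect = c(1, 1, 4),
                    isIndex = TRUE)
  expect_lt(les$ax, 2.5)  # transverse footprint smaller than one cell
  m <- sphereGland(r = 20, lesions = les)
  expect_warning(p <- planTargeted(m, 5), "stacking")
  expect_equal(nrow(p@cores), 5L)
  expect_equal(length(unique(paste(p@cores$midX, p@cores$midY))) <= 4, TRUE)
})
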