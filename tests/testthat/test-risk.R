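# Small hand-built session tables: one row per repetition.
sessionRows <- function(modelId, mccl, pct, strategy = "S") {
  data.frame(modelId = modelId, strategy = strategy,
             rep = seq_along(mccl), nCores = 3, nPositive = NA,
             mccl = mccl, pctPositive = pct, detected = mccl > 0,
             riskClass = classifyRisk(mccl, pct), stringsAsFactors = FALSE)
}

test_that("risk classification honours both inclusive boundaries", {
  expect_equal(classifyRisk(6.0, 0), "high")
  expect_equal(classifyRisk(0, 50), "high")
  expect_equal(classifyRisk(5.9, 49), "low")
  expect_equal(classifyRisk(5.999, 49.999), "low")
  # monotone: raising either input never flips high -> low
  set.seed(8)
  m0 <- runif(50, 0, 12); p0 <- runif(50, 0, 100)
  base <- classifyRisk(m0, p0)
  up <- classifyRisk(m0 + runif(50, 0, 5), p0 + runif(50, 0, 30))
  expect_false(any(base == "high" & up == "low"))
})

test_that("clinical significance applies volume and grade inclusively", {
  mk <- function(vol, gleason) {
    les <- sphereLesion("L", (3000 * vol / (4 * pi))^(1 / 3),
                        gleason = gleason, isIndex = TRUE)
    les$volume <- vol
    les[, c("ax", "ay", "az")] <- (3000 * vol / (4 * pi))^(1 / 3)
    sphereGland(r = 20, lesions = les)
  }
  expect_true(caseIsSignificant(mk(0.5, "<=6")))
  expect_true(caseIsSignificant(mk(0.4, "7")))
  expect_true(caseIsSignificant(mk(0.1, ">=8")))
  expect_false(caseIsSignificant(mk(0.49, "<=6")))
  # a false target never makes a case significant
  ft <- sphereLesion("FT", 9, isFalseTarget = TRUE)
  expect_false(caseIsSignificant(sphereGland(r = 20, lesions = ft)))
})

test_that("sensitivity averages per-repetition detection over cases", {
  mA <- sphereGland(r = 20, id = "A",
                    lesions = sphereLesion("L", 6, isIndex = TRUE))
  mB <- sphereGland(r = 20, id = "B",
                    lesions = sphereLesion("L", 6, isIndex = TRUE))
  cohort <- list(mA, mB)
  res <- rbind(sessionRows("A", mccl = rep(4, 10), pct = rep(30, 10)),
               sessionRows("B", mccl = rep(0, 10), pct = rep(0, 10)))
  expect_equal(strategySensitivity(res, cohort, "all"), 0.5)
  resAll <- rbind(sessionRows("A", rep(4, 10), rep(30, 10)),
                  sessionRows("B", rep(4, 10), rep(30, 10)))
  expect_equal(strategySensitivity(resAll, cohort, "all"), 1.0)
  # benign-target-only cohort: undefined
  ft <- sphereGland(r = 20, id = "F",
                    lesions = sphereLesion("FT", 6, isFalseTarget = TRUE))
  expect_error(strategySensitivity(sessionRows("F", rep(0, 5), rep(0, 5)),
                                   list(ft), "all"), "empty stratum")
})

test_that("attribution uses the majority rule across repetitions", {
  m <- sphereGland(r = 20, id = "A",
                   lesions = sphereLesion("L", 6, isIndex = TRUE))  # 0.9 ml
  expect_true(caseIsSignificant(m))
  # 251 of 500 repetitions high: counted high under the 0.5 threshold
  mccl <- c(rep(7, 251), rep(0, 249))
  res <- sessionRows("A", mccl, pct = rep(0, 500))
  rate <- attributionRate(res, list(m))
  expect_equal(as.numeric(rate), 1)
  expect_equal(unname(attr(rate, "perCase")), 251 / 500)
  # exactly half is not a majority
  res2 <- sessionRows("A", c(rep(7, 250), rep(0, 250)), rep(0, 500))
  expect_equal(as.numeric(attributionRate(res2, list(m))), 0)
  # all high
  res3 <- sessionRows("A", rep(7, 500), rep(0, 500))
  expect_equal(as.numeric(attributionRate(res3, list(m))), 1)
})

test_that("a targeted core through a 13-mm chord forces a high-risk case", {
  r <- 6.6  # max chord 13.2 mm
  les <- sphereLesion("L", r, centre = c(0, 0, 0), isIndex = TRUE)
  m <- sphereGland(r = 22, lesions = les)
  res <- runStrategy(m, "TARGETED_1", em = errorModel(totalSd = 0),
                     reps = 20, seed = 1)
  expect_true(all(res$mccl >= 6))
  expect_true(all(res$riskClass == "high"))
  expect_equal(as.numeric(attributionRate(res, list(m))), 1)
})

test_that("summaries reproduce constants and brute-force order statistics", {
  m <- sphereGland(r = 20, id = "A",
                   lesions = sphereLesion("L", 6, isIndex = TRUE))
  res <- sessionRows("A", rep(4.2, 8), rep(33, 8))
  sm <- summarizeCohort(res, list(m), strata = "all")
  expect_equal(sm$mcclMean, 4.2)
  expect_equal(sm$mcclMedian, 4.2)
  expect_equal(sm$mcclP90, 4.2)
  expect_equal(sm$mcclSd, 0)
  # known 10-case set: order statistics against a direct sort
  vals <- c(9.1, 0.4, 5.5, 2.2, 7.7, 3.3, 6.6, 1.1, 8.8, 4.4)
  cohort <- lapply(1:10, function(i)
    sphereGland(r = 20, id = paste0("M", i),
                lesions = sphereLesion("L", 6, isIndex = TRUE)))
  res10 <- do.call(rbind, lapply(1:10, function(i)
    sessionRows(paste0("M", i), rep(vals[i], 3), rep(10 * i, 3))))
  sm10 <- summarizeCohort(res10, cohort, strata = "all")
  s <- sort(vals)
  expect_equal(sm10$mcclMedian, (s[5] + s[6]) / 2)
  expect_equal(sm10$mcclP90, unname(quantile(vals, 0.9, type = 7)))
  expect_equal(sm10$mcclMean, mean(vals))
  expect_equal(sm10$pctPosP90, unname(quantile(10 * (1:10), 0.9, type = 7)))
})

test_that("paired strategy comparisons match closed-form statistics", {
  set.seed(44)
  ids <- paste0("M", 1:50)
  a <- runif(50, 0, 8)
  resA <- do.call(rbind, lapply(1:50, function(i)
    sessionRows(ids[i], rep(a[i], 2), rep(10, 2), strategy = "A")))
  resB <- do.call(rbind, lapply(1:50, function(i)
    sessionRows(ids[i], rep(a[i] + 5, 2), rep(10, 2), strategy = "B")))
  cmp <- compareStrategies(resA, resB, metric = "mccl")
  expect_lt(cmp$tP, 1e-4)
  expect_equal(cmp$meanDifference, 5, tolerance = 1e-12)
  # identical samples: zero statistics
  cmp0 <- compareStrategies(resA, resA, metric = "mccl")
  expect_equal(cmp0$tStatistic, 0)
  expect_equal(cmp0$ksPairedStatistic, 0)
  # textbook paired-t formula on noisy differences
  resC <- do.call(rbind, lapply(1:50, function(i)
    sessionRows(ids[i], rep(pmax(0, a[i] + rnorm(1, 1, 2)), 2), rep(10, 2))))
  cmpC <- compareStrategies(resA, resC, metric = "mccl")
  cVals <- vapply(ids, function(id)
    mean(resC$mccl[resC$modelId == id]), numeric(1))
  d <- cVals - a
  expect_equal(cmpC$tStatistic, mean(d) / (sd(d) / sqrt(50)),
               tolerance = 1e-10)
  # too few pairs refused
  expect_error(compareStrategies(resA[resA$modelId %in% ids[1:2], ],
                                 resB[resB$modelId %in% ids[1:2], ]),
               "fewer than 3")
})
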