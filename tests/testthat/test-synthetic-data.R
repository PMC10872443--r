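test_that("varianceComponents defaults encode the study variance mix", {
  vc <- varianceComponents()
  expect_equal(vc@sigmaLambda2, 0.07)
  expect_equal(vc@sigmaPi2, 0.44)
  expect_equal(vc@sigmaEps2, 0.49)
  # default session effects: centered linear habituation trend
  expect_equal(mean(vc@sessionEffects), 0)
  expect_equal(diff(vc@sessionEffects), rep(-0.05, 9))
  expect_error(varianceComponents(sigmaPi2 = -1), class = "error")
})

test_that("generateParcelVoxels is deterministic and correctly shaped", {
  vc <- varianceComponents()
  p1 <- generateParcelVoxels(vc, 5, 3, 4, seed = 11)
  p2 <- generateParcelVoxels(vc, 5, 3, 4, seed = 11)
  p3 <- generateParcelVoxels(vc, 5, 3, 4, seed = 12)
  expect_identical(p1@data, p2@data)
  expect_false(identical(p1@data$value, p3@data$value))
  expect_equal(nrow(p1@data), 5 * 3 * 4)
  expect_equal(sort(unique(p1@data$participant)), 1:5)
  expect_equal(sort(unique(p1@data$voxel)), 1:4)
  # complete crossing: every key combination exactly once
  expect_false(any(duplicated(
    p1@data[c("participant", "session", "voxel")])))
})

test_that("generated variance structure matches the generating components", {
  vc <- varianceComponents(sigmaLambda2 = 1, sigmaPi2 = 2, sigmaEps2 = 0.5,
                           sessionEffects = rep(0, 6))
  p <- generateParcelVoxels(vc, 400, 6, 5, seed = 13)
  d <- p@data
  # voxel-level noise: variance of deviations from participant-session
  # means estimates sigmaEps2
  psMean <- ave(d$value, d$participant, d$session)
  s2eHat <- sum((d$value - psMean)^2) / (400 * 6 * (5 - 1))
  expect_equal(s2eHat, 0.5, tolerance = 0.05)
  # participant-session means spread around participant means estimates
  # sigmaPi2 + sigmaEps2 / V
  ag <- aggregate(value ~ participant + session, d, mean)
  pMean <- ave(ag$value, ag$participant)
  s2pHat <- sum((ag$value - pMean)^2) / (400 * (6 - 1)) - s2eHat / 5
  expect_equal(s2pHat, 2, tolerance = 0.2)
  # participant means spread estimates sigmaLambda2 + sigmaPi2 / S + ...
  pm <- tapply(d$value, d$participant, mean)
  expect_equal(var(pm) - 2 / 6 - 0.5 / 30, 1, tolerance = 0.2)
})

test_that("predictor panel decomposition is exact and zero-sum", {
  pred <- makeTestPredictor(seed = 21)
  d <- pred@data
  expect_equal(d$x, pred@grandMean + d$xBetween + d$xWithin)
  # within component sums to ~zero inside every participant
  ws <- tapply(d$xWithin, d$participant, sum)
  expect_lt(max(abs(ws)), 1e-10)
  expect_lt(abs(mean(tapply(d$xBetween, d$participant, mean))), 1e-10)
})

test_that("predictor variance shares follow the requested SDs", {
  pred <- generatePredictorPanel(sqrt(0.44), sqrt(0.56), 2000, 10, seed = 22)
  d <- pred@data
  bet <- tapply(d$x, d$participant, mean)
  expect_equal(var(bet) - 0.56 / 10, 0.44, tolerance = 0.05)
  # person-mean deviations lose 1/k of the within variance
  expect_equal(var(d$x - bet[d$participant]) * 10 / 9, 0.56,
               tolerance = 0.02)
})

test_that("injectWithinEffect adds exactly the specified structure", {
  vc <- varianceComponents()
  p <- generateParcelVoxels(vc, 10, 4, 3, seed = 31)
  pred <- generatePredictorPanel(1, 1, 10, 4, seed = 32)
  p2 <- injectWithinEffect(p, pred, betaWithin = 0.5, betaBetween = 0.25,
                           betaTime = -0.1)
  m <- match(paste(p@data$participant, p@data$session),
             paste(pred@data$participant, pred@data$session))
  delta <- p2@data$value - p@data$value
  expected <- -0.1 * (p@data$session - 1) +
    0.25 * pred@data$xBetween[m] + 0.5 * pred@data$xWithin[m]
  expect_equal(delta, expected)
  expect_equal(p2@metadata$truth$betaWithin, 0.5)
})

test_that("injectWithinEffect refuses misaligned predictors", {
  vc <- varianceComponents()
  p <- generateParcelVoxels(vc, 10, 4, 3, seed = 33)
  pred <- generatePredictorPanel(1, 1, 8, 4, seed = 34)
  expect_error(injectWithinEffect(p, pred, 0.5),
               class = "boldrel_alignment_error")
})

test_that("label volume generator places blocks and spheres exactly", {
  lv <- generateLabelVolume(c(12, 12, 12), list(
    list(label = 1L, type = "block", corner = c(1, 2, 3), size = c(3, 4, 5)),
    list(label = 7L, type = "sphere", center = c(8, 8, 8), radius = 2)))
  arr <- lv@labels
  expect_equal(sum(arr == 1L), 3 * 4 * 5)
  expect_equal(sum(arr == 7L), oracleSphereCount(2))
  # block occupies exactly the 0-based [corner, corner+size) box
  expect_true(all(arr[2:4, 3:6, 4:8] == 1L))
  expect_error(generateLabelVolume(c(12, 12, 12), list(
    list(label = 1L, type = "block", corner = c(0, 0, 0), size = c(4, 4, 4)),
    list(label = 2L, type = "block", corner = c(3, 3, 3), size = c(2, 2, 2)))),
    class = "boldrel_specification_error")
  expect_error(generateLabelVolume(c(8, 8, 8), list(
    list(label = 1L, type = "block", corner = c(6, 6, 6), size = c(4, 4, 4)))),
    class = "boldrel_specification_error")
})

test_that("sleep and stress simulation respects its constraints", {
  ss <- generateSleepStress(4, 20, seed = 41)
  expect_true(all(ss$sleep$offset > ss$sleep$onset))
  expect_true(all(ss$stress$severity %in% seq(1, 5, by = 0.5)))
  expect_true(all(ss$stress$type %in% c("episodic", "chronic")))
  expect_setequal(unique(ss$sleep$participant), 1:4)
  # nocturnal sleep durations are plausibly near 8 h
  noct <- as.numeric(ss$sleep$offset - ss$sleep$onset, units = "hours")
  expect_gt(median(noct), 5)
  expect_error(generateSleepStress(4, 5, seed = 1),
               class = "boldrel_invalid_parameter")
})

test_that("voxel panel CSV round trip preserves data and metadata", {
  vc <- varianceComponents()
  p <- generateParcelVoxels(vc, 4, 3, 2, seed = 51, parcel = "roi_9")
  tf <- withr::local_tempfile(fileext = ".csv")
  writeVoxelPanel(p, tf)
  p2 <- readVoxelPanel(tf)
  expect_equal(p@data$value, p2@data$value)
  expect_identical(p@data$parcel, p2@data$parcel)
  expect_equal(p2@nParticipants, 4L)
  expect_equal(p2@metadata$seed, 51L)
})

test_that("studyConfig builds a 36-parcel default with varying sizes", {
  cfg <- studyConfig()
  expect_equal(nrow(cfg@parcels), 36)
  expect_equal(sort(unique(cfg@parcels$anatomy)),
               c("control", "cortex", "subcortex"))
  expect_gt(length(unique(cfg@parcels$nVoxels)), 1)
  expect_equal(cfg@nParticipants, 30L)
  expect_equal(cfg@nSessions, 10L)
  expect_equal(cfg@betaWithin, 0.17)
})
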