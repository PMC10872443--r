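test_that("iccPairFromComponents computes the ratio and guards zeros", {
  expect_equal(iccPairFromComponents(1, 1), 0.5)
  expect_equal(iccPairFromComponents(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(iccPairFromComponents(0, 0),
               class = "boldrel_undefined_ratio")
  expect_error(iccPairFromComponents(-1, 1),
               class = "boldrel_invalid_parameter")
})

test_that("two-level REML fit recovers a known variance split", {
  # direct two-level generation: participant signal 1, noise 1 -> ICC 0.5
  withr::with_seed(201, {
    N <- 250
    pi_j <- rnorm(N, 0, 1)
    d <- data.frame(participant = rep(seq_len(N), each = 2),
                    session = rep(1:2, N))
    d$value <- pi_j[d$participant] + rnorm(2 * N, 0, 1)
  })
  fit <- fitVarianceComponents2Level(d, backend = "reml", seed = 1)
  expect_equal(fit$sigmaPi2, 1, tolerance = 0.15)
  expect_equal(fit$sigmaEps2, 1, tolerance = 0.15)
  est <- estimatePairICC(d, c(1, 2), backend = "reml", seed = 1)
  expect_lt(abs(iccMedian(est) - 0.5), 0.07)
  expect_error(fitVarianceComponents2Level(
    d[d$session == 1, ], backend = "reml"),
    class = "boldrel_invalid_parameter")
})

test_that("session fixed effects do not contaminate the pair ICC", {
  # a large additive session shift must not count as error variance
  withr::with_seed(202, {
    N <- 200
    pi_j <- rnorm(N, 0, 1)
    d <- data.frame(participant = rep(seq_len(N), each = 2),
                    session = rep(1:2, N))
    d$value <- pi_j[d$participant] + rnorm(2 * N, 0, 1) +
      5 * (d$session == 2)
  })
  est <- estimatePairICC(d, c(1, 2), backend = "reml", seed = 1)
  expect_lt(abs(iccMedian(est) - 0.5), 0.07)
})

test_that("adjacentPairICC produces S-1 overlapping pairs (or disjoint)", {
  vc <- varianceComponents(sigmaLambda2 = 0.5, sigmaPi2 = 0.3,
                           sigmaEps2 = 0.2)
  p <- generateParcelVoxels(vc, 12, 6, 4, seed = 203)
  ests <- adjacentPairICC(p, backend = "reml", seed = 1)
  expect_length(ests, 5)
  expect_equal(lapply(ests, function(e) e@pair),
               lapply(1:5, function(s) c(s, s + 1L)))
  disj <- adjacentPairICC(p, backend = "reml", disjoint = TRUE, seed = 1)
  expect_length(disj, 3)
  expect_equal(disj[[2]]@pair, c(3L, 4L))
})

test_that("meta-analytic pooling degenerates to the common value", {
  # homogeneous pseudo-estimates: pooling must return the shared ICC
  common <- 0.42
  ests <- lapply(1:6, function(i) {
    new("ICCEstimate", pair = c(i, i + 1L),
        draws = rep(common, 100), median = common, logitSd = 0.15,
        backend = "reml")
  })
  pool <- poolICCMeta(ests, seed = 204)
  expect_equal(iccMedian(pool), common, tolerance = 0.01)
  expect_true(iccInterval(pool)[1] <= common &&
                common <= iccInterval(pool)[2])
})

test_that("fixed-effect pooling matches the inverse-variance closed form", {
  withr::with_seed(205, {
    meds <- plogis(rnorm(8, 0, 0.8))
    ses <- runif(8, 0.1, 0.5)
  })
  ests <- lapply(1:8, function(i)
    new("ICCEstimate", pair = c(i, i + 1L), draws = rep(meds[i], 10),
        median = meds[i], logitSd = ses[i], backend = "reml"))
  pool <- poolICCMeta(ests, fixedSigma = TRUE, nDraws = 4000, seed = 206)
  # oracle: metafor fixed-effect model on the logit scale
  fe <- metafor::rma(yi = qlogis(meds), sei = ses, method = "FE")
  expect_equal(iccMedian(pool), plogis(as.numeric(fe$beta)),
               tolerance = 0.01)
  expect_true(all(pool@sigmaDraws == 0))
  # posterior sd of mu matches the closed-form fixed-effect SE
  expect_equal(sd(pool@muDraws), as.numeric(fe$se), tolerance = 0.05)
})

test_that("internal consistency recovers the three-level variance share", {
  vc <- varianceComponents(sigmaLambda2 = 0.3, sigmaPi2 = 0.5,
                           sigmaEps2 = 0.7, sessionEffects = rep(0, 6))
  p <- generateParcelVoxels(vc, 60, 6, 8, seed = 207)
  est <- fitInternalConsistency(p, backend = "reml", seed = 1)
  truth <- 0.5 / (0.3 + 0.5 + 0.7)
  expect_lt(abs(iccMedian(est) - truth), 0.04)
  ci <- iccInterval(est)
  expect_lt(ci[1], iccMedian(est))
  expect_gt(ci[2], iccMedian(est))
  comp <- varianceEstimates(est)
  expect_equal(unname(comp["sigmaPi2"]), 0.5, tolerance = 0.12)
})

test_that("mcmc and reml internal-consistency estimates agree", {
  vc <- varianceComponents(sigmaLambda2 = 0.2, sigmaPi2 = 0.4,
                           sigmaEps2 = 0.4, sessionEffects = rep(0, 4))
  p <- generateParcelVoxels(vc, 25, 4, 5, seed = 208)
  r <- fitInternalConsistency(p, backend = "reml", seed = 2)
  m <- fitInternalConsistency(p, backend = "mcmc", seed = 2)
  expect_equal(iccMedian(m), iccMedian(r), tolerance = 0.08)
})

test_that("multilevelAlpha follows the closed-form arithmetic", {
  # hand-computed: 0.44 / (0.07 + 0.44 + 0.49/15) = 0.44 / 0.5426667
  expect_equal(multilevelAlpha(0.07, 0.44, 0.49, 15),
               0.44 / (0.07 + 0.44 + 0.49 / 15))
  expect_equal(multilevelAlpha(0.07, 0.44, 0.49, 15), 0.8108108,
               tolerance = 1e-6)
  # k = 1 reduces to the raw ICC_within share
  expect_equal(multilevelAlpha(1, 2, 1, 1), 0.5)
  # alpha is monotone increasing in k
  ks <- c(1, 2, 5, 15, 50)
  a <- multilevelAlpha(0.07, 0.44, 0.49, ks)
  expect_true(all(diff(a) > 0))
  expect_error(multilevelAlpha(0.1, 0.1, 0.1, 0),
               class = "boldrel_invalid_parameter")
})

test_that("iccOneway matches the balanced ANOVA oracle", {
  withr::with_seed(209, {
    g <- rep(1:20, each = 5)
    v <- rnorm(20, 0, 2)[g] + rnorm(100)
  })
  d <- data.frame(participant = g, value = v)
  expect_equal(iccOneway(d), oracleICC11(v, g), tolerance = 1e-10)
  # truncation at zero when between-group variance is negative
  withr::with_seed(210, {
    d0 <- data.frame(participant = rep(1:4, each = 2),
                     value = c(1, -1, 1, -1, 1, -1, 1, -1) + rnorm(8, 0, 1e-3))
  })
  expect_gte(iccOneway(d0), 0)
  expect_error(iccOneway(data.frame(participant = c(1, 1, 2, 2),
                                    value = rnorm(4))),
               class = "boldrel_insufficient_data")
  expect_error(iccOneway(data.frame(participant = rep(1:5, 2),
                                    value = rep(1, 10))),
               class = "boldrel_degenerate_input")
})

test_that("pair ICC attenuates with voxel-mean noise as theory predicts", {
  # averaging V voxels shrinks the error term: the 2-level fit on parcel
  # means sees participant variance sigmaLambda2 and residual
  # sigmaPi2 + sigmaEps2 / V
  vc <- varianceComponents(sigmaLambda2 = 0.4, sigmaPi2 = 0.4,
                           sigmaEps2 = 0.8, sessionEffects = c(0, 0))
  p <- generateParcelVoxels(vc, 300, 2, 4, seed = 211)
  ag <- aggregate(value ~ participant + session, p@data, mean)
  est <- estimatePairICC(ag, c(1, 2), backend = "reml", seed = 1)
  expected <- 0.4 / (0.4 + 0.4 + 0.8 / 4)
  expect_equal(iccMedian(est), expected, tolerance = 0.07)
})
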