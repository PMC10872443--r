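test_that("centerWithinBetween reproduces x exactly with zero-sum parts", {
  withr::with_seed(301, {
    raw <- data.frame(participant = rep(1:6, each = 4),
                      session = rep(1:4, 6), x = rnorm(24, 5, 2))
  })
  p <- centerWithinBetween(raw)
  d <- p@data
  expect_equal(d$x, p@grandMean + d$xBetween + d$xWithin)
  expect_lt(max(abs(tapply(d$xWithin, d$participant, sum))), 1e-10)
  expect_lt(abs(sum(tapply(d$xBetween, d$participant, mean))), 1e-10)
  expect_error(centerWithinBetween(raw[, 1:2]),
               class = "boldrel_invalid_parameter")
})

test_that("aggregateSleep matches a hand-computed window oracle", {
  # one participant, scan on day 15; nightly sleep 22:00 -> 06:00 (8 h),
  # every night. Each 19:00-19:00 window contains exactly one full night.
  onsets <- as.POSIXct(paste(as.Date("2020-01-01") + 0:13, "22:00:00"),
                       tz = "UTC")
  days <- data.frame(onset = onsets, offset = onsets + 8 * 3600)
  res <- aggregateSleep(days, scanDate = as.Date("2020-01-15"))
  expect_equal(res, 8)
  # an event spanning 19:00 is split across two windows: sleep
  # 18:00 -> 20:00 on the day before the scan contributes 1 h to each of
  # two adjacent windows
  one <- data.frame(
    onset = as.POSIXct("2020-01-14 18:00:00", tz = "UTC"),
    offset = as.POSIXct("2020-01-14 20:00:00", tz = "UTC"))
  both <- rbind(days, one)
  # 13 windows of 8 h, plus the split event: window ending Jan 14 19:00
  # gains 1 h (9 h total), window ending Jan 15 19:00 has 8 + 1 h
  res2 <- aggregateSleep(both, scanDate = as.Date("2020-01-15"))
  expect_equal(res2, (12 * 8 + 9 + 9) / 14)
})

test_that("aggregateSleep returns a reasoned NA under sparse coverage", {
  onsets <- as.POSIXct(paste(as.Date("2020-01-01") + 0:3, "22:00:00"),
                       tz = "UTC")
  days <- data.frame(onset = onsets, offset = onsets + 7 * 3600)
  res <- aggregateSleep(days, scanDate = as.Date("2020-01-15"))
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "windows")
  # exactly at the threshold: 7 observed windows are accepted
  onsets7 <- as.POSIXct(paste(as.Date("2020-01-08") + 0:6, "22:00:00"),
                        tz = "UTC")
  days7 <- data.frame(onset = onsets7, offset = onsets7 + 6 * 3600)
  expect_equal(aggregateSleep(days7, scanDate = as.Date("2020-01-15")), 6)
})

test_that("stress scores follow the severity-grid rules", {
  ev <- data.frame(severity = c(2, 3.5, 1, 4),
                   type = c("episodic", "episodic", "chronic", "chronic"))
  expect_equal(sleSumScore(ev), 5.5)
  expect_equal(chronicScore(ev), 4)
  expect_equal(sleSumScore(ev[0, ]), 0)
  expect_equal(chronicScore(ev[0, ]), 0)
  expect_equal(chronicScore(ev[ev$type == "episodic", ]), 0)
  bad <- data.frame(severity = 2.3, type = "episodic")
  expect_error(sleSumScore(bad), class = "boldrel_validation_error")
  expect_error(chronicScore(bad), class = "boldrel_validation_error")
})

test_that("fitLongitudinalModel recovers slopes with honest errors", {
  pred <- makeTestPredictor(seed = 302)
  pd <- pred@data
  withr::with_seed(303, {
    y <- 1 + 0.5 * pd$xWithin + 0.3 * pd$xBetween - 0.1 * (pd$session - 1) +
      rep(rnorm(30, 0, 0.3), each = 10) + rnorm(300, 0, 0.6)
  })
  out <- data.frame(participant = pd$participant, session = pd$session,
                    y = y)
  fit <- fitLongitudinalModel(out, pred)
  co <- coef(fit)
  expect_lt(abs(co[["xWithin"]] - 0.5), 0.2)
  expect_lt(abs(co[["time"]] + 0.1), 0.05)
  expect_lt(abs(co[["(Intercept)"]] - 1), 0.25)
  tab <- coefTable(fit)
  expect_setequal(tab$term, c("(Intercept)", "time", "xBetween", "xWithin"))
  expect_true(all(tab$df > 1))
  expect_lt(tab$p[tab$term == "xWithin"], 0.001)
  # z and p are consistent transforms
  expect_equal(2 * pnorm(-abs(tab$z)), tab$p, tolerance = 1e-10)
})

test_that("fitLongitudinalModel guards its preconditions", {
  pred <- makeTestPredictor(n = 4, s = 6, seed = 304)
  out <- data.frame(participant = pred@data$participant,
                    session = pred@data$session, y = rnorm(24))
  expect_error(fitLongitudinalModel(out, pred),
               class = "boldrel_insufficient_data")
  pred2 <- makeTestPredictor(n = 10, s = 2, seed = 305)
  out2 <- data.frame(participant = pred2@data$participant,
                     session = pred2@data$session, y = rnorm(20))
  expect_error(fitLongitudinalModel(out2, pred2),
               class = "boldrel_insufficient_data")
  # collinear time: constant within every participant after centering
  pred3 <- makeTestPredictor(n = 10, s = 5, seed = 306)
  out3 <- data.frame(participant = pred3@data$participant,
                     session = pred3@data$session, y = rnorm(50))
  expect_error(
    fitLongitudinalModel(out3, pred3, time = rep(1, 50)),
    class = "boldrel_rank_deficiency")
})

test_that("makeWithinPermutations permutes only within blocks", {
  blocks <- split(1:20, rep(1:4, each = 5))
  perms <- makeWithinPermutations(blocks, 30, seed = 307)
  idx <- permIndices(perms)
  expect_equal(idx[1, ], 1:20)
  expect_equal(nrow(idx), 31)
  expect_false(any(duplicated(apply(idx, 1, paste, collapse = ","))))
  for (r in 2:31) {
    for (b in blocks) expect_setequal(idx[r, b], b)
  }
})

test_that("exhaustive enumeration matches the factorial count", {
  blocks <- split(1:5, c(1, 1, 1, 2, 2))
  perms <- makeWithinPermutations(blocks, 100, seed = 1, exhaustive = TRUE)
  expect_equal(nrow(permIndices(perms)), factorial(3) * factorial(2))
  expect_equal(permIndices(perms)[1, ], 1:5)
})

test_that("permutation generation is seeded and rejects impossible requests", {
  blocks <- split(1:6, rep(1:3, each = 2))
  p1 <- makeWithinPermutations(blocks, 5, seed = 308)
  p2 <- makeWithinPermutations(blocks, 5, seed = 308)
  expect_identical(permIndices(p1), permIndices(p2))
  # only 2^3 = 8 distinct permutations exist (7 excluding identity)
  expect_error(makeWithinPermutations(blocks, 50, seed = 1),
               class = "boldrel_insufficient_data")
})

test_that("freedmanLaneNull returns observed stat in row 1 and a calibrated null", {
  pred <- makeTestPredictor(n = 20, s = 6, seed = 309)
  pd <- pred@data
  withr::with_seed(310, {
    y <- 0.3 * pd$xWithin + rep(rnorm(20, 0, 0.3), each = 6) + rnorm(120)
  })
  out <- data.frame(participant = pd$participant, session = pd$session,
                    y = y)
  blocks <- split(seq_len(120), pd$participant)
  perms <- makeWithinPermutations(blocks, 60, seed = 311)
  z <- freedmanLaneNull(out, pred, perms)
  expect_length(z, 61)
  fit <- fitLongitudinalModel(out, pred)
  expect_equal(z[1], unname(fit@z["xWithin"]), tolerance = 1e-8)
  # null distribution roughly standard normal
  expect_lt(abs(mean(z[-1])), 0.5)
  expect_lt(abs(sd(z[-1]) - 1), 0.45)
})

test_that("cluster FWE threshold uses strict exceedance and honest ties", {
  # observed volume with one 5-voxel and one 2-voxel cluster
  obs <- array(0, c(8, 8, 8))
  obs[2:6, 2, 2] <- 4
  obs[5:6, 6, 6] <- 4
  # constructed null maxima: 180 nulls with known cluster sizes
  nullZ <- lapply(1:180, function(i) {
    a <- array(0, c(8, 8, 8))
    ext <- c(rep(2, 171), rep(5, 9))[i]    # 95% quantile = 2, ties at 5
    a[seq_len(ext), 1, 1] <- 4
    a
  })
  tab <- clusterFweThreshold(obs, nullZ, clusterFormingP = 0.01,
                             alpha = 0.05)
  crit <- attr(tab, "critical")
  expect_equal(crit, 2)
  # strict '>' rule: the 2-voxel cluster does NOT survive at critical 2
  expect_true(tab$survives[tab$extent == 5])
  expect_false(tab$survives[tab$extent == 2])
  expect_equal(sort(tab$extent, decreasing = TRUE), c(5, 2))
  expect_length(attr(tab, "nullMax"), 180)
})

test_that("cluster labeling agrees with the flood-fill oracle", {
  withr::with_seed(312, {
    for (rep in 1:3) {
      mask <- array(runif(10^3) < 0.35, c(10, 10, 10))
      cc <- boldReliability:::.labelComponents6(mask)
      lab <- array(0L, dim(mask))
      lab[cc$index] <- cc$labels
      want <- oracleComponents6(mask)
      # same partition: extents of components agree as multisets and the
      # label maps are a relabeling of each other
      expect_equal(sort(tabulate(lab[lab > 0])),
                   sort(tabulate(want[want > 0])))
      key <- paste(lab[mask], want[mask])
      expect_equal(length(unique(key)), length(unique(lab[lab > 0])))
    }
  })
})

test_that("clusterFweThreshold warns on few nulls and errors on none", {
  obs <- array(rnorm(5^3), c(5, 5, 5))
  nulls <- lapply(1:20, function(i) array(rnorm(5^3), c(5, 5, 5)))
  expect_warning(clusterFweThreshold(obs, nulls), "100")
  expect_error(clusterFweThreshold(obs, list()),
               class = "boldrel_invalid_parameter")
})

test_that("signErrorSelect implements the worked example exactly", {
  mk <- function(id, p) new("ParcelPosterior", parcel = id,
                            draws = numeric(0), median = 1, pSign = p)
  parcels <- list(mk("a", 0.99), mk("b", 1.0), mk("c", 0.97), mk("d", 0.98))
  sel <- signErrorSelect(parcels, errorBudget = 0.05)
  # sorted descending: 1.0, .99, .98, .97; cumulative products 1.0, .99,
  # .9702, .9411 -> select the first 3, sign-error 1 - .9702 = .0298
  expect_equal(sel$parcel, c("b", "a", "d", "c"))
  expect_equal(sel$selected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sel$cumProduct, c(1, 0.99, 0.9702, 0.941094),
               tolerance = 1e-9)
  expect_equal(1 - min(sel$cumProduct[sel$selected]), 0.0298,
               tolerance = 1e-9)
})

test_that("signErrorSelect keeps a prefix even when later products recover", {
  mk <- function(id, p) new("ParcelPosterior", parcel = id,
                            draws = numeric(0), median = 1, pSign = p)
  # all equal: ties broken by parcel id, still a prefix
  parcels <- list(mk("p2", 0.99), mk("p1", 0.99), mk("p3", 0.99))
  sel <- signErrorSelect(parcels, errorBudget = 0.05)
  expect_equal(sel$parcel, c("p1", "p2", "p3"))
  expect_equal(sel$selected, c(TRUE, TRUE, TRUE))
  sel2 <- signErrorSelect(parcels, errorBudget = 0.015)
  expect_equal(sel2$selected, c(TRUE, FALSE, FALSE))
  # selection never violates the budget
  expect_gte(min(sel$cumProduct[sel$selected]), 0.95)
})

test_that("parcel posterior sign probabilities respond to the true effect", {
  vc <- varianceComponents()
  pred <- makeTestPredictor(n = 25, s = 8, seed = 313)
  pos <- injectWithinEffect(
    generateParcelVoxels(vc, 25, 8, 10, seed = 314), pred, 0.6)
  none <- generateParcelVoxels(vc, 25, 8, 10, seed = 315)
  pPos <- fitParcelPosterior(pos, pred, backend = "approx", seed = 316)
  pNone <- fitParcelPosterior(none, pred, backend = "approx", seed = 317)
  expect_gt(signProb(pPos), 0.99)
  expect_gt(pPos@median, 0.3)
  expect_lt(signProb(pNone), signProb(pPos))
  expect_gte(signProb(pNone), 0.5)
})

test_that("approx and mcmc parcel posteriors agree on a strong effect", {
  vc <- varianceComponents()
  pred <- makeTestPredictor(n = 15, s = 5, seed = 318)
  p <- injectWithinEffect(
    generateParcelVoxels(vc, 15, 5, 6, seed = 319), pred, 0.5)
  a <- fitParcelPosterior(p, pred, backend = "approx", seed = 320)
  m <- fitParcelPosterior(p, pred, backend = "mcmc", seed = 320)
  expect_lt(abs(a@median - m@median), 0.1)
})

test_that("estimatePower returns a calibrated Monte-Carlo summary", {
  pw <- estimatePower(nSim = 150, seed = 321)
  expect_named(pw, c("power", "mcse", "nSim", "alpha"))
  expect_equal(pw$mcse, sqrt(pw$power * (1 - pw$power) / 150),
               tolerance = 1e-10)
  # small-n sanity: power at effect .17 should be well above alpha
  expect_gt(pw$power, 0.5)
  # at zero effect, rejection rate collapses toward alpha
  p0 <- estimatePower(betaWithinStd = 0, nSim = 150, seed = 322)
  expect_lt(p0$power, 0.15)
})
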