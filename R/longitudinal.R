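# Longitudinal within-person inference: predictor scoring, within/between
# centering, random-intercept models with CR2 cluster-robust SE and
# Satterthwaite df, Freedman-Lane permutation nested within participants,
# max-cluster-extent FWE, parcel-level posteriors with sign-error-controlled
# selection, and the design power simulation.

#' Decompose a longitudinal predictor into within/between components
#'
#' x_w = x - person mean; x_b = person mean - grand mean. The reconstruction
#' x = grand mean + x_b + x_w holds exactly.
#'
#' @param raw data.frame with columns participant, session, x.
#' @return a \linkS4class{PredictorPanel}.
#' @export
centerWithinBetween <- function(raw) {
  need <- c("participant", "session", "x")
  if (!all(need %in% names(raw)))
    .err("raw predictor needs columns participant, session, x",
         "boldrel_invalid_parameter")
  pm <- tapply(raw$x, raw$participant, mean)
  gm <- mean(pm)  # grand mean as mean of person means (balanced-robust)
  d <- raw[c("participant", "session", "x")]
  d$xBetween <- as.numeric(pm[as.character(d$participant)]) - gm
  # enforce the identity x = grand mean + between + within exactly
  d$xWithin <- d$x - gm - d$xBetween
  row.names(d) <- NULL
  new("PredictorPanel", data = d, grandMean = gm, metadata = list())
}

#' Mean nightly sleep hours over the two weeks before a scan
#'
#' Days run 19:00 to 19:00. Per window, the durations of all sleep events
#' intersected with the window are summed (naps included, awake gaps
#' excluded); events spanning 19:00 are split across windows. The mean is
#' taken over observed windows (windows with any sleep), and a missing-value
#' sentinel is returned when fewer than `minWindows` of the 14 windows are
#' observed.
#'
#' @param days data.frame of sleep events with columns onset, offset
#'   (POSIXct); rows for a single participant.
#' @param scanDate Date of the scan.
#' @param minWindows minimum observed windows required (default 7 of 14).
#' @param tz timezone in which 19:00 is defined (default UTC).
#' @return mean nightly hours, or NA with attribute `reason` when coverage
#'   is insufficient.
#' @export
aggregateSleep <- function(days, scanDate, minWindows = 7L, tz = "UTC") {
  if (any(days$offset <= days$onset))
    .err("sleep offsets must follow onsets", "boldrel_invalid_parameter")
  ends <- as.POSIXct(paste(scanDate - (0:13), "19:00:00"), tz = tz)
  hours <- vapply(ends, function(e) {
    s <- e - 86400
    ov <- pmin(as.numeric(days$offset), as.numeric(e)) -
      pmax(as.numeric(days$onset), as.numeric(s))
    sum(pmax(ov, 0)) / 3600
  }, numeric(1))
  observed <- hours > 0
  if (sum(observed) < minWindows) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "only %d of 14 pre-scan sleep windows observed (need >= %d)",
      sum(observed), minWindows)
    return(out)
  }
  mean(hours[observed])
}

.severityGrid <- seq(1, 5, by = 0.5)

#' Monthly stress scores from event lists
#'
#' `sleSumScore` returns the episodic score: the sum of severity scores over
#' all episodic events (zero when no events are reported). `chronicScore`
#' returns the maximum chronic severity across life domains. Severities must
#' lie on the 1-5 half-point grid.
#'
#' @param events data.frame with columns severity, type (and domain) for one
#'   participant-month; may have zero rows.
#' @return numeric(1).
#' @export
sleSumScore <- function(events) {
  if (nrow(events) == 0L) return(0)
  if (!all(events$severity %in% .severityGrid))
    .err("severities must lie on the 1-5 half-point grid",
         "boldrel_validation_error")
  sum(events$severity[events$type == "episodic"])
}

#' @rdname sleSumScore
#' @export
chronicScore <- function(events) {
  if (nrow(events) == 0L) return(0)
  if (!all(events$severity %in% .severityGrid))
    .err("severities must lie on the 1-5 half-point grid",
         "boldrel_validation_error")
  ch <- events$severity[events$type == "chronic"]
  if (length(ch) == 0L) return(0)
  max(ch)
}

# REML random-intercept fit; returns beta, variance components and residuals.
# Falls back to OLS when the mixed fit degenerates (e.g. zero residual
# variance in noise-free data).
.fitRandomIntercept <- function(y, X, cluster) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    .err(paste("design is rank deficient; collinear columns:",
               paste(bad, collapse = ", ")), "boldrel_rank_deficiency")
  }
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  df$.cl <- cluster
  fixed <- stats::reformulate(colnames(df)[seq_len(ncol(X) - 1L)],
                              response = ".y")
  # returnObject = TRUE deliberately keeps non-converged fits (their
  # convergence warnings included), since degenerate solutions fall through
  # to the OLS path below
  fit <- tryCatch(
    suppressWarnings(
      nlme::lme(fixed, random = ~ 1 | .cl, data = df, method = "REML",
                control = nlme::lmeControl(returnObject = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
    s2l <- vc[1]; s2e <- vc[2]
    beta <- nlme::fixef(fit)
    if (is.finite(s2l) && is.finite(s2e) && s2e > 1e-12 * stats::var(y)) {
      e <- y - as.vector(X %*% beta)
      return(list(beta = beta, s2l = s2l, s2e = s2e, e = e))
    }
  }
  beta <- qr.coef(qrX, y)
  e <- y - as.vector(X %*% beta)
  s2e <- max(sum(e^2) / max(length(y) - ncol(X), 1L), .Machine$double.xmin)
  list(beta = beta, s2l = 0, s2e = s2e, e = e)
}

.blocksFromCluster <- function(cluster) {
  split(seq_along(cluster), cluster)
}

# p-value and signed Z from t statistic with Satterthwaite df
.tToZ <- function(tstat, df) {
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  z <- sign(tstat) * stats::qnorm(p / 2, lower.tail = FALSE)
  list(p = p, z = z)
}

#' Fit the longitudinal within-person model with robust inference
#'
#' Random-intercept linear mixed model (REML)
#' y = b0 + b_time * time + b_between * x_b + b_within * x_w + lambda_j + e,
#' with CR2 cluster-robust standard errors (clustered by participant) and
#' Satterthwaite degrees of freedom; two-sided p-values from t(df) are
#' converted to signed Z statistics.
#'
#' @param outcome data.frame with columns participant, session, y.
#' @param pred a \linkS4class{PredictorPanel} sharing keys with `outcome`.
#' @param time numeric vector of months since first visit, aligned with
#'   `outcome` rows; defaults to session - 1.
#' @return a \linkS4class{LongitudinalFit}.
#' @export
fitLongitudinalModel <- function(outcome, pred, time = NULL) {
  stopifnot(is(pred, "PredictorPanel"))
  pd <- pred@data
  m <- match(paste(outcome$participant, outcome$session),
             paste(pd$participant, pd$session))
  if (anyNA(m))
    .err("outcome and predictor keys do not align", "boldrel_alignment_error")
  if (length(unique(outcome$participant)) < 5L)
    .err("need at least 5 participants", "boldrel_insufficient_data")
  sess <- table(outcome$participant)
  if (min(sess) < 3L)
    .err("need at least 3 sessions per participant",
         "boldrel_insufficient_data")
  if (is.null(time)) time <- outcome$session - 1
  X <- cbind(`(Intercept)` = 1, time = time, xBetween = pd$xBetween[m],
             xWithin = pd$xWithin[m])
  cluster <- factor(outcome$participant)
  fit <- .fitRandomIntercept(outcome$y, X, cluster)
  blocks <- .blocksFromCluster(cluster)
  theta <- fit$s2l / fit$s2e
  rob <- .crVcovDf(X, blocks, theta, fit$e)
  se <- sqrt(diag(rob$vcov))
  tz <- .tToZ(fit$beta / se, rob$df)
  beta <- fit$beta
  names(beta) <- colnames(X)
  new("LongitudinalFit", coefficients = beta, vcovRobust = rob$vcov,
      df = rob$df, p = stats::setNames(tz$p, colnames(X)),
      z = stats::setNames(tz$z, colnames(X)),
      varComps = c(sigmaLambda2 = fit$s2l, sigmaEps2 = fit$s2e),
      nObs = nrow(outcome), nClusters = length(blocks))
}

#' Generate within-participant permutations
#'
#' Each permutation shuffles observation indices only within participant
#' blocks. The first row is always the identity (so the observed statistic
#' belongs to its own null set); random rows are distinct and exclude the
#' identity unless the block structure admits no other permutation. With
#' `exhaustive = TRUE` all distinct permutations are enumerated.
#'
#' @param blocks list of integer vectors: observation indices per participant.
#' @param nPerm number of random permutations (rows beyond the identity).
#' @param seed integer seed.
#' @param exhaustive enumerate all block-wise permutations instead.
#' @return a \linkS4class{PermutationSet}.
#' @export
makeWithinPermutations <- function(blocks, nPerm, seed, exhaustive = FALSE) {
  n <- sum(lengths(blocks))
  identity <- seq_len(n)
  if (exhaustive) {
    permsOf <- function(v) {
      if (length(v) <= 1L) return(matrix(v, nrow = 1L))
      out <- NULL
      for (i in seq_along(v))
        out <- rbind(out, cbind(v[i], permsOf(v[-i])))
      out
    }
    rows <- matrix(identity, nrow = 1L)
    for (b in blocks) {
      pb <- permsOf(b)
      rows <- do.call(rbind, lapply(seq_len(nrow(pb)), function(i) {
        r <- rows
        r[, b] <- matrix(pb[i, ], nrow(rows), length(b), byrow = TRUE)
        r
      }))
    }
    ord <- do.call(order, as.data.frame(rows))
    rows <- rows[ord, , drop = FALSE]
    idRow <- which(apply(rows, 1L, function(r) all(r == identity)))
    rows <- rbind(identity, rows[-idRow, , drop = FALSE])
    return(new("PermutationSet", indices = unname(rows), blocks = blocks))
  }
  if (nPerm < 1L)
    .err("nPerm must be >= 1", "boldrel_invalid_parameter")
  rows <- withr::with_seed(seed, {
    seen <- new.env(hash = TRUE)
    assign(paste(identity, collapse = ","), TRUE, envir = seen)
    out <- vector("list", nPerm)
    got <- 0L
    tries <- 0L
    while (got < nPerm && tries < 50L * nPerm + 100L) {
      tries <- tries + 1L
      r <- identity
      for (b in blocks) r[b] <- b[sample.int(length(b))]
      key <- paste(r, collapse = ",")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      out[[got]] <- r
    }
    do.call(rbind, out[seq_len(got)])
  })
  if (is.null(rows) || nrow(rows) < nPerm)
    .err(sprintf(
      "only %d distinct non-identity permutations found (requested %d)",
      if (is.null(rows)) 0L else nrow(rows), nPerm),
      "boldrel_insufficient_data")
  new("PermutationSet", indices = unname(rbind(identity, rows)),
      blocks = blocks)
}

#' Freedman-Lane permutation null for the within-person coefficient
#'
#' Residualizes the outcome on the nuisance covariates (time and the
#' between-person predictor component) under a random-intercept model, adds
#' within-participant-permuted residuals back to the fixed-effect fitted
#' values, refits the full model, and records the within-person coefficient's
#' signed Z through the identical CR2/Satterthwaite pipeline. The first
#' element (identity permutation) reproduces the observed Z exactly.
#'
#' @param outcome data.frame with columns participant, session, y.
#' @param pred a \linkS4class{PredictorPanel}.
#' @param perms a \linkS4class{PermutationSet} over the rows of `outcome`.
#' @param time optional time covariate (months since first visit).
#' @return numeric vector of Z statistics, one per permutation row; the
#'   first is the observed statistic.
#' @export
freedmanLaneNull <- function(outcome, pred, perms, time = NULL) {
  stopifnot(is(perms, "PermutationSet"))
  pd <- pred@data
  m <- match(paste(outcome$participant, outcome$session),
             paste(pd$participant, pd$session))
  if (anyNA(m))
    .err("outcome and predictor keys do not align", "boldrel_alignment_error")
  if (is.null(time)) time <- outcome$session - 1
  cluster <- factor(outcome$participant)
  Xred <- cbind(`(Intercept)` = 1, time = time, xBetween = pd$xBetween[m])
  red <- .fitRandomIntercept(outcome$y, Xred, cluster)
  fitted <- as.vector(Xred %*% red$beta)
  resid <- outcome$y - fitted
  idx <- perms@indices
  vapply(seq_len(nrow(idx)), function(i) {
    oc <- outcome
    oc$y <- fitted + resid[idx[i, ]]
    f <- tryCatch(fitLongitudinalModel(oc, pred, time = time),
                  error = function(e)
                    .err(sprintf("fit failed at permutation %d: %s", i,
                                 conditionMessage(e)),
                         "boldrel_permutation_fit_error"))
    f@z[["xWithin"]]
  }, numeric(1))
}

# 6-connectivity components of a logical 3-D array; returns integer labels
.labelComponents6 <- function(b) {
  shape <- dim(b)
  idx <- which(b)
  lab <- integer(length(idx))
  if (length(idx) == 0L)
    return(list(labels = integer(0), index = idx, sizes = integer(0)))
  pos <- match(seq_len(prod(shape)), idx)  # linear -> compact index
  parent <- seq_along(idx)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lin0 <- idx - 1L
  ci <- lin0 %% shape[1]
  cj <- (lin0 %/% shape[1]) %% shape[2]
  ck <- lin0 %/% (shape[1] * shape[2])
  offs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  strides <- c(1L, shape[1], shape[1] * shape[2])
  for (a in 1:3) {
    ok <- switch(a, ci < shape[1] - 1L, cj < shape[2] - 1L, ck < shape[3] - 1L)
    nb <- pos[idx[ok] + strides[a]]
    hit <- which(!is.na(nb))
    src <- which(ok)[hit]
    dst <- nb[hit]
    for (t in seq_along(src)) {
      r1 <- findRoot(src[t]); r2 <- findRoot(dst[t])
      if (r1 != r2) parent[r2] <- r1
    }
  }
  roots <- vapply(seq_along(idx), findRoot, integer(1))
  lab <- match(roots, unique(roots))
  list(labels = lab, index = idx, sizes = tabulate(lab))
}

#' Max-cluster-extent familywise error control
#'
#' Simplified permutation cluster correction: |Z| maps are binarized at the
#' two-sided cluster-forming threshold, 6-connectivity components are formed
#' within the mask, and the null distribution of the maximum cluster extent
#' (over permutation maps) calibrates the familywise threshold. Observed
#' clusters survive only when strictly larger than the (1 - alpha) quantile
#' of the null maxima.
#'
#' @param observedZ 3-D numeric array of Z statistics.
#' @param nullZ list of 3-D arrays, or a matrix with one column per
#'   permutation and one row per in-mask voxel (mask order = array order).
#' @param mask logical array; NULL means all voxels.
#' @param clusterFormingP two-sided cluster-forming p threshold.
#' @param alpha familywise error level.
#' @return data.frame with one row per observed cluster: id, extent, peakZ,
#'   peak i/j/k (0-based), survives; the null maxima and the critical extent
#'   are attached as attributes `nullMax` and `critical`.
#' @export
clusterFweThreshold <- function(observedZ, nullZ, mask = NULL,
                                clusterFormingP = 0.01, alpha = 0.05) {
  shape <- dim(observedZ)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  zc <- stats::qnorm(1 - clusterFormingP / 2)
  if (is.matrix(nullZ)) {
    nperm <- ncol(nullZ)
    maskIdx <- which(mask)
    if (nrow(nullZ) != length(maskIdx))
      .err("null matrix rows must match in-mask voxel count",
           "boldrel_invalid_parameter")
    getNull <- function(i) {
      a <- array(0, dim = shape)
      a[maskIdx] <- nullZ[, i]
      a
    }
  } else {
    nperm <- length(nullZ)
    getNull <- function(i) nullZ[[i]]
  }
  if (nperm == 0L)
    .err("at least one null volume is required", "boldrel_invalid_parameter")
  if (nperm < 100L)
    warning("fewer than 100 null volumes: familywise threshold is imprecise")
  nullMax <- vapply(seq_len(nperm), function(i) {
    cc <- .labelComponents6(abs(getNull(i)) >= zc & mask)
    if (length(cc$sizes)) max(cc$sizes) else 0L
  }, integer(1))
  critical <- as.integer(stats::quantile(nullMax, 1 - alpha, type = 1))
  cc <- .labelComponents6(abs(observedZ) >= zc & mask)
  if (length(cc$sizes) == 0L) {
    out <- data.frame(id = integer(0), extent = integer(0),
                      peakZ = numeric(0), i = integer(0), j = integer(0),
                      k = integer(0), survives = logical(0))
  } else {
    rows <- lapply(seq_along(cc$sizes), function(l) {
      vox <- cc$index[cc$labels == l]
      zv <- observedZ[vox]
      pk <- vox[which.max(abs(zv))] - 1L
      data.frame(id = l, extent = cc$sizes[l], peakZ = zv[which.max(abs(zv))],
                 i = pk %% shape[1], j = (pk %/% shape[1]) %% shape[2],
                 k = pk %/% (shape[1] * shape[2]),
                 survives = cc$sizes[l] > critical)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$extent), ]
    row.names(out) <- NULL
  }
  attr(out, "nullMax") <- nullMax
  attr(out, "critical") <- critical
  out
}

#' Parcel-level posterior of the within-person coefficient
#'
#' Fits the longitudinal model to voxel-level rows of one parcel with
#' participant and participant-session random intercepts, which averages
#' across voxels in a model-based way, and returns posterior draws of the
#' within-person coefficient with its sign-agreement probability.
#'
#' @param panel a \linkS4class{VoxelPanel} restricted to one parcel.
#' @param pred a \linkS4class{PredictorPanel}.
#' @param backend "mcmc" (JAGS) or "approx" (REML fit with draws from the
#'   asymptotic normal distribution of the coefficient).
#' @param time optional time covariate per participant-session (defaults to
#'   session - 1).
#' @param nDraws posterior draws (per chain for "mcmc").
#' @param nChains,nAdapt MCMC settings.
#' @param seed integer seed.
#' @return a \linkS4class{ParcelPosterior}.
#' @export
fitParcelPosterior <- function(panel, pred, backend = c("approx", "mcmc"),
                               time = NULL, nDraws = 1000L, nChains = 2L,
                               nAdapt = 500L, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(is(panel, "VoxelPanel"), is(pred, "PredictorPanel"))
  d <- panel@data
  if (length(unique(d$parcel)) != 1L)
    .err("panel must contain a single parcel", "boldrel_invalid_parameter")
  if (panel@nVoxels < 2L)
    .err("need at least 2 voxels", "boldrel_insufficient_data")
  pd <- pred@data
  m <- match(paste(d$participant, d$session),
             paste(pd$participant, pd$session))
  if (anyNA(m))
    .err("panel and predictor keys do not align", "boldrel_alignment_error")
  tt <- if (is.null(time)) d$session - 1 else time
  df <- data.frame(y = d$value, time = tt, xb = pd$xBetween[m],
                   xw = pd$xWithin[m],
                   pid = factor(d$participant),
                   ps = factor(paste(d$participant, d$session)))
  if (backend == "approx") {
    fit <- lme4::lmer(y ~ time + xb + xw + (1 | pid) + (1 | ps), data = df,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    est <- lme4::fixef(fit)[["xw"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["xw"]]
    draws <- withr::with_seed(seed, stats::rnorm(nDraws * nChains, est, se))
  } else {
    draws <- .jagsParcelPosterior(df, nDraws = nDraws, nChains = nChains,
                                  nAdapt = nAdapt, seed = seed)
  }
  med <- stats::median(draws)
  pPos <- mean(draws > 0)
  pS <- max(pPos, 1 - pPos)
  new("ParcelPosterior", parcel = as.character(d$parcel[1]), draws = draws,
      median = med, pSign = pS)
}

#' Sign-error-controlled parcel selection
#'
#' Orders parcels by sign-agreement probability (descending, ties broken by
#' parcel id), computes the cumulative product (the probability of no sign
#' error among the prefix), and selects the maximal prefix whose cumulative
#' product stays at or above 1 - errorBudget.
#'
#' @param parcels list of \linkS4class{ParcelPosterior} objects, or a
#'   data.frame with columns parcel, pSign.
#' @param errorBudget allowed probability of any sign error (default 0.05).
#' @return data.frame with columns parcel, pSign, cumProduct, selected,
#'   ordered as ranked.
#' @export
signErrorSelect <- function(parcels, errorBudget = 0.05) {
  if (errorBudget <= 0 || errorBudget >= 1)
    .err("errorBudget must be in (0, 1)", "boldrel_invalid_parameter")
  tab <- if (is.data.frame(parcels)) {
    data.frame(parcel = as.character(parcels$parcel), pSign = parcels$pSign)
  } else {
    data.frame(parcel = vapply(parcels, function(p) p@parcel, character(1)),
               pSign = vapply(parcels, signProb, numeric(1)))
  }
  tab <- tab[order(-tab$pSign, tab$parcel), ]
  tab$cumProduct <- cumprod(tab$pSign)
  tab$selected <- tab$cumProduct >= 1 - errorBudget
  if (any(!tab$selected))  # a prefix: nothing after the first failure
    tab$selected[seq(which(!tab$selected)[1], nrow(tab))] <- FALSE
  row.names(tab) <- NULL
  tab
}

#' Monte-Carlo power for the within-person coefficient test
#'
#' Simulates a standardized outcome from a random-intercept model with
#' intercept variance share tau2 and a standardized within-person predictor,
#' fits the longitudinal model with CR2 robust SE and Satterthwaite df, and
#' returns the rejection fraction at level alpha.
#'
#' @param nParticipants,nSessions design size.
#' @param betaWithinStd standardized within-person slope.
#' @param nSim number of simulation replicates (>= 100).
#' @param alpha test level.
#' @param seed integer seed.
#' @param tau2 random-intercept variance share of the standardized outcome.
#' @return list with power, mcse (binomial Monte-Carlo SE), nSim, alpha.
#' @export
estimatePower <- function(nParticipants = 30L, nSessions = 10L,
                          betaWithinStd = 0.17, nSim = 1000L, alpha = 0.05,
                          seed = 1L, tau2 = 0.07) {
  if (nSim < 100L)
    .err("nSim must be at least 100", "boldrel_invalid_parameter")
  n <- nParticipants; s <- nSessions
  rej <- withr::with_seed(seed, {
    vapply(seq_len(nSim), function(r) {
      raw <- data.frame(participant = rep(seq_len(n), each = s),
                        session = rep(seq_len(s), n),
                        x = stats::rnorm(n * s))
      pred <- centerWithinBetween(raw)
      lam <- stats::rnorm(n, 0, sqrt(tau2))
      y <- betaWithinStd * pred@data$xWithin + lam[raw$participant] +
        stats::rnorm(n * s, 0, sqrt(1 - tau2))
      oc <- data.frame(participant = raw$participant,
                       session = raw$session, y = y)
      fit <- fitLongitudinalModel(oc, pred)
      fit@p[["xWithin"]] < alpha
    }, logical(1))
  })
  pw <- mean(rej)
  list(power = pw, mcse = sqrt(pw * (1 - pw) / nSim), nSim = nSim,
       alpha = alpha)
}
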