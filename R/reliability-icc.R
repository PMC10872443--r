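# Reliability statistics: pairwise test-retest ICC with meta-analytic
# pooling, within-session internal consistency from the three-level model,
# multilevel alpha, and one-way ICC(1,1).

.clampLogit <- function(p, eps = 1e-6) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Fit the two-level variance-component model for a session pair
#'
#' Model: y_ij = b0 + b_i + pi_j + eps_ij for two adjacent sessions, with a
#' participant random intercept. The MCMC backend uses weakly-informative
#' half-Student-t(3, 2.5 sd(y)) priors on SDs; the REML backend is a
#' restricted-maximum-likelihood point fit whose uncertainty is propagated
#' by drawing balanced-ANOVA mean squares from their sampling distributions.
#'
#' @param values data.frame with columns participant, session, value; exactly
#'   two sessions, one value per participant-session (e.g. a parcel mean).
#' @param backend "mcmc" or "reml".
#' @param nChains,nDraws MCMC settings (split-Rhat on the ICC is checked
#'   against 1.01 for the MCMC backend).
#' @param seed integer seed.
#' @return list with `draws` (data.frame with columns sigmaPi2, sigmaEps2),
#'   `backend`, and point estimates `sigmaPi2`, `sigmaEps2`.
#' @export
fitVarianceComponents2Level <- function(values, backend = c("mcmc", "reml"),
                                        nChains = 4L, nDraws = 1000L,
                                        seed = 1L) {
  backend <- match.arg(backend)
  sessions <- sort(unique(values$session))
  if (length(sessions) != 2L)
    .err("exactly two sessions are required", "boldrel_invalid_parameter")
  if (length(unique(values$participant)) < 3L)
    .err("need at least 3 participants", "boldrel_insufficient_data")
  if (backend == "mcmc") {
    dm <- .jags2Level(values$value, values$session, values$participant,
                      nChains = nChains, nDraws = nDraws, seed = seed)
    draws <- data.frame(sigmaPi2 = dm[, "sigmaPi2"],
                        sigmaEps2 = dm[, "sigmaEps2"])
    icc <- draws$sigmaPi2 / (draws$sigmaPi2 + draws$sigmaEps2)
    rh <- .splitRhat(icc, nChains)
    if (is.finite(rh) && rh > 1.01)
      warning(sprintf("split-Rhat %.3f > 1.01 for ICC draws", rh))
    return(list(draws = draws, backend = "mcmc",
                sigmaPi2 = stats::median(draws$sigmaPi2),
                sigmaEps2 = stats::median(draws$sigmaEps2)))
  }
  fit <- lme4::lmer(value ~ factor(session) + (1 | participant),
                    data = values, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2p <- vc$vcov[vc$grp == "participant"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  # uncertainty from the balanced two-way ANOVA mean squares: MS_P with
  # df N-1, MS_E with df (N-1)(k-1), k = 2 sessions
  N <- length(unique(values$participant)); k <- 2L
  emsP <- s2e + k * s2p
  draws <- withr::with_seed(seed, {
    msP <- emsP * stats::rchisq(2000L, N - 1L) / (N - 1L)
    msE <- s2e * stats::rchisq(2000L, (N - 1L) * (k - 1L)) /
      ((N - 1L) * (k - 1L))
    data.frame(sigmaPi2 = pmax((msP - msE) / k, 0), sigmaEps2 = msE)
  })
  list(draws = draws, backend = "reml", sigmaPi2 = s2p, sigmaEps2 = s2e)
}

#' Pairwise ICC from variance components
#'
#' ICC_pair = sigma_pi^2 / (sigma_pi^2 + sigma_eps^2); vectorized so it can
#' be applied per posterior draw.
#'
#' @param sigmaPi2,sigmaEps2 non-negative variances (vectors of equal
#'   length).
#' @return ICC values in [0, 1].
#' @export
iccPairFromComponents <- function(sigmaPi2, sigmaEps2) {
  if (any(sigmaPi2 < 0) || any(sigmaEps2 < 0))
    .err("variances must be non-negative", "boldrel_invalid_parameter")
  tot <- sigmaPi2 + sigmaEps2
  if (any(tot == 0))
    .err("ICC undefined when both variances are zero",
         "boldrel_undefined_ratio")
  sigmaPi2 / tot
}

#' Pairwise test-retest ICC for one session pair of a parcel panel
#'
#' Averages voxels to one value per participant-session, fits the two-level
#' model and summarizes the ICC posterior.
#'
#' @param values data.frame with columns participant, session, value.
#' @param pair integer(2) session indices.
#' @inheritParams fitVarianceComponents2Level
#' @return an \linkS4class{ICCEstimate}.
#' @export
estimatePairICC <- function(values, pair, backend = c("mcmc", "reml"),
                            nChains = 4L, nDraws = 1000L, seed = 1L) {
  backend <- match.arg(backend)
  sub <- values[values$session %in% pair, ]
  fit <- fitVarianceComponents2Level(sub, backend = backend,
                                     nChains = nChains, nDraws = nDraws,
                                     seed = seed)
  icc <- iccPairFromComponents(fit$draws$sigmaPi2, fit$draws$sigmaEps2)
  new("ICCEstimate", pair = as.integer(pair), draws = icc,
      median = stats::median(icc),
      logitSd = stats::sd(.clampLogit(icc)), backend = fit$backend)
}

#' Pairwise ICCs across adjacent sessions
#'
#' Fits the two-level model for each pair of adjacent sessions. Pairs are
#' overlapping by default ((1,2), (2,3), ..., (S-1,S)); `disjoint = TRUE`
#' uses (1,2), (3,4), ...
#'
#' @param panel a \linkS4class{VoxelPanel} for one parcel, or a data.frame
#'   with columns participant, session, value (one row per
#'   participant-session).
#' @param disjoint use disjoint adjacent pairs.
#' @inheritParams fitVarianceComponents2Level
#' @return list of \linkS4class{ICCEstimate} objects.
#' @export
adjacentPairICC <- function(panel, backend = c("mcmc", "reml"),
                            disjoint = FALSE, nChains = 4L, nDraws = 1000L,
                            seed = 1L) {
  backend <- match.arg(backend)
  values <- if (is(panel, "VoxelPanel")) {
    d <- panel@data
    ag <- stats::aggregate(value ~ participant + session, data = d, FUN = mean)
    ag
  } else panel
  S <- max(values$session)
  starts <- if (disjoint) seq(1L, S - 1L, by = 2L) else seq_len(S - 1L)
  lapply(starts, function(s)
    estimatePairICC(values, c(s, s + 1L), backend = backend,
                    nChains = nChains, nDraws = nDraws, seed = seed + s))
}

#' Meta-analytically pool pairwise ICC estimates
#'
#' Normal-normal hierarchical model on the logit scale: observed logit-ICC
#' medians ~ Normal(latent, SE), latent ~ Normal(mu, sigma). The pooled ICC
#' is the inverse-logit of the posterior of mu (median and 95% credible
#' interval). ICC draws are clamped to [1e-6, 1 - 1e-6] before the logit.
#'
#' @param estimates list of \linkS4class{ICCEstimate} objects (>= 2).
#' @param fixedSigma fix the between-pair SD at zero (fixed-effect pooling).
#' @param nChains,nDraws MCMC settings.
#' @param seed integer seed.
#' @return a \linkS4class{PooledICC}.
#' @export
poolICCMeta <- function(estimates, fixedSigma = FALSE, nChains = 4L,
                        nDraws = 1000L, seed = 1L) {
  if (length(estimates) < 2L)
    .err("need at least 2 pairwise estimates", "boldrel_invalid_parameter")
  yobs <- vapply(estimates, function(e) .clampLogit(e@median), numeric(1))
  sei <- vapply(estimates, function(e) e@logitSd, numeric(1))
  if (any(!is.finite(yobs)) || any(!is.finite(sei)) || any(sei <= 0))
    .err("logit summaries must be finite with positive SE",
         "boldrel_invalid_input")
  dm <- .jagsMeta(yobs, sei, fixedSigma = fixedSigma, nChains = nChains,
                  nDraws = nDraws, seed = seed)
  mu <- dm[, "mu"]
  icc <- stats::plogis(mu)
  new("PooledICC", muDraws = as.numeric(mu),
      sigmaDraws = as.numeric(dm[, "sigma"]),
      median = stats::median(icc),
      ci = unname(stats::quantile(icc, c(0.025, 0.975))))
}

#' Internal consistency of a parcel across voxels
#'
#' Fits the three-level model y_ijk = b0 + b_i + lambda_j + pi_jk + eps_ijk
#' with session fixed effects and reports
#' ICC_within = sigma_pi^2 / (sigma_lambda^2 + sigma_pi^2 + sigma_eps^2)
#' as the raw proportion of variance (no division of the error term by the
#' voxel count).
#'
#' @param panel a \linkS4class{VoxelPanel} for one parcel (>= 2 sessions,
#'   >= 3 participants, >= 2 voxels).
#' @param backend "reml" (lme4 point fit, interval from balanced-ANOVA mean
#'   squares drawn from their sampling distributions) or "mcmc" (JAGS).
#' @param nChains,nDraws MCMC settings.
#' @param seed integer seed.
#' @return an \linkS4class{ICCWithinEstimate}.
#' @export
fitInternalConsistency <- function(panel, backend = c("reml", "mcmc"),
                                   nChains = 4L, nDraws = 1000L, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(is(panel, "VoxelPanel"))
  d <- panel@data
  if (length(unique(d$parcel)) != 1L)
    .err("panel must contain a single parcel", "boldrel_invalid_parameter")
  if (panel@nVoxels < 2L || length(unique(d$voxel)) < 2L)
    .err("need at least 2 voxels", "boldrel_insufficient_data")
  if (panel@nSessions < 2L)
    .err("need at least 2 sessions", "boldrel_insufficient_data")
  if (panel@nParticipants < 3L)
    .err("need at least 3 participants", "boldrel_insufficient_data")
  if (backend == "mcmc") {
    dm <- .jags3Level(d$value, d$session, d$participant, nChains = nChains,
                      nDraws = nDraws, seed = seed)
    icc <- dm[, "sigmaPi2"] /
      (dm[, "sigmaLambda2"] + dm[, "sigmaPi2"] + dm[, "sigmaEps2"])
    comp <- c(sigmaLambda2 = stats::median(dm[, "sigmaLambda2"]),
              sigmaPi2 = stats::median(dm[, "sigmaPi2"]),
              sigmaEps2 = stats::median(dm[, "sigmaEps2"]))
    return(new("ICCWithinEstimate", parcel = as.character(d$parcel[1]),
               median = stats::median(icc),
               ci = unname(stats::quantile(icc, c(0.025, 0.975))),
               components = comp, draws = as.numeric(icc),
               backend = "mcmc"))
  }
  d$ps <- paste(d$participant, d$session)
  fit <- lme4::lmer(value ~ factor(session) + (1 | participant) + (1 | ps),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2l <- vc$vcov[vc$grp == "participant"]
  s2p <- vc$vcov[vc$grp == "ps"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  # interval via balanced nested ANOVA expected mean squares:
  # E[MS_P] = s2e + V s2p + S V s2l  (df N-1)
  # E[MS_PS] = s2e + V s2p           (df N(S-1) less S-1 session-effect df)
  # E[MS_E] = s2e                    (df N S (V-1))
  N <- panel@nParticipants; S <- panel@nSessions; V <- panel@nVoxels
  dfP <- N - 1L
  dfPS <- (N - 1L) * (S - 1L)
  dfE <- N * S * (V - 1L)
  emsP <- s2e + V * s2p + S * V * s2l
  emsPS <- s2e + V * s2p
  icc <- withr::with_seed(seed, {
    msP <- emsP * stats::rchisq(2000L, dfP) / dfP
    msPS <- emsPS * stats::rchisq(2000L, dfPS) / dfPS
    msE <- s2e * stats::rchisq(2000L, dfE) / dfE
    l2 <- pmax((msP - msPS) / (S * V), 0)
    p2 <- pmax((msPS - msE) / V, 0)
    p2 / (l2 + p2 + msE)
  })
  new("ICCWithinEstimate", parcel = as.character(d$parcel[1]),
      median = s2p / (s2l + s2p + s2e),
      ci = unname(stats::quantile(icc, c(0.025, 0.975))),
      components = c(sigmaLambda2 = s2l, sigmaPi2 = s2p, sigmaEps2 = s2e),
      draws = as.numeric(icc), backend = "reml")
}

#' Multilevel coefficient alpha
#'
#' alpha = sigma_pi^2 / (sigma_lambda^2 + sigma_pi^2 + sigma_eps^2 / k):
#' the internal-consistency ratio with the error variance divided by the
#' item (voxel) count. Reduces to ICC_within at k = 1.
#'
#' @param sigmaLambda2,sigmaPi2,sigmaEps2 non-negative variance components.
#' @param k item count (>= 1).
#' @return alpha in [0, 1] for non-negative components.
#' @export
multilevelAlpha <- function(sigmaLambda2, sigmaPi2, sigmaEps2, k) {
  if (any(k < 1))
    .err("item count k must be >= 1", "boldrel_invalid_parameter")
  sigmaPi2 / (sigmaLambda2 + sigmaPi2 + sigmaEps2 / k)
}

#' One-way random-effects ICC(1,1)
#'
#' Between/(between + within) variance ratio from one-way ANOVA mean
#' squares; a negative between-unit variance estimate is truncated at zero.
#' Handles unbalanced groups via the standard n0 correction.
#'
#' @param x a \linkS4class{PredictorPanel}, or a data.frame with columns
#'   participant and a value column named `value` or `x`.
#' @return ICC(1,1) in [0, 1].
#' @export
iccOneway <- function(x) {
  d <- if (is(x, "PredictorPanel")) {
    data.frame(g = x@data$participant, v = x@data$x)
  } else {
    val <- if ("value" %in% names(x)) x$value else x$x
    data.frame(g = x$participant, v = val)
  }
  if (length(unique(d$g)) < 3L)
    .err("need at least 3 units", "boldrel_insufficient_data")
  if (min(table(d$g)) < 2L)
    .err("need at least 2 observations per unit",
         "boldrel_insufficient_data")
  if (stats::var(d$v) == 0)
    .err("all values constant: ICC undefined", "boldrel_degenerate_input")
  ni <- as.numeric(table(d$g))
  a <- length(ni); Ntot <- sum(ni)
  gm <- tapply(d$v, d$g, mean)
  ssb <- sum(ni * (gm - mean(d$v))^2)
  ssw <- sum((d$v - gm[as.character(d$g)])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (Ntot - a)
  n0 <- (Ntot - sum(ni^2) / Ntot) / (a - 1)
  s2b <- max((msb - msw) / n0, 0)
  s2b / (s2b + msw)
}
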