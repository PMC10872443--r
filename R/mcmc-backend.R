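# JAGS backend for the Bayesian variance-component models. Priors: improper
# (numerically flat) normals on means and fixed effects, half-Student-t(3,
# 2.5 * sd(y)) on standard deviations.

.runJags <- function(model, data, params, nChains = 4L, nAdapt = 1000L,
                     nBurn = 1000L, nDraws = 1000L, seed = 1L) {
  inits <- lapply(seq_len(nChains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + i) %% 2147483647L))
  jm <- rjags::jags.model(textConnection(model), data = data, inits = inits,
                          n.chains = nChains, n.adapt = nAdapt, quiet = TRUE)
  stats::update(jm, nBurn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, params, n.iter = nDraws,
                            progress.bar = "none")
  do.call(rbind, lapply(sm, as.matrix))
}

# two-level model y_ij = b0 + b_i + pi_j + eps for one session pair
.jags2LevelModel <- "
model {
  for (r in 1:N) {
    y[r] ~ dnorm(b0 + bs[sess[r]] + u[pid[r]], tauE)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tauU) }
  b0 ~ dnorm(0, 1e-8)
  bs[1] <- 0
  bs[2] ~ dnorm(0, 1e-8)
  sigmaE ~ dt(0, prec, 3) T(0,)
  sigmaU ~ dt(0, prec, 3) T(0,)
  tauE <- pow(sigmaE, -2)
  tauU <- pow(sigmaU, -2)
  sigmaPi2 <- pow(sigmaU, 2)
  sigmaEps2 <- pow(sigmaE, 2)
}"

.jags2Level <- function(y, session, participant, nChains = 4L,
                        nDraws = 1000L, seed = 1L) {
  pid <- as.integer(factor(participant))
  sess <- as.integer(factor(session))
  data <- list(y = y, sess = sess, pid = pid, N = length(y),
               J = max(pid), prec = (2.5 * stats::sd(y))^-2)
  .runJags(.jags2LevelModel, data, c("b0", "bs", "sigmaPi2", "sigmaEps2"),
           nChains = nChains, nDraws = nDraws, seed = seed)
}

# three-level model over voxel rows: participant and participant-session
# random intercepts, session fixed effects
.jags3LevelModel <- "
model {
  for (r in 1:N) {
    y[r] ~ dnorm(b0 + bs[sess[r]] + u[pid[r]] + v[psid[r]], tauE)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tauU) }
  for (k in 1:K) { v[k] ~ dnorm(0, tauV) }
  b0 ~ dnorm(0, 1e-8)
  bs[1] <- 0
  for (s in 2:S) { bs[s] ~ dnorm(0, 1e-8) }
  sigmaE ~ dt(0, prec, 3) T(0,)
  sigmaU ~ dt(0, prec, 3) T(0,)
  sigmaV ~ dt(0, prec, 3) T(0,)
  tauE <- pow(sigmaE, -2)
  tauU <- pow(sigmaU, -2)
  tauV <- pow(sigmaV, -2)
  sigmaLambda2 <- pow(sigmaU, 2)
  sigmaPi2 <- pow(sigmaV, 2)
  sigmaEps2 <- pow(sigmaE, 2)
}"

.jags3Level <- function(y, session, participant, nChains = 4L,
                        nDraws = 1000L, seed = 1L) {
  pid <- as.integer(factor(participant))
  sess <- as.integer(factor(session))
  psid <- as.integer(factor(paste(pid, sess)))
  data <- list(y = y, sess = sess, pid = pid, psid = psid, N = length(y),
               J = max(pid), K = max(psid), S = max(sess),
               prec = (2.5 * stats::sd(y))^-2)
  .runJags(.jags3LevelModel, data,
           c("sigmaLambda2", "sigmaPi2", "sigmaEps2"),
           nChains = nChains, nDraws = nDraws, seed = seed)
}

# normal-normal meta-analysis of logit-ICC summaries
.jagsMetaModel <- "
model {
  for (i in 1:K) {
    yobs[i] ~ dnorm(theta[i], pow(sei[i], -2))
    theta[i] ~ dnorm(mu, tauT)
  }
  mu ~ dnorm(0, 1e-8)
  sigma ~ dt(0, prec, 3) T(0,)
  tauT <- pow(sigma, -2)
}"

.jagsMetaFixedModel <- "
model {
  for (i in 1:K) {
    yobs[i] ~ dnorm(mu, pow(sei[i], -2))
  }
  mu ~ dnorm(0, 1e-8)
  sigma <- 0
}"

.jagsMeta <- function(yobs, sei, fixedSigma = FALSE, nChains = 4L,
                      nDraws = 1000L, seed = 1L) {
  data <- list(yobs = yobs, sei = sei, K = length(yobs))
  if (!fixedSigma)
    data$prec <- (2.5 * max(stats::sd(yobs), 0.05))^-2
  .runJags(if (fixedSigma) .jagsMetaFixedModel else .jagsMetaModel,
           data, c("mu", "sigma"), nChains = nChains, nDraws = nDraws,
           seed = seed)
}

# parcel-level longitudinal model over voxel rows
.jagsParcelModel <- "
model {
  for (r in 1:N) {
    y[r] ~ dnorm(b0 + bt * time[r] + bb * xb[r] + bw * xw[r] +
                 u[pid[r]] + v[psid[r]], tauE)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tauU) }
  for (k in 1:K) { v[k] ~ dnorm(0, tauV) }
  b0 ~ dnorm(0, 1e-8)
  bt ~ dnorm(0, 1e-8)
  bb ~ dnorm(0, 1e-8)
  bw ~ dnorm(0, 1e-8)
  sigmaE ~ dt(0, prec, 3) T(0,)
  sigmaU ~ dt(0, prec, 3) T(0,)
  sigmaV ~ dt(0, prec, 3) T(0,)
  tauE <- pow(sigmaE, -2)
  tauU <- pow(sigmaU, -2)
  tauV <- pow(sigmaV, -2)
}"

.jagsParcelPosterior <- function(df, nChains = 2L, nAdapt = 500L,
                                 nDraws = 1000L, seed = 1L) {
  data <- list(y = df$y, time = df$time, xb = df$xb, xw = df$xw,
               pid = as.integer(df$pid), psid = as.integer(df$ps),
               N = nrow(df), J = nlevels(df$pid), K = nlevels(df$ps),
               prec = (2.5 * stats::sd(df$y))^-2)
  draws <- .runJags(.jagsParcelModel, data, "bw", nChains = nChains,
                    nAdapt = nAdapt, nDraws = nDraws, seed = seed)
  as.numeric(draws[, "bw"])
}

# split-Rhat convergence diagnostic over a draws matrix split by chain
.splitRhat <- function(draws, nChains) {
  m <- matrix(draws, ncol = nChains)
  half <- floor(nrow(m) / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[half + seq_len(half), , drop = FALSE])
  W <- mean(apply(sub, 2, stats::var))
  B <- half * stats::var(colMeans(sub))
  sqrt(((half - 1) / half * W + B / half) / W)
}
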