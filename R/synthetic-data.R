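# Synthetic-data generators. These define the study conditions every
# downstream estimator is tested against: a three-level Gaussian variance
# structure for voxel contrasts, separable between/within variance for
# behavioral predictors, daily sleep records, and monthly stress-event lists.

#' Construct a VarianceComponents object
#'
#' @param grandMean overall mean of the contrast (beta0).
#' @param sessionEffects numeric vector of per-session fixed effects (beta_i).
#'   Defaults, given `nSessions`, to a linear habituation trend.
#' @param sigmaLambda2 participant-mean variance.
#' @param sigmaPi2 participant-session variance.
#' @param sigmaEps2 voxel error variance.
#' @param nSessions used only to build the default session-effect trend.
#' @param habituationSlope per-session change used for the default trend.
#' @return a \linkS4class{VarianceComponents}.
#' @export
varianceComponents <- function(grandMean = 0.25,
                               sessionEffects = NULL,
                               sigmaLambda2 = 0.07,
                               sigmaPi2 = 0.44,
                               sigmaEps2 = 0.49,
                               nSessions = 10L,
                               habituationSlope = -0.05) {
  if (any(!is.finite(c(sigmaLambda2, sigmaPi2, sigmaEps2))))
    .err("variance components must be finite", "boldrel_invalid_parameter")
  if (is.null(sessionEffects)) {
    sessionEffects <- habituationSlope * (seq_len(nSessions) - 1L)
    sessionEffects <- sessionEffects - mean(sessionEffects)
  }
  new("VarianceComponents", grandMean = grandMean,
      sessionEffects = as.numeric(sessionEffects),
      sigmaLambda2 = sigmaLambda2, sigmaPi2 = sigmaPi2,
      sigmaEps2 = sigmaEps2)
}

#' Construct a StudyConfig
#'
#' Defaults mirror a dense-sampling design of 30 participants scanned at 10
#' monthly sessions, with parcels split across cortex, subcortex and
#' matched-control anatomy.
#'
#' @param nParticipants,nSessions design size.
#' @param parcels data.frame with columns parcel, nVoxels, anatomy; a default
#'   set of 36 parcels (12 per anatomy class) is built when NULL.
#' @param nVoxels voxels per default parcel.
#' @param varComps a \linkS4class{VarianceComponents}.
#' @param betweenSd,withinSd SDs of the behavioral predictor components.
#' @param betaWithin,betaBetween,betaTime injected effect sizes.
#' @param seed integer seed recorded in all outputs.
#' @return a \linkS4class{StudyConfig}.
#' @export
studyConfig <- function(nParticipants = 30L, nSessions = 10L,
                        parcels = NULL, nVoxels = 50L,
                        varComps = varianceComponents(nSessions = nSessions),
                        betweenSd = sqrt(0.44), withinSd = sqrt(0.56),
                        betaWithin = 0.17, betaBetween = 0, betaTime = -0.05,
                        seed = 1L) {
  if (is.null(parcels)) {
    anatomy <- rep(c("cortex", "subcortex", "control"), each = 12L)
    # sizes vary deterministically around nVoxels so size can act as a
    # covariate downstream
    sizes <- as.integer(round(nVoxels * seq(0.6, 1.6, length.out = 12L)))
    parcels <- data.frame(
      parcel = sprintf("%s_%02d", anatomy, sequence(rep(12L, 3L))),
      nVoxels = rep(sizes, 3L),
      anatomy = anatomy
    )
  }
  new("StudyConfig", nParticipants = as.integer(nParticipants),
      nSessions = as.integer(nSessions), parcels = parcels,
      varComps = varComps, betweenSd = betweenSd, withinSd = withinSd,
      betaWithin = betaWithin, betaBetween = betaBetween,
      betaTime = betaTime, seed = as.integer(seed))
}

#' Generate a voxel contrast panel for one parcel
#'
#' Draws \eqn{y_{ijk} = \beta_0 + \beta_i + \lambda_j + \pi_{jk} +
#' \epsilon_{ijk}} with \eqn{\lambda_j \sim N(0, \sigma^2_\lambda)},
#' \eqn{\pi_{jk} \sim N(0, \sigma^2_\pi)} and
#' \eqn{\epsilon_{ijk} \sim N(0, \sigma^2_\epsilon)} over a complete
#' participant x session x voxel crossing.
#'
#' @param vc a \linkS4class{VarianceComponents}; its sessionEffects are
#'   recycled/truncated to `nSessions`.
#' @param nParticipants,nSessions,nVoxels design size.
#' @param seed integer seed; identical seeds give identical panels.
#' @param parcel parcel id stored in the panel.
#' @return a \linkS4class{VoxelPanel}.
#' @export
generateParcelVoxels <- function(vc, nParticipants, nSessions, nVoxels, seed,
                                 parcel = "parcel_01") {
  stopifnot(is(vc, "VarianceComponents"))
  validObject(vc)
  n <- as.integer(nParticipants); s <- as.integer(nSessions)
  v <- as.integer(nVoxels)
  if (n < 1L || s < 1L || v < 1L)
    .err("design sizes must be positive", "boldrel_invalid_parameter")
  se <- rep_len(vc@sessionEffects, s)
  d <- withr::with_seed(seed, {
    lambda <- rnorm(n, 0, sqrt(vc@sigmaLambda2))
    pi_jk <- rnorm(n * s, 0, sqrt(vc@sigmaPi2))
    eps <- rnorm(n * s * v, 0, sqrt(vc@sigmaEps2))
    d <- expand.grid(voxel = seq_len(v), session = seq_len(s),
                     participant = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    d$parcel <- parcel
    d$value <- vc@grandMean + se[d$session] +
      lambda[d$participant] +
      pi_jk[(d$participant - 1L) * s + d$session] + eps
    d[, c("participant", "session", "parcel", "voxel", "value")]
  })
  new("VoxelPanel", data = d, nParticipants = n, nSessions = s, nVoxels = v,
      metadata = list(seed = as.integer(seed), truth = list(
        grandMean = vc@grandMean, sessionEffects = se,
        sigmaLambda2 = vc@sigmaLambda2, sigmaPi2 = vc@sigmaPi2,
        sigmaEps2 = vc@sigmaEps2)))
}

#' Generate a longitudinal behavioral predictor panel
#'
#' One value per participant-session:
#' x = grand mean + b_j + w_{jk}, with b_j ~ N(0, betweenSd^2) and
#' w_{jk} ~ N(0, withinSd^2). The returned panel carries exact
#' within/between centered components.
#'
#' @param betweenSd,withinSd component SDs (>= 0).
#' @param nParticipants,nSessions design size.
#' @param seed integer seed.
#' @param grandMean overall mean of the raw predictor.
#' @return a \linkS4class{PredictorPanel}.
#' @export
generatePredictorPanel <- function(betweenSd, withinSd, nParticipants,
                                   nSessions, seed, grandMean = 0) {
  if (betweenSd < 0 || withinSd < 0 || !all(is.finite(c(betweenSd, withinSd))))
    .err("component SDs must be finite and >= 0", "boldrel_invalid_parameter")
  n <- as.integer(nParticipants); s <- as.integer(nSessions)
  raw <- withr::with_seed(seed, {
    b <- rnorm(n, 0, betweenSd)
    w <- rnorm(n * s, 0, withinSd)
    d <- expand.grid(session = seq_len(s), participant = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE)
    d$x <- grandMean + b[d$participant] + w
    d[, c("participant", "session", "x")]
  })
  p <- centerWithinBetween(raw)
  p@metadata <- list(seed = as.integer(seed), betweenSd = betweenSd,
                     withinSd = withinSd)
  p
}

#' Inject time/between/within effects into a voxel panel
#'
#' Adds beta_time * (session - 1) + beta_between * x_b + beta_within * x_w to
#' every voxel value; the ground-truth slopes are recorded in the panel
#' metadata. Time is in sessions (months) since the first visit.
#'
#' @param panel a \linkS4class{VoxelPanel}.
#' @param pred a \linkS4class{PredictorPanel} sharing participant/session keys.
#' @param betaWithin,betaBetween,betaTime slopes.
#' @return the modified \linkS4class{VoxelPanel}.
#' @export
injectWithinEffect <- function(panel, pred, betaWithin, betaBetween = 0,
                               betaTime = 0) {
  stopifnot(is(panel, "VoxelPanel"), is(pred, "PredictorPanel"))
  d <- panel@data
  pd <- pred@data
  key <- paste(d$participant, d$session)
  pkey <- paste(pd$participant, pd$session)
  m <- match(key, pkey)
  if (anyNA(m))
    .err("panel and predictor keys do not align", "boldrel_alignment_error")
  d$value <- d$value + betaTime * (d$session - 1L) +
    betaBetween * pd$xBetween[m] + betaWithin * pd$xWithin[m]
  out <- panel
  out@data <- d
  out@metadata$truth$betaWithin <- betaWithin
  out@metadata$truth$betaBetween <- betaBetween
  out@metadata$truth$betaTime <- betaTime
  out
}

#' Generate a 3-D integer label volume
#'
#' Regions are blocks or discrete spheres (voxel-center distance <= radius).
#' Overlapping regions are a specification error.
#'
#' @param shape integer(3) volume dimensions.
#' @param regionSpecs list of specs; each is a list with `label` (positive
#'   integer) and either `type = "block"` with `corner` (0-based integer(3))
#'   and `size` (integer(3)), or `type = "sphere"` with `center` (0-based
#'   numeric(3)) and `radius` (voxels).
#' @param voxelSize numeric(3) mm per axis.
#' @return a \linkS4class{LabelVolume}.
#' @export
generateLabelVolume <- function(shape, regionSpecs, voxelSize = c(3, 3, 3)) {
  shape <- as.integer(shape)
  arr <- array(0L, dim = shape)
  for (spec in regionSpecs) {
    lab <- as.integer(spec$label)
    if (lab <= 0L)
      .err("labels must be positive integers", "boldrel_specification_error")
    if (identical(spec$type, "block")) {
      c0 <- as.integer(spec$corner); sz <- as.integer(spec$size)
      if (any(c0 < 0L) || any(c0 + sz > shape))
        .err("block does not fit within the volume",
             "boldrel_specification_error")
      idx <- as.matrix(expand.grid(c0[1] + seq_len(sz[1]) - 1L,
                                   c0[2] + seq_len(sz[2]) - 1L,
                                   c0[3] + seq_len(sz[3]) - 1L))
    } else if (identical(spec$type, "sphere")) {
      ctr <- spec$center; r <- spec$radius
      rng <- lapply(1:3, function(a) {
        lo <- max(0L, floor(ctr[a] - r)); hi <- min(shape[a] - 1L, ceiling(ctr[a] + r))
        seq.int(lo, hi)
      })
      idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
      idx <- idx[d2 <= r^2 + 1e-12, , drop = FALSE]
      if (any(idx < 0L) || any(t(t(idx) - (shape - 1L)) > 0L))
        .err("sphere does not fit within the volume",
             "boldrel_specification_error")
    } else {
      .err("unknown region type", "boldrel_specification_error")
    }
    lin <- 1L + idx[, 1] + shape[1] * idx[, 2] + shape[1] * shape[2] * idx[, 3]
    if (any(arr[lin] != 0L))
      .err(sprintf("region with label %d overlaps an existing region", lab),
           "boldrel_specification_error")
    arr[lin] <- lab
  }
  new("LabelVolume", labels = arr, voxelSize = as.numeric(voxelSize))
}

#' Generate daily sleep records and monthly stress-event lists
#'
#' Sleep: one nocturnal sleep event per day (onset around 23:00, duration
#' around 8 h) plus optional naps; events may span midnight. Stress: monthly
#' episodic events with severities on the 1-5 half-point grid, plus chronic
#' severities per life domain.
#'
#' @param nParticipants number of participants.
#' @param nDays days of actigraphy per participant (>= 14).
#' @param seed integer seed.
#' @param startDate first day of recording.
#' @param napProb probability of a daytime nap on a given day.
#' @param nMonths months of stress interviews.
#' @param episodicRate mean number of episodic events per month.
#' @return list with elements `sleep` (data.frame: participant, date, onset,
#'   offset as POSIXct UTC) and `stress` (data.frame: participant, month,
#'   severity, domain, type).
#' @export
generateSleepStress <- function(nParticipants, nDays, seed,
                                startDate = as.Date("2020-01-01"),
                                napProb = 0.15, nMonths = 10L,
                                episodicRate = 1.5) {
  if (nDays < 14L)
    .err("need at least 14 days of records", "boldrel_invalid_parameter")
  grid <- seq(1, 5, by = 0.5)
  domains <- c("peer", "family", "school", "health", "finance")
  withr::with_seed(seed, {
    sl <- list(); k <- 0L
    for (j in seq_len(nParticipants)) {
      for (day in seq_len(nDays)) {
        base <- as.POSIXct(paste(startDate + (day - 1L), "00:00:00"),
                           tz = "UTC")
        onset <- base + 3600 * (23 + rnorm(1, 0, 0.75))
        dur <- pmax(4, rnorm(1, 8, 0.8))
        k <- k + 1L
        sl[[k]] <- data.frame(participant = j, date = startDate + (day - 1L),
                              onset = onset, offset = onset + 3600 * dur)
        if (runif(1) < napProb) {
          nap_on <- base + 3600 * (14 + rnorm(1, 0, 1))
          nap_dur <- pmax(0.25, rnorm(1, 0.75, 0.25))
          k <- k + 1L
          sl[[k]] <- data.frame(participant = j,
                                date = startDate + (day - 1L),
                                onset = nap_on,
                                offset = nap_on + 3600 * nap_dur)
        }
      }
    }
    sleep <- do.call(rbind, sl)
    st <- list(); k <- 0L
    for (j in seq_len(nParticipants)) {
      for (m in seq_len(nMonths)) {
        nEv <- rpois(1, episodicRate)
        if (nEv > 0) {
          k <- k + 1L
          st[[k]] <- data.frame(
            participant = j, month = m,
            severity = sample(grid, nEv, TRUE,
                              prob = rev(seq_along(grid))),
            domain = sample(domains, nEv, TRUE), type = "episodic")
        }
        k <- k + 1L
        st[[k]] <- data.frame(
          participant = j, month = m,
          severity = sample(grid, length(domains), TRUE,
                            prob = rev(seq_along(grid))),
          domain = domains, type = "chronic")
      }
    }
    stress <- do.call(rbind, st)
    row.names(sleep) <- NULL; row.names(stress) <- NULL
    list(sleep = sleep, stress = stress)
  })
}

#' Write / read a voxel panel as tidy CSV
#'
#' The CSV holds the long-format rows; a sidecar JSON (same path with
#' `.json` appended) records design sizes, the seed and any ground truth.
#'
#' @param panel a \linkS4class{VoxelPanel}.
#' @param path CSV path.
#' @return `writeVoxelPanel` returns the path invisibly; `readVoxelPanel`
#'   returns a \linkS4class{VoxelPanel}.
#' @export
writeVoxelPanel <- function(panel, path) {
  stopifnot(is(panel, "VoxelPanel"))
  utils::write.csv(panel@data, path, row.names = FALSE)
  meta <- c(list(nParticipants = panel@nParticipants,
                 nSessions = panel@nSessions, nVoxels = panel@nVoxels),
            panel@metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVoxelPanel
#' @export
readVoxelPanel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath,
                                                         simplifyVector = TRUE)
          else list(nParticipants = length(unique(d$participant)),
                    nSessions = max(d$session),
                    nVoxels = length(unique(d$voxel)))
  new("VoxelPanel", data = d,
      nParticipants = as.integer(meta$nParticipants),
      nSessions = as.integer(meta$nSessions),
      nVoxels = as.integer(meta$nVoxels),
      metadata = meta[setdiff(names(meta),
                              c("nParticipants", "nSessions", "nVoxels"))])
}
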