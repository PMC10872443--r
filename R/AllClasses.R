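#' @import methods
NULL

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "boldrel_error")))
}

#' Variance components of the voxel contrast model
#'
#' Ground-truth (or estimated) components of the three-level contrast model
#' \eqn{y_{ijk} = \beta_0 + \beta_i + \lambda_j + \pi_{jk} + \epsilon_{ijk}}:
#' a grand mean, fixed session effects, participant-mean variance
#' \eqn{\sigma^2_\lambda}, participant-session variance \eqn{\sigma^2_\pi},
#' and voxel error variance \eqn{\sigma^2_\epsilon}.
#'
#' @slot grandMean numeric(1), overall mean in contrast units.
#' @slot sessionEffects numeric vector of per-session fixed effects.
#' @slot sigmaLambda2 numeric(1), participant-mean variance.
#' @slot sigmaPi2 numeric(1), participant-session variance.
#' @slot sigmaEps2 numeric(1), voxel error variance.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(
    grandMean = "numeric",
    sessionEffects = "numeric",
    sigmaLambda2 = "numeric",
    sigmaPi2 = "numeric",
    sigmaEps2 = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  v <- c(object@sigmaLambda2, object@sigmaPi2, object@sigmaEps2)
  if (length(object@grandMean) != 1L || !is.finite(object@grandMean))
    return("grandMean must be a single finite number")
  if (length(v) != 3L || any(!is.finite(v)))
    return("variance components must be finite")
  if (any(v < 0))
    return("variance components must be non-negative")
  if (any(!is.finite(object@sessionEffects)))
    return("sessionEffects must be finite")
  TRUE
})

#' Long-format panel of voxel contrast values
#'
#' Rows are (participant, session, parcel, voxel, value). A complete crossing
#' is generated by default; the key must be unique.
#'
#' @slot data data.frame with columns participant, session, parcel, voxel,
#'   value.
#' @slot nParticipants integer(1).
#' @slot nSessions integer(1).
#' @slot nVoxels integer(1), voxels per parcel.
#' @slot metadata list; carries the generating seed and any injected
#'   ground-truth slopes.
#' @exportClass VoxelPanel
setClass("VoxelPanel",
  representation(
    data = "data.frame",
    nParticipants = "integer",
    nSessions = "integer",
    nVoxels = "integer",
    metadata = "list"
  )
)

setValidity("VoxelPanel", function(object) {
  d <- object@data
  need <- c("participant", "session", "parcel", "voxel", "value")
  if (!all(need %in% names(d)))
    return(paste("panel data must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(d[c("participant", "session", "parcel", "voxel")]))
    return("(participant, session, parcel, voxel) must be unique")
  if (any(d$session < 1L) || any(d$session > object@nSessions))
    return("session indices must lie in 1..nSessions")
  TRUE
})

#' Longitudinal predictor panel with within/between decomposition
#'
#' One value per participant-session, decomposed as
#' value = grand mean + between component + within component, exactly.
#'
#' @slot data data.frame with columns participant, session, x, xWithin,
#'   xBetween.
#' @slot grandMean numeric(1).
#' @slot metadata list (seed, generating SDs when simulated).
#' @exportClass PredictorPanel
setClass("PredictorPanel",
  representation(data = "data.frame", grandMean = "numeric", metadata = "list")
)

setValidity("PredictorPanel", function(object) {
  d <- object@data
  need <- c("participant", "session", "x", "xWithin", "xBetween")
  if (!all(need %in% names(d)))
    return(paste("predictor data must have columns", paste(need, collapse = ", ")))
  recon <- object@grandMean + d$xBetween + d$xWithin
  if (max(abs(recon - d$x)) > 1e-8)
    return("x must equal grandMean + xBetween + xWithin")
  sw <- tapply(d$xWithin, d$participant, sum)
  if (max(abs(sw)) > 1e-6 * (1 + max(abs(d$x))))
    return("within components must sum to zero per participant")
  TRUE
})

#' Study design and ground-truth configuration for simulation
#'
#' Defaults mirror a dense-sampling design: 30 participants scanned at 10
#' monthly sessions.
#'
#' @slot nParticipants integer(1).
#' @slot nSessions integer(1).
#' @slot parcels data.frame with columns parcel, nVoxels, anatomy.
#' @slot varComps VarianceComponents shared by parcels (per-parcel overrides
#'   via the generator).
#' @slot betweenSd,withinSd numeric(1), predictor SDs.
#' @slot betaWithin,betaBetween,betaTime numeric(1), injected effect sizes.
#' @slot seed integer(1), recorded in all outputs.
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    nParticipants = "integer",
    nSessions = "integer",
    parcels = "data.frame",
    varComps = "VarianceComponents",
    betweenSd = "numeric",
    withinSd = "numeric",
    betaWithin = "numeric",
    betaBetween = "numeric",
    betaTime = "numeric",
    seed = "integer"
  )
)

setValidity("StudyConfig", function(object) {
  if (object@nParticipants < 2L) return("need at least 2 participants")
  if (object@nSessions < 2L) return("need at least 2 sessions")
  if (nrow(object@parcels) < 1L || any(object@parcels$nVoxels < 1L))
    return("parcels must have at least one voxel each")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})

#' Pairwise test-retest ICC estimate
#'
#' Posterior summary of \eqn{ICC_{pair} = \sigma^2_\pi / (\sigma^2_\pi +
#' \sigma^2_\epsilon)} for one pair of adjacent sessions.
#'
#' @slot pair integer(2), the session indices.
#' @slot draws numeric, posterior draws of the ICC on [0, 1].
#' @slot median numeric(1), posterior median ICC.
#' @slot logitSd numeric(1), posterior SD of logit(ICC).
#' @slot backend character(1), "mcmc" or "reml".
#' @exportClass ICCEstimate
setClass("ICCEstimate",
  representation(pair = "integer", draws = "numeric", median = "numeric",
                 logitSd = "numeric", backend = "character")
)

setValidity("ICCEstimate", function(object) {
  if (length(object@pair) != 2L) return("pair must name two sessions")
  if (length(object@draws) && (min(object@draws) < 0 || max(object@draws) > 1))
    return("ICC draws must lie in [0, 1]")
  if (object@logitSd < 0) return("logitSd must be non-negative")
  TRUE
})

#' Meta-analytically pooled test-retest ICC
#'
#' Normal-normal hierarchical pooling of logit-scale pairwise ICC summaries;
#' reports the inverse-logit of the latent mean.
#'
#' @slot muDraws numeric, posterior draws of the latent mean (logit scale).
#' @slot sigmaDraws numeric, posterior draws of the between-pair SD.
#' @slot median numeric(1), pooled ICC (back-transformed posterior median).
#' @slot ci numeric(2), 95% credible interval on [0, 1].
#' @exportClass PooledICC
setClass("PooledICC",
  representation(muDraws = "numeric", sigmaDraws = "numeric",
                 median = "numeric", ci = "numeric")
)

setValidity("PooledICC", function(object) {
  if (object@median < 0 || object@median > 1) return("median must be in [0, 1]")
  if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
    return("ci must be an ordered pair")
  TRUE
})

#' Internal-consistency (within-session) ICC estimate for one parcel
#'
#' @slot parcel character(1) or coercible id.
#' @slot median numeric(1), posterior median of
#'   \eqn{ICC_{within} = \sigma^2_\pi / (\sigma^2_\lambda + \sigma^2_\pi +
#'   \sigma^2_\epsilon)}.
#' @slot ci numeric(2), 95% interval.
#' @slot components named numeric(3): sigmaLambda2, sigmaPi2, sigmaEps2
#'   point estimates.
#' @slot draws numeric, posterior draws of the ICC (empty for REML backend).
#' @slot backend character(1).
#' @exportClass ICCWithinEstimate
setClass("ICCWithinEstimate",
  representation(parcel = "character", median = "numeric", ci = "numeric",
                 components = "numeric", draws = "numeric",
                 backend = "character")
)

setValidity("ICCWithinEstimate", function(object) {
  if (object@median < 0 || object@median > 1)
    return("ICC_within must be in [0, 1]")
  if (any(object@components < 0)) return("variance components must be >= 0")
  if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
    return("ci must be ordered")
  TRUE
})

#' 3-D integer label volume
#'
#' @slot labels 3-D integer array; 0 is background.
#' @slot voxelSize numeric(3), mm per axis.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric")
)

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  if (any(object@labels < 0)) return("labels must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (mm)")
  TRUE
})

#' Set of voxel coordinates
#'
#' @slot coords integer matrix, one row per voxel, columns (i, j, k),
#'   0-based.
#' @slot label integer(1), source label.
#' @exportClass VoxelSet
setClass("VoxelSet",
  representation(coords = "matrix", label = "integer")
)

setValidity("VoxelSet", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (anyDuplicated(object@coords)) return("coordinates must be unique")
  if (any(object@coords < 0)) return("coordinates are 0-based and must be >= 0")
  TRUE
})

#' Residual smoothness estimate
#'
#' @slot perAxis numeric(3), FWHM in mm per axis.
#' @slot combined numeric(1), geometric mean of the finite axes.
#' @exportClass SmoothnessEstimate
setClass("SmoothnessEstimate",
  representation(perAxis = "numeric", combined = "numeric")
)

setValidity("SmoothnessEstimate", function(object) {
  if (any(object@perAxis < 0, na.rm = TRUE) || object@combined < 0)
    return("FWHM must be non-negative")
  TRUE
})

#' Beta regression of internal consistency on size/smoothness/anatomy
#'
#' @slot fit the underlying mgcv::gam fit (logit-link beta family).
#' @slot spec character(1), "constrained" or "unconstrained".
#' @slot records data.frame of consistency records used.
#' @slot phi numeric(1), beta precision parameter.
#' @slot splineDf integer(1), B-spline df for the unconstrained spec.
#' @exportClass BetaConsistencyModel
setClass("BetaConsistencyModel",
  representation(fit = "ANY", spec = "character", records = "data.frame",
                 phi = "numeric", splineDf = "integer")
)

setValidity("BetaConsistencyModel", function(object) {
  if (!object@spec %in% c("constrained", "unconstrained"))
    return("spec must be 'constrained' or 'unconstrained'")
  if (object@phi <= 0) return("precision phi must be positive")
  TRUE
})

#' ELPD model comparison
#'
#' @slot deltaElpd numeric(1), ELPD(unconstrained) - ELPD(constrained);
#'   positive favors the unconstrained model.
#' @slot se numeric(1), SE of the difference from pointwise contributions.
#' @slot decision character(1), "equivalent" (retain constrained) or
#'   "non-equivalent" (retain the better-predicting model).
#' @slot elpd named numeric(2), total ELPD per model.
#' @slot pointwise data.frame of per-observation ELPD contributions.
#' @slot method character(1), "exact" or "is".
#' @exportClass ELPDComparison
setClass("ELPDComparison",
  representation(deltaElpd = "numeric", se = "numeric", decision = "character",
                 elpd = "numeric", pointwise = "data.frame",
                 method = "character")
)

setValidity("ELPDComparison", function(object) {
  if (object@se < 0) return("se must be non-negative")
  if (!object@decision %in% c("equivalent", "non-equivalent"))
    return("decision must be 'equivalent' or 'non-equivalent'")
  TRUE
})

#' Longitudinal mixed-model fit with cluster-robust inference
#'
#' Random-intercept model fit by REML with CR2 cluster-robust standard
#' errors and Satterthwaite degrees of freedom per coefficient.
#'
#' @slot coefficients named numeric, fixed-effect estimates.
#' @slot vcovRobust matrix, CR2 sandwich covariance.
#' @slot df named numeric, Satterthwaite degrees of freedom.
#' @slot p named numeric, two-sided p-values.
#' @slot z named numeric, signed Z equivalents of the p-values.
#' @slot varComps named numeric(2): sigmaLambda2 (random intercept) and
#'   sigmaEps2 (residual).
#' @slot nObs integer(1).
#' @slot nClusters integer(1).
#' @exportClass LongitudinalFit
setClass("LongitudinalFit",
  representation(coefficients = "numeric", vcovRobust = "matrix",
                 df = "numeric", p = "numeric", z = "numeric",
                 varComps = "numeric", nObs = "integer",
                 nClusters = "integer")
)

setValidity("LongitudinalFit", function(object) {
  if (any(object@df <= 0)) return("Satterthwaite df must be positive")
  if (any(object@p <= 0 | object@p > 1)) return("p-values must be in (0, 1]")
  TRUE
})

#' Within-participant permutation set
#'
#' Row 0 (the first row) is the identity; each row restricted to a
#' participant's observations is a bijection of those observations.
#'
#' @slot indices integer matrix, one permutation per row.
#' @slot blocks list of integer vectors, observation indices per participant.
#' @exportClass PermutationSet
setClass("PermutationSet",
  representation(indices = "matrix", blocks = "list")
)

setValidity("PermutationSet", function(object) {
  idx <- object@indices
  if (!all(idx[1, ] == seq_len(ncol(idx)))) return("row 1 must be the identity")
  for (b in object@blocks) {
    if (!all(apply(idx[, b, drop = FALSE], 1L,
                   function(r) setequal(r, b))))
      return("each row must permute indices only within participant blocks")
  }
  TRUE
})

#' Parcel-level posterior of the within-person coefficient
#'
#' @slot parcel character(1).
#' @slot draws numeric, posterior draws of beta_within.
#' @slot median numeric(1).
#' @slot pSign numeric(1), fraction of draws sharing the median's sign.
#' @exportClass ParcelPosterior
setClass("ParcelPosterior",
  representation(parcel = "character", draws = "numeric", median = "numeric",
                 pSign = "numeric")
)

setValidity("ParcelPosterior", function(object) {
  if (object@pSign < 0.5 - 1e-12 || object@pSign > 1)
    return("sign-agreement probability must lie in [0.5, 1]")
  TRUE
})
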