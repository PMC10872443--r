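# Generics and accessors. Slots are never reached into by user code; these
# accessors are the supported surface.

#' Extract the tabular data of a panel object
#' @param x a VoxelPanel or PredictorPanel.
#' @return a data.frame.
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' @rdname panelData
#' @export
setMethod("panelData", "VoxelPanel", function(x) x@data)

#' @rdname panelData
#' @export
setMethod("panelData", "PredictorPanel", function(x) x@data)

#' Number of participants in a design or panel
#' @param x a VoxelPanel or StudyConfig.
#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))

#' @rdname nParticipants
#' @export
setMethod("nParticipants", "VoxelPanel", function(x) x@nParticipants)

#' @rdname nParticipants
#' @export
setMethod("nParticipants", "StudyConfig", function(x) x@nParticipants)

#' Number of sessions in a design or panel
#' @param x a VoxelPanel or StudyConfig.
#' @export
setGeneric("nSessions", function(x) standardGeneric("nSessions"))

#' @rdname nSessions
#' @export
setMethod("nSessions", "VoxelPanel", function(x) x@nSessions)

#' @rdname nSessions
#' @export
setMethod("nSessions", "StudyConfig", function(x) x@nSessions)

#' Posterior draws stored in an estimate object
#' @param x an ICCEstimate, ICCWithinEstimate, PooledICC or ParcelPosterior.
#' @return numeric vector of draws (may be empty for point backends).
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "ICCEstimate", function(x) x@draws)

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "ICCWithinEstimate", function(x) x@draws)

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "PooledICC", function(x) x@muDraws)

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "ParcelPosterior", function(x) x@draws)

#' Point summary (posterior median) of an estimate
#' @param x an estimate object.
#' @export
setGeneric("iccMedian", function(x) standardGeneric("iccMedian"))

#' @rdname iccMedian
#' @export
setMethod("iccMedian", "ICCEstimate", function(x) x@median)

#' @rdname iccMedian
#' @export
setMethod("iccMedian", "ICCWithinEstimate", function(x) x@median)

#' @rdname iccMedian
#' @export
setMethod("iccMedian", "PooledICC", function(x) x@median)

#' 95% interval of an estimate
#' @param x an ICCEstimate, ICCWithinEstimate or PooledICC.
#' @return numeric(2).
#' @export
setGeneric("iccInterval", function(x) standardGeneric("iccInterval"))

#' @rdname iccInterval
#' @export
setMethod("iccInterval", "ICCEstimate", function(x)
  unname(stats::quantile(x@draws, c(0.025, 0.975))))

#' @rdname iccInterval
#' @export
setMethod("iccInterval", "ICCWithinEstimate", function(x) x@ci)

#' @rdname iccInterval
#' @export
setMethod("iccInterval", "PooledICC", function(x) x@ci)

#' Estimated variance components
#' @param x an ICCWithinEstimate or LongitudinalFit.
#' @return named numeric vector.
#' @export
setGeneric("varianceEstimates", function(x) standardGeneric("varianceEstimates"))

#' @rdname varianceEstimates
#' @export
setMethod("varianceEstimates", "ICCWithinEstimate", function(x) x@components)

#' @rdname varianceEstimates
#' @export
setMethod("varianceEstimates", "LongitudinalFit", function(x) x@varComps)

#' Sign-agreement probability of a parcel posterior
#' @param x a ParcelPosterior.
#' @export
setGeneric("signProb", function(x) standardGeneric("signProb"))

#' @rdname signProb
#' @export
setMethod("signProb", "ParcelPosterior", function(x) x@pSign)

#' Voxel coordinates of a VoxelSet
#' @param x a VoxelSet.
#' @return integer matrix with columns i, j, k (0-based).
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' @rdname voxelCoords
#' @export
setMethod("voxelCoords", "VoxelSet", function(x) x@coords)

#' Label array of a LabelVolume
#' @param x a LabelVolume.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname labelArray
#' @export
setMethod("labelArray", "LabelVolume", function(x) x@labels)

#' Voxel size in mm
#' @param x a LabelVolume.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

#' Coefficient table of a longitudinal fit
#'
#' @param x a LongitudinalFit.
#' @return data.frame with estimate, robust SE, Satterthwaite df, p and
#'   signed Z per coefficient.
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname coefTable
#' @export
setMethod("coefTable", "LongitudinalFit", function(x) {
  data.frame(
    term = names(x@coefficients),
    estimate = unname(x@coefficients),
    se = sqrt(diag(x@vcovRobust)),
    df = unname(x@df),
    p = unname(x@p),
    z = unname(x@z),
    row.names = NULL
  )
})

#' @export
setMethod("coef", "LongitudinalFit", function(object, ...) object@coefficients)

#' @export
setMethod("vcov", "LongitudinalFit", function(object, ...) object@vcovRobust)

#' Smoothness summaries
#' @param x a SmoothnessEstimate.
#' @return numeric(1) combined FWHM in mm.
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' @rdname fwhm
#' @export
setMethod("fwhm", "SmoothnessEstimate", function(x) x@combined)

#' Per-axis FWHM
#' @param x a SmoothnessEstimate.
#' @export
setGeneric("fwhmPerAxis", function(x) standardGeneric("fwhmPerAxis"))

#' @rdname fwhmPerAxis
#' @export
setMethod("fwhmPerAxis", "SmoothnessEstimate", function(x) x@perAxis)

#' Permutation index matrix
#' @param x a PermutationSet.
#' @return integer matrix, one permutation per row; row 1 is the identity.
#' @export
setGeneric("permIndices", function(x) standardGeneric("permIndices"))

#' @rdname permIndices
#' @export
setMethod("permIndices", "PermutationSet", function(x) x@indices)

# show methods ---------------------------------------------------------------

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents: grand mean", format(object@grandMean),
      "|", length(object@sessionEffects), "session effects\n")
  cat(sprintf("  sigma_lambda2 = %.4g  sigma_pi2 = %.4g  sigma_eps2 = %.4g\n",
              object@sigmaLambda2, object@sigmaPi2, object@sigmaEps2))
})

setMethod("show", "VoxelPanel", function(object) {
  cat(sprintf(
    "VoxelPanel: %d rows (%d participants x %d sessions x %d parcel(s) x %d voxels)\n",
    nrow(object@data), object@nParticipants, object@nSessions,
    length(unique(object@data$parcel)), object@nVoxels))
})

setMethod("show", "PredictorPanel", function(object) {
  cat(sprintf("PredictorPanel: %d rows, %d participants, grand mean %.4g\n",
              nrow(object@data), length(unique(object@data$participant)),
              object@grandMean))
})

setMethod("show", "ICCEstimate", function(object) {
  cat(sprintf("ICCEstimate [sessions %d-%d, %s]: median %.3f (logit SD %.3f)\n",
              object@pair[1], object@pair[2], object@backend,
              object@median, object@logitSd))
})

setMethod("show", "PooledICC", function(object) {
  cat(sprintf("PooledICC: %.3f [%.3f, %.3f]\n",
              object@median, object@ci[1], object@ci[2]))
})

setMethod("show", "ICCWithinEstimate", function(object) {
  cat(sprintf("ICCWithinEstimate [parcel %s, %s]: %.3f [%.3f, %.3f]\n",
              object@parcel, object@backend, object@median,
              object@ci[1], object@ci[2]))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d label(s)\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], length(setdiff(unique(as.vector(object@labels)), 0L))))
})

setMethod("show", "VoxelSet", function(object) {
  cat(sprintf("VoxelSet: %d voxels from label %d\n",
              nrow(object@coords), object@label))
})

setMethod("show", "SmoothnessEstimate", function(object) {
  cat(sprintf("SmoothnessEstimate: combined FWHM %.3f mm (axes: %s)\n",
              object@combined,
              paste(format(object@perAxis, digits = 3), collapse = ", ")))
})

setMethod("show", "BetaConsistencyModel", function(object) {
  cat(sprintf("BetaConsistencyModel [%s]: %d records, phi = %.2f\n",
              object@spec, nrow(object@records), object@phi))
})

setMethod("show", "ELPDComparison", function(object) {
  cat(sprintf("ELPDComparison (%s): dELPD = %.2f (SE %.2f) -> %s\n",
              object@method, object@deltaElpd, object@se, object@decision))
})

setMethod("show", "LongitudinalFit", function(object) {
  cat(sprintf("LongitudinalFit: %d obs in %d clusters\n",
              object@nObs, object@nClusters))
  print(coefTable(object), digits = 4)
})

setMethod("show", "PermutationSet", function(object) {
  cat(sprintf("PermutationSet: %d permutations of %d observations in %d blocks (row 1 = identity)\n",
              nrow(object@indices), ncol(object@indices), length(object@blocks)))
})

setMethod("show", "ParcelPosterior", function(object) {
  cat(sprintf("ParcelPosterior [parcel %s]: median %.4g, P(sign agrees) = %.3f\n",
              object@parcel, object@median, object@pSign))
})
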