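# Volume-domain utilities: size-matched control spheres, parcel extraction,
# voxel subsampling, and residual smoothness (FWHM) estimation.

#' Radius of a sphere with a given voxel volume
#'
#' Inverts V = 4/3 pi r^3.
#'
#' @param targetVoxels volume in voxels (> 0).
#' @return radius in voxel units.
#' @export
sphereRadiusForVolume <- function(targetVoxels) {
  if (!is.finite(targetVoxels) || targetVoxels <= 0)
    .err("target volume must be positive", "boldrel_invalid_parameter")
  (3 * targetVoxels / (4 * pi))^(1 / 3)
}

#' Place a size-matched control sphere inside a labeled region
#'
#' Mirrors the size-matching procedure for control ROIs: pick a random center
#' voxel carrying `controlLabel`, grow a discrete sphere (voxel-center
#' distance <= r, starting from the volume-matched radius) until it contains
#' at least `targetVoxels` in-bounds voxels, and check containment. If any
#' sphere voxel falls outside the control region, a new center is drawn
#' (steps repeated). The final set is trimmed deterministically to the exact
#' count: voxels sorted by distance to the center, ties broken by
#' lexicographic (i, j, k).
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param controlLabel label of the control region.
#' @param targetVoxels requested sphere size in voxels.
#' @param seed integer seed for center selection.
#' @param maxTries maximum number of centers to try before failing.
#' @return a \linkS4class{VoxelSet} of exactly `targetVoxels` voxels.
#' @export
matchControlSphere <- function(labels, controlLabel, targetVoxels, seed,
                               maxTries = 1000L) {
  stopifnot(is(labels, "LabelVolume"))
  arr <- labels@labels
  shape <- dim(arr)
  inside <- which(arr == as.integer(controlLabel))
  if (length(inside) == 0L)
    .err("control label not present in volume", "boldrel_invalid_parameter")
  if (targetVoxels < 1L)
    .err("target size must be >= 1", "boldrel_invalid_parameter")
  if (length(inside) < targetVoxels)
    .err(sprintf(
      "cannot place a %d-voxel sphere in control label %d (only %d voxels)",
      targetVoxels, controlLabel, length(inside)),
      "boldrel_placement_failure")
  # 0-based coordinates of candidate centers
  coordOf <- function(lin) {
    lin0 <- lin - 1L
    cbind(lin0 %% shape[1],
          (lin0 %/% shape[1]) %% shape[2],
          lin0 %/% (shape[1] * shape[2]))
  }
  withr::with_seed(seed, {
    for (try in seq_len(maxTries)) {
      ctr <- coordOf(sample(inside, 1L))[1, ]
      r <- sphereRadiusForVolume(targetVoxels)
      repeat {
        rng <- lapply(1:3, function(a)
          seq.int(max(0L, floor(ctr[a] - r)),
                  min(shape[a] - 1L, ceiling(ctr[a] + r))))
        idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
        d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
          (idx[, 3] - ctr[3])^2
        keep <- d2 <= r^2 + 1e-9
        if (sum(keep) >= targetVoxels) {
          idx <- idx[keep, , drop = FALSE]
          d2 <- d2[keep]
          break
        }
        r <- r + 0.5
      }
      ord <- order(d2, idx[, 1], idx[, 2], idx[, 3])
      idx <- idx[ord[seq_len(targetVoxels)], , drop = FALSE]
      lin <- 1L + idx[, 1] + shape[1] * idx[, 2] +
        shape[1] * shape[2] * idx[, 3]
      if (all(arr[lin] == as.integer(controlLabel))) {
        dimnames(idx) <- list(NULL, c("i", "j", "k"))
        return(new("VoxelSet", coords = idx,
                   label = as.integer(controlLabel)))
      }
    }
  })
  .err(sprintf(
    "no contained %d-voxel sphere found in control label %d after %d tries",
    targetVoxels, controlLabel, maxTries), "boldrel_placement_failure")
}

#' Extract voxel values of a parcel from a contrast volume
#'
#' Values are returned in a stable lexicographic (i, j, k) voxel order,
#' which coincides with R's array storage order.
#'
#' @param contrastVolume 3-D numeric array, same shape as the labels.
#' @param labels a \linkS4class{LabelVolume}.
#' @param parcelId integer label of the parcel.
#' @return numeric vector, one value per parcel voxel.
#' @export
extractParcelValues <- function(contrastVolume, labels, parcelId) {
  stopifnot(is(labels, "LabelVolume"))
  if (!identical(dim(contrastVolume), dim(labels@labels)))
    .err("contrast volume and labels must share shape",
         "boldrel_invalid_parameter")
  sel <- labels@labels == as.integer(parcelId)
  if (!any(sel))
    .err(sprintf("parcel label %d absent from volume", parcelId),
         "boldrel_unknown_parcel")
  # column-major linear order == lexicographic by (k, j, i) ascending with i
  # fastest, i.e. sorted (i, j, k) tuples in array order: stable across calls
  as.numeric(contrastVolume[sel])
}

#' Subsample voxels from a parcel without replacement
#'
#' @param parcelVoxels a \linkS4class{VoxelSet}.
#' @param k number of voxels to draw (<= parcel size).
#' @param seed integer seed.
#' @return a \linkS4class{VoxelSet} of k voxels, order-normalized
#'   (lexicographic).
#' @export
subsampleVoxels <- function(parcelVoxels, k, seed) {
  stopifnot(is(parcelVoxels, "VoxelSet"))
  n <- nrow(parcelVoxels@coords)
  if (k > n)
    .err("cannot subsample more voxels than the parcel contains",
         "boldrel_invalid_parameter")
  pick <- withr::with_seed(seed, sample.int(n, k))
  co <- parcelVoxels@coords[pick, , drop = FALSE]
  co <- co[order(co[, 1], co[, 2], co[, 3]), , drop = FALSE]
  new("VoxelSet", coords = co, label = parcelVoxels@label)
}

#' Estimate residual smoothness (FWHM) from a value volume
#'
#' Classical Gaussian-autocorrelation estimator: per axis a,
#' rho_a = var(first differences along a) / (2 var(values)), and
#' FWHM_a = delta_a * sqrt(-2 log 2 / log(1 - rho_a)), clamped to 0 when
#' rho_a >= 1 (the independence limit). The combined estimate is the
#' geometric mean over axes with a finite estimate. For a 4-D stack the
#' per-axis ratios are pooled across the 4th dimension.
#'
#' @param residuals 3-D numeric array, or 4-D stack of such arrays.
#' @param mask optional \linkS4class{VoxelSet} or logical array restricting
#'   the estimation; differences are used only where both voxels are in the
#'   mask.
#' @param voxelSize numeric(3) mm per axis.
#' @return a \linkS4class{SmoothnessEstimate}.
#' @export
estimateFWHM <- function(residuals, mask = NULL, voxelSize = c(3, 3, 3)) {
  dims <- dim(residuals)
  if (length(dims) == 3L) {
    residuals <- array(residuals, dim = c(dims, 1L))
    dims <- dim(residuals)
  }
  if (length(dims) != 4L)
    .err("residuals must be a 3-D array or 4-D stack",
         "boldrel_invalid_parameter")
  shape <- dims[1:3]
  m <- if (is.null(mask)) {
    array(TRUE, dim = shape)
  } else if (is(mask, "VoxelSet")) {
    mm <- array(FALSE, dim = shape)
    co <- mask@coords
    mm[1L + co[, 1] + shape[1] * co[, 2] + shape[1] * shape[2] * co[, 3]] <- TRUE
    mm
  } else {
    array(as.logical(mask), dim = shape)
  }
  ssd <- numeric(3); nd <- numeric(3)
  sv <- 0; sv2 <- 0; nv <- 0
  for (t in seq_len(dims[4])) {
    vol <- residuals[, , , t]
    vals <- vol[m]
    sv <- sv + sum(vals); sv2 <- sv2 + sum(vals^2); nv <- nv + length(vals)
    for (a in 1:3) {
      n <- shape[a]
      if (n < 2L) next
      shift <- function(x) {
        # neighbor along axis a (offset +1)
        if (a == 1) x[-1, , , drop = FALSE]
        else if (a == 2) x[, -1, , drop = FALSE]
        else x[, , -1, drop = FALSE]
      }
      head_ <- function(x) {
        if (a == 1) x[-n, , , drop = FALSE]
        else if (a == 2) x[, -n, , drop = FALSE]
        else x[, , -n, drop = FALSE]
      }
      ok <- head_(m) & shift(m)
      dif <- (shift(vol) - head_(vol))[ok]
      ssd[a] <- ssd[a] + sum(dif^2)
      nd[a] <- nd[a] + length(dif)
    }
  }
  if (nv < 2L)
    .err("mask must cover at least 2 voxels", "boldrel_degenerate_input")
  varv <- (sv2 - sv^2 / nv) / (nv - 1)
  if (varv <= 0)
    .err("zero variance within mask", "boldrel_degenerate_input")
  perAxis <- rep(NA_real_, 3)
  for (a in 1:3) {
    if (nd[a] < 1) next
    rho <- (ssd[a] / nd[a]) / (2 * varv)
    perAxis[a] <- if (rho >= 1) 0 else
      voxelSize[a] * sqrt(-2 * log(2) / log(1 - rho))
  }
  fin <- perAxis[is.finite(perAxis)]
  combined <- if (length(fin)) exp(mean(log(pmax(fin, 1e-12)))) else 0
  if (combined < 1e-10) combined <- 0
  new("SmoothnessEstimate", perAxis = perAxis, combined = combined)
}

#' Smooth a 3-D volume with a separable Gaussian kernel
#'
#' Simulation utility used to study smoothness recovery: convolves with a
#' truncated (4 SD) sampled Gaussian per axis, zero-boundary handling with
#' kernel renormalization at the edges.
#'
#' @param volume 3-D numeric array.
#' @param fwhmVoxels kernel FWHM in voxel units; 0 returns the input.
#' @return smoothed array of the same shape.
#' @export
smoothVolume <- function(volume, fwhmVoxels) {
  if (fwhmVoxels <= 0) return(volume)
  sigma <- fwhmVoxels / sqrt(8 * log(2))
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  convAxis <- function(x, axis) {
    d <- dim(x)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    mat <- matrix(xp, nrow = dp[1])
    n <- dp[1]
    out <- matrix(0, nrow = n, ncol = ncol(mat))
    wt <- numeric(n)
    for (o in seq(-half, half)) {
      kv <- k[o + half + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kv * mat[src[ok], ]
      wt[ok] <- wt[ok] + kv
    }
    out <- out / wt
    aperm(array(out, dim = dp), order(perm))
  }
  for (a in 1:3) volume <- convAxis(volume, a)
  volume
}

#' Write / read a label volume as NIfTI-1
#'
#' Labels are stored as int16; voxel sizes go into the pixdim fields.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param path file path (.nii or .nii.gz).
#' @return `writeLabelVolume` returns the path invisibly; `readLabelVolume`
#'   returns a \linkS4class{LabelVolume}.
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  img <- RNifti::asNifti(labels@labels, internal = FALSE)
  RNifti::pixdim(img) <- labels@voxelSize
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  new("LabelVolume", labels = arr, voxelSize = as.numeric(vs))
}

#' Render one participant-session of a voxel panel into a 3-D volume
#'
#' Voxel ids map to parcel voxels in lexicographic (array) order, so
#' \code{extractParcelValues} round-trips the panel values exactly.
#'
#' @param panel a \linkS4class{VoxelPanel} for one parcel.
#' @param labels a \linkS4class{LabelVolume} whose parcel has exactly the
#'   panel's voxel count.
#' @param parcelId integer label of the parcel in `labels`.
#' @param participant,session which panel slice to render.
#' @param background fill value outside the parcel.
#' @return 3-D numeric array.
#' @export
panelToVolume <- function(panel, labels, parcelId, participant, session,
                          background = 0) {
  stopifnot(is(panel, "VoxelPanel"), is(labels, "LabelVolume"))
  d <- panel@data
  d <- d[d$participant == participant & d$session == session, ]
  d <- d[order(d$voxel), ]
  sel <- which(labels@labels == as.integer(parcelId))
  if (length(sel) != nrow(d))
    .err("parcel voxel count does not match the panel",
         "boldrel_invalid_parameter")
  vol <- array(background, dim = dim(labels@labels))
  vol[sel] <- d$value
  vol
}
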