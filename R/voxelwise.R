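# Mass-univariate engine for voxel-wise longitudinal models. The same
# random-intercept model, CR2 robust SE and Satterthwaite df as
# fitLongitudinalModel, profiled over a fixed grid of variance ratios
# theta = sigma_lambda2 / sigma_eps2 so that thousands of voxels sharing one
# design matrix can be fit with matrix algebra. All permutation maps reuse
# the engine, so observed and null statistics go through an identical
# pipeline.

#' Build a voxel-wise inference engine for a fixed design
#'
#' Precomputes, for every variance-ratio grid point, the GLS projections,
#' REML determinant terms, CR2 residual functionals and Satterthwaite df for
#' the coefficient of interest.
#'
#' @param X design matrix (n x p) with named columns.
#' @param cluster participant factor of length n.
#' @param coefName coefficient whose Z map is produced (default "xWithin").
#' @param thetaGrid grid of sigma_lambda2/sigma_eps2 ratios; the default
#'   spans intracluster correlations from 0 to 0.9 on a log scale.
#' @return an engine object (opaque list) for \code{fitVoxelwise}.
#' @export
voxelwiseEngine <- function(X, cluster, coefName = "xWithin",
                            thetaGrid = c(0, exp(seq(log(1e-3), log(9),
                                                     length.out = 20)))) {
  cluster <- factor(cluster)
  blocks <- split(seq_len(nrow(X)), cluster)
  n <- nrow(X); p <- ncol(X); J <- length(blocks)
  cIdx <- match(coefName, colnames(X))
  if (is.na(cIdx))
    .err("coefficient not found in design", "boldrel_invalid_parameter")
  nj <- lengths(blocks)
  # cluster indicator bookkeeping
  rowCl <- as.integer(cluster)
  Xbar <- rowsum(X, rowCl) / nj                    # J x p block means
  per <- vector("list", length(thetaGrid))
  for (g in seq_along(thetaGrid)) {
    th <- thetaGrid[g]
    alpha <- 1 - 1 / sqrt(1 + nj * th)
    w <- alpha * (2 - alpha) * nj                  # quasi-demeaning weights
    Xt <- X - (alpha[rowCl] * Xbar[rowCl, , drop = FALSE])
    XtX <- crossprod(Xt)
    XtXinv <- solve(XtX)
    cp <- .cr2Pieces(X, blocks, th)
    # z-vectors for the target coefficient, stacked into a J x n matrix
    G <- matrix(0, J, n)
    aMat <- matrix(0, p, J)
    bVec <- numeric(J)
    for (j in seq_len(J)) {
      pc <- cp$pieces[[j]]
      G[j, pc$block] <- pc$Z[, cIdx]
      aMat[, j] <- pc$XtZ[, cIdx]
      bVec[j] <- pc$ZtVZ[cIdx, cIdx]
    }
    Gm <- crossprod(aMat, cp$M %*% aMat)
    dj <- bVec - diag(Gm)
    df <- sum(dj)^2 /
      max(sum(dj^2) + sum(Gm^2) - sum(diag(Gm)^2), .Machine$double.xmin)
    per[[g]] <- list(theta = th, alphaW = w, XtXinv = XtXinv,
                     logdet = sum(log(1 + nj * th)) +
                       determinant(XtX)$modulus[1],
                     G = G, ZX = G %*% X, df = df)
  }
  list(X = X, rowCl = rowCl, nj = nj, Xbar = Xbar, blocks = blocks,
       n = n, p = p, J = J, cIdx = cIdx, thetaGrid = thetaGrid, per = per)
}

#' Fit the longitudinal model to many voxels at once
#'
#' For each column of Y: grid-profiled REML selection of the variance ratio,
#' GLS coefficients, CR2 robust SE and Satterthwaite df for the engine's
#' target coefficient, and the signed Z statistic.
#'
#' @param engine object from \code{voxelwiseEngine}.
#' @param Y numeric matrix, one column per voxel (rows aligned with the
#'   engine design).
#' @return list with vectors z, beta, se, df, theta (one entry per voxel).
#' @export
fitVoxelwise <- function(engine, Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != engine$n)
    .err("Y rows must match the design", "boldrel_invalid_parameter")
  V <- ncol(Y)
  n <- engine$n; p <- engine$p
  csY2 <- colSums(Y^2)
  XtY <- crossprod(engine$X, Y)                    # p x V
  YBar <- rowsum(Y, engine$rowCl) / engine$nj      # J x V
  YBar2 <- YBar^2
  nG <- length(engine$thetaGrid)
  best <- rep.int(1L, V)
  bestCrit <- rep.int(Inf, V)
  XtYt <- vector("list", nG)
  for (g in seq_len(nG)) {
    pg <- engine$per[[g]]
    XtYg <- XtY - crossprod(engine$Xbar, pg$alphaW * YBar)
    cs2g <- csY2 - as.numeric(crossprod(pg$alphaW, YBar2))
    rss <- pmax(cs2g - colSums(XtYg * (pg$XtXinv %*% XtYg)), 1e-300)
    crit <- (n - p) * log(rss) + pg$logdet
    upd <- crit < bestCrit
    bestCrit[upd] <- crit[upd]
    best[upd] <- g
    XtYt[[g]] <- XtYg
  }
  z <- beta <- se <- df <- theta <- numeric(V)
  for (g in unique(best)) {
    sel <- which(best == g)
    pg <- engine$per[[g]]
    B <- pg$XtXinv %*% XtYt[[g]][, sel, drop = FALSE]   # p x Vg
    # CR2 meat: per cluster j, t_j = z_j' e_j = (G Y)_j - (G X) B
    TZ <- pg$G %*% Y[, sel, drop = FALSE] - pg$ZX %*% B
    vc <- colSums(TZ^2)
    b <- B[engine$cIdx, ]
    s <- sqrt(vc)
    tt <- b / s
    tz <- .tToZ(tt, pg$df)
    z[sel] <- tz$z
    beta[sel] <- b
    se[sel] <- s
    df[sel] <- pg$df
    theta[sel] <- pg$theta
  }
  list(z = z, beta = beta, se = se, df = df, theta = theta)
}

#' Freedman-Lane permutation Z maps for a voxel matrix
#'
#' Residualizes every voxel on the nuisance design (time and the
#' between-person component, with the random intercept), reconstructs
#' permuted outcomes from fixed-effect fitted values plus
#' within-participant-permuted residuals, and refits the full model per
#' permutation through the identical engine.
#'
#' @param Y numeric matrix, one column per voxel.
#' @param pred a \linkS4class{PredictorPanel} aligned with the rows of Y via
#'   `participant`/`session`.
#' @param participant,session vectors aligned with the rows of Y.
#' @param perms a \linkS4class{PermutationSet} over the rows.
#' @param time optional time covariate; defaults to session - 1.
#' @param thetaGrid passed to \code{voxelwiseEngine}.
#' @return list with `observed` (Z vector from the identity row) and `null`
#'   (matrix, voxels x permutations, excluding the identity).
#' @export
freedmanLaneVoxelwise <- function(Y, pred, participant, session, perms,
                                  time = NULL,
                                  thetaGrid = c(0, exp(seq(log(1e-3), log(9),
                                                           length.out = 20)))) {
  stopifnot(is(perms, "PermutationSet"))
  Y <- as.matrix(Y)
  pd <- pred@data
  m <- match(paste(participant, session), paste(pd$participant, pd$session))
  if (anyNA(m))
    .err("rows and predictor keys do not align", "boldrel_alignment_error")
  if (is.null(time)) time <- session - 1
  Xfull <- cbind(`(Intercept)` = 1, time = time, xBetween = pd$xBetween[m],
                 xWithin = pd$xWithin[m])
  Xred <- Xfull[, 1:3, drop = FALSE]
  engRed <- voxelwiseEngine(Xred, participant, coefName = "xBetween",
                            thetaGrid = thetaGrid)
  engFull <- voxelwiseEngine(Xfull, participant, coefName = "xWithin",
                             thetaGrid = thetaGrid)
  # reduced-model GLS fitted values per voxel
  csY2 <- colSums(Y^2)
  XtY <- crossprod(Xred, Y)
  YBar <- rowsum(Y, engRed$rowCl) / engRed$nj
  nG <- length(thetaGrid)
  best <- rep.int(1L, ncol(Y)); bestCrit <- rep.int(Inf, ncol(Y))
  for (g in seq_len(nG)) {
    pg <- engRed$per[[g]]
    XtYg <- XtY - crossprod(engRed$Xbar, pg$alphaW * YBar)
    cs2g <- csY2 - as.numeric(crossprod(pg$alphaW, YBar^2))
    rss <- pmax(cs2g - colSums(XtYg * (pg$XtXinv %*% XtYg)), 1e-300)
    crit <- (engRed$n - engRed$p) * log(rss) + pg$logdet
    upd <- crit < bestCrit
    bestCrit[upd] <- crit[upd]; best[upd] <- g
  }
  Fitted <- matrix(0, nrow(Y), ncol(Y))
  for (g in unique(best)) {
    sel <- which(best == g)
    pg <- engRed$per[[g]]
    XtYg <- XtY[, sel, drop = FALSE] -
      crossprod(engRed$Xbar, pg$alphaW * YBar[, sel, drop = FALSE])
    B <- pg$XtXinv %*% XtYg
    Fitted[, sel] <- Xred %*% B
  }
  Resid <- Y - Fitted
  idx <- perms@indices
  observed <- fitVoxelwise(engFull, Y)$z
  nullZ <- matrix(0, ncol(Y), nrow(idx) - 1L)
  for (i in seq_len(nrow(idx) - 1L)) {
    Ystar <- Fitted + Resid[idx[i + 1L, ], , drop = FALSE]
    nullZ[, i] <- fitVoxelwise(engFull, Ystar)$z
  }
  list(observed = observed, null = nullZ)
}
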