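# Internal consistency as a function of parcel size, residual smoothness and
# anatomy class: logit-link beta regression, and model comparison by
# leave-one-out expected log pointwise predictive density (ELPD).

.clampUnit <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

#' Assemble and validate consistency records
#'
#' @param parcel parcel ids.
#' @param anatomy anatomy class per parcel: "cortex", "subcortex" or
#'   "control".
#' @param nVoxels parcel sizes in voxels (>= 1).
#' @param smoothness mean residual FWHM per parcel, mm.
#' @param iccWithin internal-consistency estimates; clamped into
#'   (1e-4, 1 - 1e-4).
#' @return data.frame with validated columns.
#' @export
consistencyRecords <- function(parcel, anatomy, nVoxels, smoothness,
                               iccWithin) {
  anatomy <- as.character(anatomy)
  if (!all(anatomy %in% c("cortex", "subcortex", "control")))
    .err("anatomy must be cortex, subcortex or control",
         "boldrel_invalid_input")
  if (any(nVoxels < 1))
    .err("parcel sizes must be >= 1", "boldrel_invalid_input")
  if (any(iccWithin <= 0 | iccWithin >= 1)) {
    if (any(iccWithin < 0 | iccWithin > 1))
      .err("iccWithin must lie in [0, 1] before clamping",
           "boldrel_invalid_input")
  }
  data.frame(parcel = as.character(parcel),
             anatomy = factor(anatomy,
                              levels = c("cortex", "subcortex", "control")),
             nVoxels = as.numeric(nVoxels),
             smoothness = as.numeric(smoothness),
             iccWithin = .clampUnit(iccWithin))
}

#' Simulate consistency records with known generating structure
#'
#' Emulates a region table (cortical parcels, subcortical regions,
#' size-matched controls) with anatomy-specific mean consistency on the
#' logit scale, optional linear size and smoothness effects, and
#' beta-distributed responses with precision phi.
#'
#' @param nCortex,nSubcortex,nControl region counts (defaults 400/14/24).
#' @param meansLogit named numeric(3): logit-scale anatomy intercepts.
#' @param sizeSlope,smoothSlope logit-scale slopes per voxel and per mm.
#' @param phi beta precision.
#' @param seed integer seed.
#' @return data.frame of consistency records.
#' @export
simulateConsistencyRecords <- function(nCortex = 400L, nSubcortex = 14L,
                                       nControl = 24L,
                                       meansLogit = c(cortex = stats::qlogis(0.44),
                                                      subcortex = stats::qlogis(0.36),
                                                      control = stats::qlogis(0.35)),
                                       sizeSlope = 0, smoothSlope = 0,
                                       phi = 50, seed = 1L) {
  n <- c(cortex = nCortex, subcortex = nSubcortex, control = nControl)
  withr::with_seed(seed, {
    anatomy <- rep(names(n), n)
    size <- round(c(stats::rlnorm(nCortex, log(300), 0.45),
                    stats::rlnorm(nSubcortex, log(250), 0.6),
                    stats::rlnorm(nControl, log(250), 0.6)))
    size <- pmax(size, 20)
    sm <- stats::rnorm(sum(n), 7.5, 1)
    eta <- meansLogit[anatomy] + sizeSlope * (size - 300) +
      smoothSlope * (sm - 7.5)
    mu <- stats::plogis(eta)
    icc <- stats::rbeta(sum(n), mu * phi, (1 - mu) * phi)
    consistencyRecords(sprintf("%s_%03d", anatomy, sequence(n)), anatomy,
                       size, sm, icc)
  })
}

.betaFormula <- function(spec, splineDf, records = NULL) {
  if (spec == "constrained") return(iccWithin ~ anatomy + nVoxels)
  # pin the spline boundary knots to the full-data range so that
  # leave-one-out refits never extrapolate an ill-conditioned basis
  # widened by a negligible epsilon because formula deparsing can lose the
  # last binary digits of an exact data bound
  bk <- function(x) {
    eps <- 1e-6 * max(max(x) - min(x), 1)
    sprintf("Boundary.knots = c(%.17g, %.17g)", min(x) - eps, max(x) + eps)
  }
  bkN <- if (is.null(records)) "" else paste0(", ", bk(records$nVoxels))
  bkS <- if (is.null(records)) "" else paste0(", ", bk(records$smoothness))
  stats::as.formula(sprintf(
    "iccWithin ~ anatomy + anatomy:splines::bs(nVoxels, df = %d%s) + anatomy:splines::bs(smoothness, df = %d%s)",
    splineDf, bkN, splineDf, bkS))
}

#' Fit a beta regression of internal consistency
#'
#' Logit-link beta regression (maximum likelihood via mgcv's beta family).
#' The constrained specification has anatomy intercepts and a single linear
#' parcel-size slope; the unconstrained specification gives each anatomy
#' class its own fixed-df B-spline terms in parcel size and smoothness.
#'
#' @param records data.frame from \code{consistencyRecords} (>= 30 rows,
#'   >= 2 anatomy classes).
#' @param spec "constrained" or "unconstrained".
#' @param splineDf B-spline degrees of freedom (unconstrained spec).
#' @return a \linkS4class{BetaConsistencyModel}.
#' @export
fitBetaConsistency <- function(records, spec = c("constrained",
                                                 "unconstrained"),
                               splineDf = 4L) {
  spec <- match.arg(spec)
  if (nrow(records) < 30L)
    .err("need at least 30 records", "boldrel_invalid_input")
  if (length(unique(records$anatomy)) < 2L)
    .err("need at least 2 anatomy classes", "boldrel_invalid_input")
  records$iccWithin <- .clampUnit(records$iccWithin)
  if (any(records$iccWithin <= 0 | records$iccWithin >= 1))
    .err("responses must lie in (0, 1) after clamping",
         "boldrel_invalid_input")
  records$anatomy <- droplevels(factor(records$anatomy))
  fit <- mgcv::gam(.betaFormula(spec, splineDf, records), data = records,
                   family = mgcv::betar(link = "logit"), method = "REML")
  if (any(!is.finite(stats::coef(fit))))
    .err(sprintf("beta regression did not converge (max |grad| %.3g)",
                 max(abs(fit$outer.info$grad %||% NA))),
         "boldrel_nonconvergence")
  phi <- fit$family$getTheta(TRUE)
  new("BetaConsistencyModel", fit = fit, spec = spec, records = records,
      phi = phi, splineDf = as.integer(splineDf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pointwise log predictive density of records under a fitted model
.betaLogDens <- function(fit, newdata, y, phi) {
  mu <- as.numeric(stats::predict(fit, newdata = newdata, type = "response"))
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

.elpdExact <- function(model) {
  rec <- model@records
  n <- nrow(rec)
  vapply(seq_len(n), function(i) {
    refit <- mgcv::gam(.betaFormula(model@spec, model@splineDf, rec),
                       data = rec[-i, ], family = mgcv::betar(link = "logit"),
                       method = "REML")
    .betaLogDens(refit, rec[i, ], rec$iccWithin[i],
                 refit$family$getTheta(TRUE))
  }, numeric(1))
}

.elpdIS <- function(model, nDraws = 2000L, seed = 1L) {
  fit <- model@fit
  rec <- model@records
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  Xl <- stats::predict(fit, newdata = rec, type = "lpmatrix")
  phi <- model@phi
  y <- rec$iccWithin
  withr::with_seed(seed, {
    L <- chol(V + diag(1e-12, ncol(V)))
    B <- matrix(stats::rnorm(nDraws * length(beta)), nDraws) %*% L
    B <- sweep(B, 2, beta, "+")
    eta <- Xl %*% t(B)                       # n x S
    mu <- stats::plogis(eta)
    ll <- stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
    # importance-sampling LOO per observation with weights 1/p(y_i|beta_s):
    # elpd_i = log S - logsumexp_s(-l_is)
    apply(ll, 1L, function(l) {
      m <- max(-l)
      log(length(l)) - (m + log(sum(exp(-l - m))))
    })
  })
}

#' Compare constrained and unconstrained consistency models by LOO ELPD
#'
#' Delta ELPD = ELPD(unconstrained) - ELPD(constrained); positive values
#' favor the unconstrained model. The SE comes from the pointwise ELPD
#' differences. Models are judged non-equivalent when |Delta| > 2 SE; in the
#' absence of evidence of non-equivalence the constrained model is retained.
#' ELPD is computed by exact leave-one-out refits when n <= 600 (and
#' `method = "auto"`), by importance sampling from the Laplace approximation
#' of the coefficient distribution otherwise.
#'
#' @param mConstrained,mUnconstrained \linkS4class{BetaConsistencyModel}
#'   objects fit to the identical records.
#' @param method "auto", "exact" or "is".
#' @param nDraws draws for the importance-sampling method.
#' @param seed integer seed for the importance-sampling method.
#' @return an \linkS4class{ELPDComparison}.
#' @export
compareModelsLoo <- function(mConstrained, mUnconstrained,
                             method = c("auto", "exact", "is"),
                             nDraws = 2000L, seed = 1L) {
  method <- match.arg(method)
  rc <- mConstrained@records; ru <- mUnconstrained@records
  if (nrow(rc) != nrow(ru) ||
      !isTRUE(all.equal(rc$iccWithin, ru$iccWithin)) ||
      !identical(as.character(rc$parcel), as.character(ru$parcel)))
    .err("models must be fit to identical records",
         "boldrel_invalid_comparison")
  if (mConstrained@spec != "constrained" ||
      mUnconstrained@spec != "unconstrained")
    .err("pass the constrained model first, the unconstrained second",
         "boldrel_invalid_comparison")
  if (method == "auto") method <- if (nrow(rc) <= 600L) "exact" else "is"
  ptC <- if (method == "exact") .elpdExact(mConstrained)
         else .elpdIS(mConstrained, nDraws, seed)
  ptU <- if (method == "exact") .elpdExact(mUnconstrained)
         else .elpdIS(mUnconstrained, nDraws, seed + 1L)
  dif <- ptU - ptC
  delta <- sum(dif)
  se <- sqrt(length(dif) * stats::var(dif))
  decision <- if (abs(delta) > 2 * se) "non-equivalent" else "equivalent"
  new("ELPDComparison", deltaElpd = delta, se = se, decision = decision,
      elpd = c(constrained = sum(ptC), unconstrained = sum(ptU)),
      pointwise = data.frame(constrained = ptC, unconstrained = ptU,
                             diff = dif),
      method = method)
}

#' Model-expected internal consistency at given covariates
#'
#' Inverse-logit of the linear predictor at the requested anatomy and parcel
#' size (and smoothness for the unconstrained model), with a 95% interval
#' from the link-scale standard error.
#'
#' @param model a \linkS4class{BetaConsistencyModel}.
#' @param anatomy anatomy class present in the fit.
#' @param nVoxels parcel size in voxels.
#' @param smoothness smoothness in mm (defaults to the median of the fitted
#'   records; only used by the unconstrained spec).
#' @return list with mean, lower, upper, and extrapolated (TRUE when
#'   nVoxels exceeds twice the observed size range).
#' @export
expectedConsistency <- function(model, anatomy, nVoxels, smoothness = NULL) {
  stopifnot(is(model, "BetaConsistencyModel"))
  if (!anatomy %in% levels(model@records$anatomy))
    .err("anatomy class not present in the fit", "boldrel_invalid_parameter")
  if (is.null(smoothness))
    smoothness <- stats::median(model@records$smoothness)
  nd <- data.frame(anatomy = factor(anatomy,
                                    levels = levels(model@records$anatomy)),
                   nVoxels = nVoxels, smoothness = smoothness)
  pr <- stats::predict(model@fit, newdata = nd, type = "link", se.fit = TRUE)
  extrapolated <- nVoxels > 2 * max(model@records$nVoxels) ||
    nVoxels < 0.5 * min(model@records$nVoxels)
  if (extrapolated)
    warning("requested size lies beyond twice the observed range")
  list(mean = stats::plogis(pr$fit),
       lower = stats::plogis(pr$fit - 1.96 * pr$se.fit),
       upper = stats::plogis(pr$fit + 1.96 * pr$se.fit),
       extrapolated = extrapolated)
}
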