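# End-to-end orchestration: simulate -> reliability ICCs -> consistency
# model -> longitudinal inference -> power, with provenance and reproducible
# seeds.

#' Run report
#'
#' @slot sections named list of per-stage results (tables and estimate
#'   objects); disabled stages carry the string "skipped".
#' @slot provenance list: config echo, seed, backend, package version,
#'   timestamps.
#' @exportClass RunReport
setClass("RunReport",
  representation(sections = "list", provenance = "list"))

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed", object@provenance$seed, "):\n")
  for (nm in names(object@sections)) {
    s <- object@sections[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (identical(s, "skipped")) "skipped" else "done"))
  }
})

#' Report sections
#' @param x a RunReport.
#' @return named list of stage outputs.
#' @export
setGeneric("reportSections", function(x) standardGeneric("reportSections"))

#' @rdname reportSections
#' @export
setMethod("reportSections", "RunReport", function(x) x@sections)

.stageOrder <- c("simulate", "icc_retest", "icc_within", "consistency",
                 "longitudinal", "cluster", "power")
.stageDeps <- list(
  simulate = character(0),
  icc_retest = "simulate", icc_within = "simulate",
  consistency = "icc_within", longitudinal = "simulate",
  cluster = "simulate", power = character(0))

#' Run the full analysis pipeline on simulated data
#'
#' Executes the enabled stages in dependency order: data simulation,
#' pairwise test-retest ICC with meta-analytic pooling, per-parcel internal
#' consistency, the beta consistency model with LOO comparison, parcel-level
#' longitudinal inference with sign-error selection, a voxel-wise
#' Freedman-Lane cluster-FWE demonstration, and the design power simulation.
#' Identical config and seed reproduce identical tables (REML backend).
#'
#' @param config a \linkS4class{StudyConfig}.
#' @param stages character vector of stages to run (subset of simulate,
#'   icc_retest, icc_within, consistency, longitudinal, cluster, power).
#' @param backend "reml" (deterministic, fast) or "mcmc" for the Bayesian
#'   estimators.
#' @param outDir optional directory: stage tables are written as TSV with a
#'   provenance header comment, plus a JSON run summary.
#' @param nPerm permutations for the cluster stage.
#' @param alpha familywise level for the cluster stage.
#' @param errorBudget sign-error budget for parcel selection.
#' @param nSimPower replicates for the power stage.
#' @param nRetestParcels number of parcels run through the pairwise-ICC
#'   stage (it is the most expensive reliability stage).
#' @param verbose log stage progress to stderr.
#' @return a \linkS4class{RunReport}.
#' @export
runPipeline <- function(config = studyConfig(), stages = .stageOrder,
                        backend = c("reml", "mcmc"), outDir = NULL,
                        nPerm = 200L, alpha = 0.05, errorBudget = 0.05,
                        nSimPower = 200L, nRetestParcels = 3L,
                        verbose = TRUE) {
  backend <- match.arg(backend)
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  bad <- setdiff(stages, .stageOrder)
  if (length(bad))
    .err(paste("unknown stage(s):", paste(bad, collapse = ", ")),
         "boldrel_invalid_parameter")
  say <- function(...) if (verbose) message(sprintf(...))
  sections <- stats::setNames(
    rep(list("skipped"), length(.stageOrder)), .stageOrder)
  ranStage <- function(nm) !identical(sections[[nm]], "skipped")
  needs <- function(nm) {
    dep <- .stageDeps[[nm]]
    miss <- dep[!vapply(dep, ranStage, logical(1))]
    if (length(miss))
      .err(sprintf("stage '%s' requires skipped stage(s): %s", nm,
                   paste(miss, collapse = ", ")), "boldrel_stage_failure")
  }
  runStage <- function(nm, fn) {
    if (!nm %in% stages) return(invisible())
    needs(nm)
    say("stage %s ...", nm)
    sections[[nm]] <<- tryCatch(fn(), error = function(e) {
      .err(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           "boldrel_stage_failure")
    })
  }
  seed <- config@seed
  panels <- NULL; pred <- NULL

  runStage("simulate", function() {
    pred <<- generatePredictorPanel(config@betweenSd, config@withinSd,
                                    config@nParticipants, config@nSessions,
                                    seed = seed)
    panels <<- lapply(seq_len(nrow(config@parcels)), function(i) {
      p <- generateParcelVoxels(config@varComps, config@nParticipants,
                                config@nSessions,
                                config@parcels$nVoxels[i],
                                seed = seed + i,
                                parcel = config@parcels$parcel[i])
      injectWithinEffect(p, pred, config@betaWithin, config@betaBetween,
                         config@betaTime)
    })
    list(nParcels = length(panels),
         predictorICC = iccOneway(pred),
         parcels = config@parcels)
  })

  runStage("icc_retest", function() {
    sel <- seq_len(min(nRetestParcels, length(panels)))
    perParcel <- lapply(sel, function(i) {
      ests <- adjacentPairICC(panels[[i]],
                              backend = if (backend == "mcmc") "mcmc"
                                        else "reml",
                              seed = seed + 100L + i)
      pooled <- poolICCMeta(ests, seed = seed + 200L + i)
      list(parcel = config@parcels$parcel[i], pairs = ests, pooled = pooled)
    })
    tab <- do.call(rbind, lapply(perParcel, function(x)
      data.frame(parcel = x$parcel, pooledICC = iccMedian(x$pooled),
                 lower = iccInterval(x$pooled)[1],
                 upper = iccInterval(x$pooled)[2])))
    list(table = tab, detail = perParcel)
  })

  runStage("icc_within", function() {
    ests <- lapply(panels, fitInternalConsistency,
                   backend = if (backend == "mcmc") "mcmc" else "reml",
                   seed = seed + 300L)
    tab <- do.call(rbind, lapply(ests, function(e) {
      comp <- varianceEstimates(e)
      data.frame(parcel = e@parcel, iccWithin = iccMedian(e),
                 lower = iccInterval(e)[1], upper = iccInterval(e)[2],
                 alphaAll = multilevelAlpha(comp[1], comp[2], comp[3],
                                            config@parcels$nVoxels[1]),
                 alpha15 = multilevelAlpha(comp[1], comp[2], comp[3], 15))
    }))
    rownames(tab) <- NULL
    list(table = tab, detail = ests)
  })

  runStage("consistency", function() {
    tab <- sections$icc_within$table
    smoothness <- withr::with_seed(seed + 400L,
                                   stats::rnorm(nrow(tab), 7.5, 1))
    rec <- consistencyRecords(tab$parcel, config@parcels$anatomy,
                              config@parcels$nVoxels, smoothness,
                              tab$iccWithin)
    mC <- fitBetaConsistency(rec, "constrained")
    mU <- fitBetaConsistency(rec, "unconstrained")
    cmp <- compareModelsLoo(mC, mU, seed = seed + 401L)
    exp312 <- lapply(levels(rec$anatomy)[table(rec$anatomy) > 0],
                     function(a) expectedConsistency(
                       mC, a, stats::median(rec$nVoxels)))
    list(records = rec, comparison = cmp,
         expected = stats::setNames(
           exp312, levels(rec$anatomy)[table(rec$anatomy) > 0]))
  })

  runStage("longitudinal", function() {
    posts <- lapply(panels, fitParcelPosterior, pred = pred,
                    backend = if (backend == "mcmc") "mcmc" else "approx",
                    seed = seed + 500L)
    selTab <- signErrorSelect(posts, errorBudget = errorBudget)
    list(posteriors = posts, selection = selTab)
  })

  runStage("cluster", function() {
    # one-parcel voxel-wise demonstration on a compact block mask
    panel <- panels[[1]]
    d <- panel@data
    wide <- stats::reshape(
      d[, c("participant", "session", "voxel", "value")],
      timevar = "voxel", idvar = c("participant", "session"),
      direction = "wide")
    Y <- as.matrix(wide[, -(1:2)])
    blocks <- split(seq_len(nrow(wide)), wide$participant)
    perms <- makeWithinPermutations(blocks, nPerm, seed = seed + 600L)
    fl <- freedmanLaneVoxelwise(Y, pred, wide$participant, wide$session,
                                perms)
    v <- ncol(Y)
    side <- ceiling(v^(1 / 3))
    shape <- c(side, side, max(1L, ceiling(v / side^2)) + 1L)
    mask <- array(FALSE, dim = shape)
    mask[seq_len(v)] <- TRUE
    obs <- array(0, dim = shape); obs[seq_len(v)] <- fl$observed
    tabl <- clusterFweThreshold(obs, fl$null, mask = mask, alpha = alpha)
    list(clusters = tabl, nPerm = nPerm)
  })

  runStage("power", function() {
    estimatePower(config@nParticipants, config@nSessions,
                  betaWithinStd = config@betaWithin, nSim = nSimPower,
                  seed = seed + 700L)
  })

  prov <- list(seed = seed, backend = backend,
               packageVersion = as.character(utils::packageVersion(
                 "boldReliability")),
               config = list(nParticipants = config@nParticipants,
                             nSessions = config@nSessions,
                             nParcels = nrow(config@parcels),
                             betaWithin = config@betaWithin,
                             betaBetween = config@betaBetween,
                             betaTime = config@betaTime),
               time = format(Sys.time(), tz = "UTC"))
  report <- new("RunReport", sections = sections, provenance = prov)
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# boldReliability %s | seed %d | backend %s",
                 report@provenance$packageVersion, report@provenance$seed,
                 report@provenance$backend)
  writeTsv <- function(df, name) {
    path <- file.path(outDir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  s <- report@sections
  if (!identical(s$icc_retest, "skipped")) writeTsv(s$icc_retest$table,
                                                    "icc_retest.tsv")
  if (!identical(s$icc_within, "skipped")) writeTsv(s$icc_within$table,
                                                    "icc_within.tsv")
  if (!identical(s$longitudinal, "skipped"))
    writeTsv(s$longitudinal$selection, "parcel_selection.tsv")
  if (!identical(s$cluster, "skipped")) writeTsv(s$cluster$clusters,
                                                 "clusters.tsv")
  jsonlite::write_json(
    c(report@provenance,
      list(power = if (identical(s$power, "skipped")) NULL else s$power)),
    file.path(outDir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Validate pipeline input files
#'
#' Schema checks for tidy CSV/TSV inputs; reports issues without raising.
#'
#' @param paths named list with any of: voxelPanel, predictorPanel, sleep,
#'   stress (CSV paths), labels (NIfTI path).
#' @return data.frame with columns file, row, column, reason; zero rows when
#'   everything is well formed.
#' @export
validateInputs <- function(paths) {
  issues <- list()
  add <- function(file, row, column, reason)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, column = column, reason = reason)
  readTab <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  vp <- NULL
  if (!is.null(paths$voxelPanel)) {
    vp <- readTab(paths$voxelPanel)
    need <- c("participant", "session", "parcel", "voxel", "value")
    for (cn in setdiff(need, names(vp)))
      add(paths$voxelPanel, NA, cn, "missing column")
    if (all(need %in% names(vp))) {
      dup <- which(duplicated(vp[c("participant", "session", "parcel",
                                   "voxel")]))
      for (r in utils::head(dup, 10))
        add(paths$voxelPanel, r, "key", "duplicate (participant, session, parcel, voxel)")
      bad <- which(!is.finite(vp$value))
      for (r in utils::head(bad, 10))
        add(paths$voxelPanel, r, "value", "non-finite value")
    }
  }
  if (!is.null(paths$predictorPanel)) {
    pp <- readTab(paths$predictorPanel)
    need <- c("participant", "session", "x")
    for (cn in setdiff(need, names(pp)))
      add(paths$predictorPanel, NA, cn, "missing column")
    if (!is.null(vp) && all(need %in% names(pp)) &&
        all(c("participant", "session") %in% names(vp))) {
      miss <- !paste(vp$participant, vp$session) %in%
        paste(pp$participant, pp$session)
      if (any(miss))
        add(paths$predictorPanel, which(miss)[1], "key",
            "voxel panel keys missing from predictor panel")
    }
  }
  if (!is.null(paths$stress)) {
    st <- readTab(paths$stress)
    if (!"severity" %in% names(st)) {
      add(paths$stress, NA, "severity", "missing column")
    } else {
      off <- which(!st$severity %in% .severityGrid)
      for (r in utils::head(off, 10))
        add(paths$stress, r, "severity",
            sprintf("severity %s off the 1-5 half-point grid",
                    st$severity[r]))
    }
  }
  if (!is.null(paths$sleep)) {
    sl <- readTab(paths$sleep)
    need <- c("participant", "onset", "offset")
    for (cn in setdiff(need, names(sl)))
      add(paths$sleep, NA, cn, "missing column")
    if (all(need %in% names(sl))) {
      bad <- which(as.POSIXct(sl$offset, tz = "UTC") <=
                     as.POSIXct(sl$onset, tz = "UTC"))
      for (r in utils::head(bad, 10))
        add(paths$sleep, r, "offset", "offset not after onset")
    }
  }
  if (!is.null(paths$labels)) {
    lv <- tryCatch(readLabelVolume(paths$labels), error = function(e) e)
    if (inherits(lv, "error"))
      add(paths$labels, NA, NA, conditionMessage(lv))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(0), row = integer(0),
                  column = character(0), reason = character(0))
}
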