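#' Reference pipeline configuration
#'
#' The "redpulp2020" profile carries the printed processing defaults of
#' the red pulp reconstruction workflow: iso-values 100 (CD34, CD20) and
#' 160 (SMA, CD271); repair octree depths 9 (CD34), 7 (SMA), 8 (CD271,
#' CD20); small-component removal at 2 percent of the main diagonal for
#' CD34, 10 percent for SMA, 5 percent for CD271 (CD20 exempt); quadric
#' decimation to 10 percent (CD34) and 50 percent (CD271, CD20); flow
#' interpolation factor 7 for CD34/SMA (7 to 1 um) and CD271 (14 to 2 um);
#' CD20 left at its native 14 um spacing; registration on the sigma-6
#' blurred blue channel.  The desk scale pairs it with the default phantom
#' (256 x 256 px, 48 sections).
#'
#' @param seed master seed; fans out to per-stage seeds by fixed derivation.
#' @param profile configuration profile name.
#' @param phantom optional \linkS4class{PhantomSpec} override.
#' @return a \linkS4class{PipelineConfig}.
#' @export
defaultPipelineConfig <- function(seed = 1L, profile = "redpulp2020",
                                  phantom = NULL) {
  if (!identical(profile, "redpulp2020"))
    stop("unknown profile: ", profile)
  if (is.null(phantom)) phantom <- phantomSpec(seed = as.integer(seed))
  new("PipelineConfig",
      geometry = list(pixelSizeUm = phantom@pixelSizeUm,
                      thicknessUm = phantom@sectionThicknessUm,
                      cropPx = 224L),
      channels = list(
        CD34 = list(iso = 100, interpFactor = 7L, interpMethod = "flow",
                    octreeDepth = 9L, componentFraction = 0.02,
                    decimateFraction = 0.10, smoothIterations = 10L),
        SMA = list(iso = 160, interpFactor = 7L, interpMethod = "flow",
                   octreeDepth = 7L, componentFraction = 0.10,
                   decimateFraction = NA_real_, smoothIterations = 10L),
        CD271 = list(iso = 160, interpFactor = 7L, interpMethod = "flow",
                     octreeDepth = 8L, componentFraction = 0.05,
                     decimateFraction = 0.50, smoothIterations = 10L),
        CD20 = list(iso = 100, interpFactor = 1L, interpMethod = "nn",
                    octreeDepth = 8L, componentFraction = NA_real_,
                    decimateFraction = 0.50, smoothIterations = 0L)),
      stain = stainModel(),
      registration = list(sigma = 6, k = 2L, maxFeatures = 400L,
                          normalize = FALSE),
      phantom = phantom,
      recovery = list(toleranceUm = 4, paintThresholdUm = 8.75,
                      pruneMaxDistanceUm = 12, minDiameterUm = 10),
      seed = as.integer(seed))
}

#' Validate a pipeline configuration
#'
#' Checks channel keys and required per-channel fields before any stage
#' runs; unknown keys fail fast.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return invisibly TRUE; errors describe the offending entry.
#' @export
validatePipelineConfig <- function(config) {
  known <- c("CD34", "SMA", "CD271", "CD20")
  extra <- setdiff(names(config@channels), known)
  if (length(extra) > 0)
    stop("unknown channel key(s) in config: ", paste(extra, collapse = ", "))
  need <- c("iso", "interpFactor", "interpMethod", "octreeDepth",
            "componentFraction", "decimateFraction", "smoothIterations")
  for (ch in names(config@channels)) {
    missing <- setdiff(need, names(config@channels[[ch]]))
    if (length(missing) > 0)
      stop("channel ", ch, " misses field(s): ", paste(missing, collapse = ", "))
    iso <- config@channels[[ch]]$iso
    if (iso <= 0 || iso >= 255) stop("channel ", ch, ": iso out of (0,255)")
  }
  validObject(config@phantom)
  validObject(config@stain)
  invisible(TRUE)
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full phantom-to-score reconstruction pipeline
#'
#' Executes phantom generation, section rendering, artifacts, registration
#' on the blurred blue channel, alignment + central crop, unmixing,
#' per-channel volume interpolation and filtering, iso-surfacing, watertight
#' repair, smoothing, component filtering, decimation, SMA-proximity
#' painting of the CD34 mesh, B-cell pruning, and ground-truth scoring.
#' Stages are deterministic for a fixed master seed.  With \code{outdir}
#' set, per-stage results are cached as RDS files keyed by the config hash,
#' making re-runs resumable.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param outdir optional cache/output directory.
#' @param verbose print stage progress.
#' @return a \linkS4class{RunManifest}; its \code{outputs} carry the ground
#'   truth, alignment, meshes, paint, prune result and recovery report.
#' @export
runPipeline <- function(config, outdir = NULL, verbose = FALSE) {
  validatePipelineConfig(config)
  hash <- configHash(config)
  timings <- numeric(0)
  warningsLog <- character(0)
  cacheFile <- function(stage) {
    if (is.null(outdir)) NULL
    else file.path(outdir, paste0("stage_", stage, "_", hash, ".rds"))
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  stage <- function(name, fn) {
    cf <- cacheFile(name)
    if (!is.null(cf) && file.exists(cf)) {
      if (verbose) message("stage ", name, ": cached")
      timings[name] <<- 0
      return(readRDS(cf))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(err)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
             call. = FALSE)),
      warning = function(w) {
        warningsLog <<- c(warningsLog, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[name] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("stage %s: %.1f s", name, timings[name]))
    if (!is.null(cf)) saveRDS(res, cf)
    res
  }

  spec <- config@phantom
  spec@seed <- derive_seed(config@seed, "phantom")
  stain <- config@stain

  gt <- stage("phantom", function() buildPhantom(spec))
  stack <- stage("render", function() renderSections(gt, stain, spec))
  stack <- stage("artifacts", function()
    applySectionArtifacts(stack, spec@lostSectionIndices))

  if (isTRUE(config@registration$normalize)) {
    stack <- stage("normalize", function() {
      ref <- labStats(stack@sections[[(length(stack@sections) + 1) %/% 2]])
      out <- stack
      out@sections <- lapply(stack@sections, reinhardNormalize, referenceStats = ref)
      out
    })
  }

  alignment <- stage("register", function() {
    chans <- lapply(stack@sections, extractRegistrationChannel, stain = stain,
                    sigma = config@registration$sigma)
    registerStack(chans, k = config@registration$k,
                  maxFeatures = config@registration$maxFeatures,
                  seed = derive_seed(config@seed, "register"))
  })
  registered <- stage("align", function()
    applyAlignment(stack, alignment, cropPx = config@geometry$cropPx))

  rawVols <- stage("unmix", function() {
    vols <- unmixStack(registered, stain)
    off <- registered@meta$cropOffsetPx
    if (!is.null(off)) {
      px <- config@geometry$pixelSizeUm
      vols <- lapply(vols, function(v) {
        v@originUm[1:2] <- v@originUm[1:2] + off * px
        v
      })
    }
    vols
  })

  vols <- stage("volumes", function() {
    out <- list()
    for (ch in names(config@channels)) {
      if (is.null(rawVols[[ch]])) next
      cc <- config@channels[[ch]]
      v <- rawVols[[ch]]
      v <- if (cc$interpMethod == "flow") flowInterpolateZ(v, cc$interpFactor)
           else nnResizeZ(v, cc$interpFactor)
      out[[ch]] <- filterChannelVolume(v, ch)
    }
    out
  })

  rawVols <- NULL  # the interpolated volumes supersede the raw stacks

  meshes <- stage("mesh", function() {
    out <- list()
    for (ch in names(vols)) {
      cc <- config@channels[[ch]]
      m <- isosurface(vols[[ch]], cc$iso)
      if (nrow(m@faces) > 0) m <- repairWatertight(m, cc$octreeDepth)
      out[[ch]] <- m
    }
    out
  })
  vols <- NULL  # meshes carry the geometry from here on

  meshes <- stage("ops", function() {
    out <- meshes
    for (ch in names(out)) {
      cc <- config@channels[[ch]]
      m <- out[[ch]]
      if (nrow(m@faces) == 0) next
      if (cc$smoothIterations > 0) m <- taubinSmooth(m, cc$smoothIterations)
      if (!is.na(cc$componentFraction))
        m <- removeSmallComponents(m, cc$componentFraction)
      if (!is.na(cc$decimateFraction) && cc$decimateFraction < 1)
        m <- quadricDecimate(m, cc$decimateFraction)
      out[[ch]] <- m
    }
    out
  })

  paint <- stage("paint", function() {
    if (is.null(meshes$CD34) || is.null(meshes$SMA) ||
        nrow(meshes$CD34@faces) == 0 || nrow(meshes$SMA@faces) == 0) return(NULL)
    paintByProximity(meshes$CD34, meshes$SMA, config@recovery$paintThresholdUm)
  })

  pruned <- stage("prune", function() {
    if (is.null(meshes$CD20) || nrow(meshes$CD20@faces) == 0) return(NULL)
    pruneCellComponents(meshes$CD20, meshes["CD271"],
                        maxDistanceUm = config@recovery$pruneMaxDistanceUm,
                        minDiameterUm = config@recovery$minDiameterUm)
  })

  report <- stage("score", function() {
    ri <- alignment@referenceIndex
    jit <- stack@jitter
    frame <- NULL
    if (nrow(jit) >= ri) {
      px <- config@geometry$pixelSizeUm
      W <- dim(stack@sections[[1]]@pixels)[2]
      H <- dim(stack@sections[[1]]@pixels)[1]
      frame <- list(theta = jit$theta[ri],
                    tUm = c(jit$tx[ri], jit$ty[ri]) * px,
                    centerUm = c(W / 2 * px, H / 2 * px))
    }
    recoverTopology(meshes, gt, toleranceUm = config@recovery$toleranceUm,
                    frame = frame)
  })

  new("RunManifest", configHash = hash, seed = config@seed,
      timings = timings,
      outputs = list(groundTruth = gt, alignment = alignment,
                     meshes = meshes, paint = paint, prunedBcells = pruned,
                     report = report),
      warnings = warningsLog)
}

#' Physical volume of a region of interest
#'
#' (crop * pixel size)^2 * sections * thickness, reported in cubic
#' millimeters rounded to two decimals, matching the ROI bookkeeping of the
#' source workflow (e.g. 83 sections of 7 um over a 2000 px / 0.5 um crop
#' give 0.58 cubic mm).
#'
#' @param nSections number of sections reconstructed.
#' @param thicknessUm section thickness in micrometers.
#' @param cropPx processed square crop in pixels.
#' @param pixelSizeUm pixel size in micrometers.
#' @return ROI volume in cubic millimeters (2 decimals).
#' @export
computeRoiVolume <- function(nSections, thicknessUm = 7, cropPx = 2000,
                             pixelSizeUm = 0.5) {
  stopifnot(nSections >= 0, thicknessUm > 0, cropPx > 0, pixelSizeUm > 0)
  um3 <- (cropPx * pixelSizeUm)^2 * nSections * thicknessUm
  round(um3 / 1e9, 2)
}

#' Percentage of a cut series cropped away
#'
#' @param totalSections sections cut.
#' @param usedSections sections kept for reconstruction.
#' @return whole-number percentage cropped.
#' @export
cropAccounting <- function(totalSections, usedSections) {
  if (totalSections == 0) stop("totalSections must be positive")
  stopifnot(usedSections <= totalSections, usedSections >= 0)
  as.integer(floor(100 * (totalSections - usedSections) / totalSections + 0.5))
}
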