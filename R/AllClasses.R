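#' @import methods
NULL

#' Stain optical-density model for brightfield triple staining
#'
#' Bundles the 3x3 stain matrix used both to render synthetic sections and to
#' unmix scanned ones.  Rows are unit optical-density vectors for the three
#' chromogens in the order brown (SMA, DAB), blue (CD34, AP blue), red
#' (CD271/CD20, AP red); columns are R, G, B.
#'
#' @slot odMatrix 3x3 numeric matrix, rows unit-norm stain OD vectors.
#' @slot backgroundRgb background (unstained) transmitted color, default
#'   white (255,255,255).
#' @slot concentrationScale named numeric, optical-density amplitude per
#'   structure class used by the phantom renderer.
#' @export
setClass("StainModel",
  representation(
    odMatrix = "matrix",
    backgroundRgb = "numeric",
    concentrationScale = "numeric"
  ),
  validity = function(object) {
    m <- object@odMatrix
    if (!all(dim(m) == c(3, 3))) return("odMatrix must be 3x3")
    rn <- sqrt(rowSums(m^2))
    if (any(abs(rn - 1) > 1e-6)) return("odMatrix rows must have unit norm")
    if (abs(det(m)) < 1e-8) return("odMatrix is singular")
    if (kappa(m) > 1e6) return("odMatrix condition number too large")
    if (length(object@backgroundRgb) != 3 || any(object@backgroundRgb <= 0))
      return("backgroundRgb must be 3 positive values")
    TRUE
  }
)

#' Specification of a synthetic splenic-microvasculature phantom
#'
#' Describes the simulated acquisition (geometry, jitter, noise, losses) and
#' the vascular content (arteriole trees, sheathed capillaries with up to four
#' covered bifurcations, open-ended side branches, bypass capillaries, a
#' venule, B cells).  Ranges are length-2 integer vectors sampled uniformly.
#'
#' @slot domainSizeUm x,y,z extent of the tissue block in micrometers.
#' @slot pixelSizeUm in-plane sampling, default 0.5.
#' @slot sectionThicknessUm physical section thickness, default 7.
#' @slot nArterioles number of arteriole trees.
#' @slot branchesPerArteriole range of terminal branches per arteriole.
#' @slot sheathBifurcationDepth range (0..4) of dichotomous bifurcations
#'   covered by a sheath.
#' @slot sideBranchesPerSheath range of open-ended side branches per sheath.
#' @slot nBypassCapillaries count of non-sheathed arteriole-to-network links.
#' @slot nVenuleContacts count of capillary-venule contacts (0 disables the
#'   venule).
#' @slot bcellDensity B cells placed per sheath.
#' @slot jitterTranslationPx max abs per-section translation jitter (pixels).
#' @slot jitterRotationDeg max abs per-section rotation jitter (degrees).
#' @slot lostSectionIndices 0-based indices of sections lost at the microtome.
#' @slot noiseSd Gaussian pixel noise standard deviation (8-bit units).
#' @slot radiiUm named vessel radii (stem, branch, sheathed, side, network,
#'   bypass, venule, sheathInner, sheathOuter, bcell) in micrometers.
#' @slot stemLengthUm length of the arteriole stem; NA picks a default
#'   proportional to the domain depth.
#' @slot seed integer seed making the phantom deterministic.
#' @export
setClass("PhantomSpec",
  representation(
    domainSizeUm = "numeric",
    pixelSizeUm = "numeric",
    sectionThicknessUm = "numeric",
    nArterioles = "integer",
    branchesPerArteriole = "integer",
    sheathBifurcationDepth = "integer",
    sideBranchesPerSheath = "integer",
    nBypassCapillaries = "integer",
    nVenuleContacts = "integer",
    bcellDensity = "numeric",
    jitterTranslationPx = "numeric",
    jitterRotationDeg = "numeric",
    lostSectionIndices = "integer",
    noiseSd = "numeric",
    radiiUm = "numeric",
    stemLengthUm = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    if (length(object@domainSizeUm) != 3 || any(object@domainSizeUm <= 0))
      return("domainSizeUm must be 3 positive extents")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    if (object@sectionThicknessUm <= 0) return("sectionThicknessUm must be positive")
    for (f in c("nArterioles", "nBypassCapillaries", "nVenuleContacts"))
      if (slot(object, f) < 0) return(paste(f, "must be >= 0"))
    for (f in c("branchesPerArteriole", "sheathBifurcationDepth", "sideBranchesPerSheath")) {
      r <- slot(object, f)
      if (length(r) != 2 || any(r < 0) || r[1] > r[2])
        return(paste(f, "must be a non-decreasing, non-negative range"))
    }
    if (max(object@sheathBifurcationDepth) > 4)
      return("sheathBifurcationDepth must not exceed 4")
    if (object@bcellDensity < 0) return("bcellDensity must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (any(object@radiiUm <= 0)) return("all radii must be positive")
    need <- c("stem", "branch", "sheathed", "side", "network", "bypass",
              "venule", "sheathInner", "sheathOuter", "bcell")
    if (!all(need %in% names(object@radiiUm)))
      return(paste("radiiUm must name:", paste(need, collapse = ", ")))
    TRUE
  }
)

#' Vascular ground truth of a phantom
#'
#' A centerline graph with per-edge radii and structure classes, the sheath
#' shells, B-cell spheres and the stain assignment.  The designated
#' "hero" sheathed path (a long multi-bifurcation path built for geodesic
#' checks) is recorded with its entry/exit nodes and centerline length.
#'
#' @slot nodes N x 3 matrix of node positions (um).
#' @slot edges data.frame with columns from, to (node indices), radiusUm,
#'   class (structure class), sheath (sheath id or NA), venuleContact.
#' @slot sheaths list of lists (edges, innerRadiusUm, outerRadiusUm).
#' @slot bcells matrix with columns x, y, z, r (um).
#' @slot stainMap named list mapping structure class to stain subset.
#' @slot heroPath list (nodes, entry, exit, lengthUm) or empty list.
#' @slot domainSizeUm copied from the spec for voxelization defaults.
#' @export
setClass("PhantomGroundTruth",
  representation(
    nodes = "matrix",
    edges = "data.frame",
    sheaths = "list",
    bcells = "matrix",
    stainMap = "list",
    heroPath = "list",
    domainSizeUm = "numeric"
  ),
  validity = function(object) {
    if (nrow(object@edges) > 0) {
      if (any(object@edges$from < 1) || any(object@edges$to > nrow(object@nodes)))
        return("edge endpoints out of range")
      if (any(object@edges$radiusUm <= 0)) return("edge radii must be positive")
    }
    for (s in object@sheaths) {
      if (s$innerRadiusUm >= s$outerRadiusUm)
        return("sheath inner radius must be below outer radius")
    }
    TRUE
  }
)

#' One serial section as a registered or raw RGB raster
#'
#' @slot pixels H x W x 3 numeric array, 0..255 (float; quantized only at I/O).
#' @slot pixelSizeUm in-plane sampling in micrometers per pixel.
#' @slot sectionIndex 0-based position in the cut series.
#' @slot zUm section z, equal to sectionIndex * thickness.
#' @slot stainSet character subset of SMA, CD34 plus CD271 or CD20.
#' @slot focusOk scan focus flag.
#' @export
setClass("SectionImage",
  representation(
    pixels = "array",
    pixelSizeUm = "numeric",
    sectionIndex = "integer",
    zUm = "numeric",
    stainSet = "character",
    focusOk = "logical"
  ),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1)
      return("pixels must be a H x W x 3 array")
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    if (object@sectionIndex < 0) return("sectionIndex must be >= 0")
    TRUE
  }
)

#' An ordered stack of serial sections plus acquisition metadata
#'
#' @slot sections list of \linkS4class{SectionImage}.
#' @slot thicknessUm nominal section thickness.
#' @slot jitter data.frame (theta, tx, ty) of the true per-section rigid
#'   jitter applied by the renderer (radians / pixels); empty for real data.
#' @slot lostSections 0-based indices removed from the series.
#' @slot meta free-form list (seed, parity, provenance).
#' @export
setClass("SectionStack",
  representation(
    sections = "list",
    thicknessUm = "numeric",
    jitter = "data.frame",
    lostSections = "integer",
    meta = "list"
  )
)

#' Per-section planar transforms into a common stack frame
#'
#' The transform of section k maps its raw pixel coordinates into the frame
#' of the reference section: p' = R(theta) (p - c) + c + t with c the image
#' center; the reference transform is the identity (gauge fixing).
#'
#' @slot transforms data.frame with columns theta (radians), tx, ty (pixels).
#' @slot referenceIndex 1-based index of the gauge-fixing section.
#' @slot residuals data.frame of per-pair RMS match residuals (pixels).
#' @export
setClass("StackAlignment",
  representation(
    transforms = "data.frame",
    referenceIndex = "integer",
    residuals = "data.frame"
  ),
  validity = function(object) {
    tr <- object@transforms
    if (!all(c("theta", "tx", "ty") %in% names(tr)))
      return("transforms needs columns theta, tx, ty")
    ri <- object@referenceIndex
    if (ri < 1 || ri > nrow(tr)) return("referenceIndex out of range")
    if (max(abs(unlist(tr[ri, c("theta", "tx", "ty")]))) > 1e-9)
      return("reference transform must be the identity")
    TRUE
  }
)

#' A scalar channel volume with anisotropic spacing
#'
#' @slot values H x W x Z numeric array (0..255 intensity scale).
#' @slot spacingUm voxel spacing (x, y, z) in micrometers.
#' @slot originUm world offset of the grid (voxel center of index (0,0,0) is
#'   originUm + spacingUm/2).
#' @slot channel one of CD34, SMA, CD271, CD20 (or a free label).
#' @slot provenance raw, interpolated or filtered.
#' @export
setClass("ChannelVolume",
  representation(
    values = "array",
    spacingUm = "numeric",
    originUm = "numeric",
    channel = "character",
    provenance = "character"
  ),
  validity = function(object) {
    if (length(dim(object@values)) != 3) return("values must be 3-dimensional")
    if (length(object@spacingUm) != 3 || any(object@spacingUm <= 0))
      return("spacingUm must be 3 positive values")
    if (length(object@originUm) != 3) return("originUm must have length 3")
    TRUE
  }
)

#' A triangulated surface in micrometer world coordinates
#'
#' @slot vertices N x 3 numeric matrix (um).
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @slot vertexColors N x 3 numeric matrix (0..255) or 0-row matrix.
#' @slot channel channel label of origin.
#' @export
setClass("SurfaceMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    vertexColors = "matrix",
    channel = "character"
  ),
  validity = function(object) {
    if (nrow(object@faces) > 0) {
      if (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices))
        return("face indices out of range")
    }
    if (nrow(object@vertexColors) > 0 &&
        nrow(object@vertexColors) != nrow(object@vertices))
      return("vertexColors must have one row per vertex")
    TRUE
  }
)

#' Result of proximity painting of one mesh by another
#'
#' @slot mesh the painted source mesh (vertex colors set).
#' @slot thresholdUm strict highlight distance in micrometers.
#' @slot highlighted logical per source vertex.
#' @slot distancesUm per-vertex distance to the target surface.
#' @export
setClass("ProximityPaint",
  representation(
    mesh = "SurfaceMesh",
    thresholdUm = "numeric",
    highlighted = "logical",
    distancesUm = "numeric"
  )
)

#' Phantom-based recovery scores of the reconstructed meshes
#'
#' @slot sheathDetectionRate fraction of ground-truth sheaths recovered.
#' @slot sideBranchDetectionRate fraction of open-ended side branches whose
#'   free end is present in the capillary mesh.
#' @slot bypassCount,bypassTruth detected vs true bypass capillaries.
#' @slot venuleContactCount,venuleContactTruth detected vs true contacts.
#' @slot geodesicUm data.frame of measured vs true entry-to-exit geodesic
#'   lengths of designated sheathed paths.
#' @export
setClass("RecoveryReport",
  representation(
    sheathDetectionRate = "numeric",
    sideBranchDetectionRate = "numeric",
    bypassCount = "integer",
    bypassTruth = "integer",
    venuleContactCount = "integer",
    venuleContactTruth = "integer",
    geodesicUm = "data.frame"
  ),
  validity = function(object) {
    r <- c(object@sheathDetectionRate, object@sideBranchDetectionRate)
    r <- r[!is.na(r)]
    if (any(r < 0 | r > 1)) return("rates must lie in [0, 1]")
    if (any(c(object@bypassCount, object@venuleContactCount) < 0))
      return("counts must be non-negative")
    TRUE
  }
)

#' Full pipeline configuration
#'
#' @slot geometry list (pixelSizeUm, thicknessUm, cropPx).
#' @slot channels per-channel blocks (iso, interpFactor, interpMethod,
#'   morphology, octreeDepth, componentFraction, decimateFraction).
#' @slot stain \linkS4class{StainModel}.
#' @slot registration list (sigma, k, maxFeatures).
#' @slot phantom \linkS4class{PhantomSpec}.
#' @slot recovery list (toleranceUm).
#' @slot seed integer master seed.
#' @export
setClass("PipelineConfig",
  representation(
    geometry = "list",
    channels = "list",
    stain = "StainModel",
    registration = "list",
    phantom = "PhantomSpec",
    recovery = "list",
    seed = "integer"
  )
)

#' Record of one pipeline run
#'
#' @slot configHash hash of the serialized configuration.
#' @slot seed master seed of the run.
#' @slot timings named numeric, seconds per stage.
#' @slot outputs named list of stage outputs kept in memory or paths.
#' @slot warnings character vector of stage warnings.
#' @export
setClass("RunManifest",
  representation(
    configHash = "character",
    seed = "integer",
    timings = "numeric",
    outputs = "list",
    warnings = "character"
  )
)
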