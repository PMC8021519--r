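#' Write a section stack as numbered TIFF files plus a JSON sidecar
#'
#' Files are named \code{section_0000.tif} after the 0-based section index;
#' the sidecar records pixel size, thickness, stain sets, focus flags, lost
#' sections and (for phantoms) the true jitter.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param dir output directory (created if needed).
#' @return invisibly the sidecar path.
#' @export
writeSectionStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in stack@sections) {
    tiff::writeTIFF(pmin(pmax(s@pixels / 255, 0), 1),
                    file.path(dir, sprintf("section_%04d.tif", s@sectionIndex)))
  }
  meta <- list(
    pixelSizeUm = stack@sections[[1]]@pixelSizeUm,
    thicknessUm = stack@thicknessUm,
    lostSections = stack@lostSections,
    sections = lapply(stack@sections, function(s)
      list(index = s@sectionIndex, zUm = s@zUm, stainSet = s@stainSet,
           focusOk = s@focusOk)),
    jitter = if (nrow(stack@jitter) > 0) stack@jitter else NULL)
  path <- file.path(dir, "stack.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a section stack written by \code{\link{writeSectionStack}}
#'
#' @param dir directory holding section_####.tif and stack.json.
#' @return a \linkS4class{SectionStack}.
#' @export
readSectionStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  secs <- lapply(seq_len(nrow(meta$sections)), function(i) {
    r <- meta$sections[i, ]
    px <- tiff::readTIFF(file.path(dir, sprintf("section_%04d.tif", r$index)))
    new("SectionImage", pixels = px * 255, pixelSizeUm = meta$pixelSizeUm,
        sectionIndex = as.integer(r$index), zUm = r$zUm,
        stainSet = unlist(r$stainSet), focusOk = r$focusOk)
  })
  jit <- if (!is.null(meta$jitter)) as.data.frame(meta$jitter)
         else data.frame(theta = numeric(0), tx = numeric(0), ty = numeric(0))
  new("SectionStack", sections = secs, thicknessUm = meta$thicknessUm,
      jitter = jit, lostSections = as.integer(meta$lostSections %||% integer(0)),
      meta = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a channel volume as a multi-page TIFF plus JSON sidecar
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param path output TIFF path; the sidecar gets extension .json.
#' @return invisibly the sidecar path.
#' @export
writeChannelVolume <- function(volume, path) {
  pages <- lapply(seq_len(dim(volume@values)[3]), function(k)
    pmin(pmax(volume@values[, , k] / 255, 0), 1))
  tiff::writeTIFF(pages, path)
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(spacingUm = volume@spacingUm,
                            originUm = volume@originUm,
                            channel = volume@channel,
                            provenance = volume@provenance),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a channel volume written by \code{\link{writeChannelVolume}}
#'
#' @param path TIFF path with .json sidecar alongside.
#' @return a \linkS4class{ChannelVolume}.
#' @export
readChannelVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 255
  new("ChannelVolume", values = arr, spacingUm = meta$spacingUm,
      originUm = meta$originUm, channel = meta$channel,
      provenance = meta$provenance)
}

#' Write a mesh as PLY
#'
#' ASCII or binary-little-endian PLY; per-vertex uchar colors are written
#' when the mesh carries them.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output path.
#' @param binary write binary_little_endian (default) or ascii.
#' @return invisibly the path.
#' @export
writeMeshPLY <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  hasCol <- nrow(mesh@vertexColors) == nv && nv > 0
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment splenvas mesh",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (hasCol)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (binary) {
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh@vertices[i, ]), con, size = 4,
               endian = "little")
      if (hasCol)
        writeBin(as.raw(round(mesh@vertexColors[i, ])), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh@faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    if (nv > 0) {
      vl <- apply(mesh@vertices, 1, function(v)
        sprintf("%.6g %.6g %.6g", v[1], v[2], v[3]))
      if (hasCol)
        vl <- paste(vl, apply(round(mesh@vertexColors), 1, paste, collapse = " "))
      writeLines(vl, con)
    }
    if (nf > 0)
      writeLines(apply(mesh@faces - 1L, 1, function(f)
        paste(c(3, f), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PLY mesh (ascii or binary little-endian)
#'
#' Supports the vertex/face layout written by \code{\link{writeMeshPLY}}
#' (float x/y/z, optional uchar rgb, uchar-counted int face lists).
#'
#' @param path PLY path.
#' @param channel channel label to attach.
#' @return a \linkS4class{SurfaceMesh}.
#' @export
readMeshPLY <- function(path, channel = "generic") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face", hdr, value = TRUE)))
  hasCol <- any(grepl("property uchar red", hdr))
  if (fmt == "ascii") {
    V <- matrix(0, nv, 3)
    C <- if (hasCol) matrix(0, nv, 3) else matrix(numeric(0), 0, 3)
    for (i in seq_len(nv)) {
      x <- scan(con, numeric(), n = if (hasCol) 6 else 3, quiet = TRUE)
      V[i, ] <- x[1:3]
      if (hasCol) C[i, ] <- x[4:6]
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      x <- scan(con, integer(), n = 4, quiet = TRUE)
      F[i, ] <- x[2:4] + 1L
    }
  } else {
    V <- matrix(0, nv, 3)
    C <- if (hasCol) matrix(0, nv, 3) else matrix(numeric(0), 0, 3)
    for (i in seq_len(nv)) {
      V[i, ] <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
      if (hasCol) C[i, ] <- as.integer(readBin(con, raw(), n = 3))
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      readBin(con, raw(), n = 1)
      F[i, ] <- readBin(con, integer(), n = 3, size = 4, endian = "little") + 1L
    }
  }
  makeMesh(V, F, channel, if (hasCol) C else NULL)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output path.
#' @return invisibly the path.
#' @export
writeMeshOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh@vertices) > 0)
    writeLines(apply(mesh@vertices, 1, function(v)
      sprintf("v %.6g %.6g %.6g", v[1], v[2], v[3])), con)
  if (nrow(mesh@faces) > 0)
    writeLines(apply(mesh@faces, 1, function(f)
      sprintf("f %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}

#' Write a closed mesh as ASCII STL
#'
#' @param mesh a closed \linkS4class{SurfaceMesh}.
#' @param path output path.
#' @return invisibly the path.
#' @export
writeMeshSTL <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid splenvas", con)
  V <- mesh@vertices
  for (i in seq_len(nrow(mesh@faces))) {
    f <- mesh@faces[i, ]
    a <- V[f[1], ]; b <- V[f[2], ]; cc <- V[f[3], ]
    n <- c((b[2]-a[2])*(cc[3]-a[3]) - (b[3]-a[3])*(cc[2]-a[2]),
           (b[3]-a[3])*(cc[1]-a[1]) - (b[1]-a[1])*(cc[3]-a[3]),
           (b[1]-a[1])*(cc[2]-a[2]) - (b[2]-a[2])*(cc[1]-a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.6g %.6g %.6g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.6g %.6g %.6g", a[1], a[2], a[3]),
                 sprintf("    vertex %.6g %.6g %.6g", b[1], b[2], b[3]),
                 sprintf("    vertex %.6g %.6g %.6g", cc[1], cc[2], cc[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid splenvas", con)
  invisible(path)
}

#' Serialize phantom ground truth to JSON
#'
#' @param gt a \linkS4class{PhantomGroundTruth}.
#' @param path output path.
#' @return invisibly the path.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(list(
    nodes = gt@nodes, edges = gt@edges, sheaths = gt@sheaths,
    bcells = gt@bcells, stainMap = gt@stainMap, heroPath = gt@heroPath,
    domainSizeUm = gt@domainSizeUm),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read phantom ground truth from JSON
#'
#' @param path JSON path written by \code{\link{writeGroundTruth}}.
#' @return a \linkS4class{PhantomGroundTruth}.
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  nodes <- if (length(j$nodes) > 0)
    do.call(rbind, lapply(j$nodes, num)) else matrix(numeric(0), 0, 3)
  edges <- data.frame(
    from = as.integer(unlist(j$edges$from)),
    to = as.integer(unlist(j$edges$to)),
    radiusUm = num(j$edges$radiusUm),
    class = as.character(unlist(j$edges$class)),
    sheath = vapply(j$edges$sheath, function(x) {
      if (is.null(x)) return(NA_integer_)
      xi <- suppressWarnings(as.integer(x))
      if (length(xi) == 0 || is.na(xi)) NA_integer_ else xi
    }, integer(1)),
    venuleContact = as.logical(unlist(j$edges$venuleContact)))
  sheaths <- lapply(j$sheaths, function(s) {
    s$edges <- as.integer(unlist(s$edges))
    s$pathNodes <- as.integer(unlist(s$pathNodes))
    s[c("innerRadiusUm", "outerRadiusUm", "nBifurcations", "entry", "exit")] <-
      lapply(s[c("innerRadiusUm", "outerRadiusUm", "nBifurcations", "entry",
                 "exit")], as.numeric)
    s
  })
  hero <- lapply(j$heroPath, function(x) unlist(x))
  if (length(hero) > 0) hero$nodes <- as.integer(hero$nodes)
  bc <- if (length(j$bcells) > 0)
    do.call(rbind, lapply(j$bcells, num)) else matrix(numeric(0), 0, 4)
  colnames(bc) <- c("x", "y", "z", "r")
  new("PhantomGroundTruth", nodes = nodes, edges = edges, sheaths = sheaths,
      bcells = bc, stainMap = lapply(j$stainMap, function(x) unlist(x)),
      heroPath = hero, domainSizeUm = num(j$domainSizeUm))
}

#' Write a stack alignment as a plain-text table
#'
#' Tab-separated columns: section (1-based), theta (radians), tx, ty
#' (pixels); header comments record the reference index.
#'
#' @param alignment a \linkS4class{StackAlignment}.
#' @param path output path.
#' @return invisibly the path.
#' @export
writeAlignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference_index\t%d", alignment@referenceIndex), con)
  tr <- alignment@transforms
  writeLines("section\ttheta\ttx\tty", con)
  writeLines(sprintf("%d\t%.10g\t%.10g\t%.10g", seq_len(nrow(tr)),
                     tr$theta, tr$tx, tr$ty), con)
  invisible(path)
}

#' Read a stack alignment written by \code{\link{writeAlignment}}
#'
#' @param path alignment table path.
#' @return a \linkS4class{StackAlignment}.
#' @export
readAlignment <- function(path) {
  lns <- readLines(path)
  ref <- as.integer(sub("^# reference_index\t", "", lns[1]))
  df <- utils::read.table(text = lns[-1], header = TRUE, sep = "\t")
  new("StackAlignment",
      transforms = df[, c("theta", "tx", "ty")],
      referenceIndex = ref,
      residuals = data.frame())
}

#' Write a pipeline configuration as YAML
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path output path.
#' @return invisibly the path.
#' @export
writePipelineConfig <- function(config, path) {
  sp <- config@phantom
  lst <- list(
    seed = config@seed,
    geometry = config@geometry,
    channels = config@channels,
    registration = config@registration,
    recovery = config@recovery,
    stain = list(odMatrix = as.numeric(config@stain@odMatrix),
                 backgroundRgb = config@stain@backgroundRgb,
                 concentrationScale = as.list(config@stain@concentrationScale)),
    phantom = list(
      domainSizeUm = sp@domainSizeUm, pixelSizeUm = sp@pixelSizeUm,
      sectionThicknessUm = sp@sectionThicknessUm,
      nArterioles = sp@nArterioles,
      branchesPerArteriole = sp@branchesPerArteriole,
      sheathBifurcationDepth = sp@sheathBifurcationDepth,
      sideBranchesPerSheath = sp@sideBranchesPerSheath,
      nBypassCapillaries = sp@nBypassCapillaries,
      nVenuleContacts = sp@nVenuleContacts,
      bcellDensity = sp@bcellDensity,
      jitterTranslationPx = sp@jitterTranslationPx,
      jitterRotationDeg = sp@jitterRotationDeg,
      lostSectionIndices = sp@lostSectionIndices,
      noiseSd = sp@noiseSd,
      radiiUm = as.list(sp@radiiUm),
      stemLengthUm = sp@stemLengthUm,
      seed = sp@seed))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration written by \code{\link{writePipelineConfig}}
#'
#' @param path YAML path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  spec <- phantomSpec(
    domainSizeUm = as.numeric(ph$domainSizeUm),
    pixelSizeUm = ph$pixelSizeUm,
    sectionThicknessUm = ph$sectionThicknessUm,
    nArterioles = ph$nArterioles,
    branchesPerArteriole = as.integer(ph$branchesPerArteriole),
    sheathBifurcationDepth = as.integer(ph$sheathBifurcationDepth),
    sideBranchesPerSheath = as.integer(ph$sideBranchesPerSheath),
    nBypassCapillaries = ph$nBypassCapillaries,
    nVenuleContacts = ph$nVenuleContacts,
    bcellDensity = ph$bcellDensity,
    jitterTranslationPx = ph$jitterTranslationPx,
    jitterRotationDeg = ph$jitterRotationDeg,
    lostSectionIndices = as.integer(ph$lostSectionIndices %||% integer(0)),
    noiseSd = ph$noiseSd,
    radiiUm = unlist(ph$radiiUm),
    stemLengthUm = ph$stemLengthUm %||% NA_real_,
    seed = ph$seed)
  sm <- stainModel(
    odMatrix = matrix(y$stain$odMatrix, 3, 3),
    backgroundRgb = as.numeric(y$stain$backgroundRgb),
    concentrationScale = unlist(y$stain$concentrationScale))
  cfg <- new("PipelineConfig",
             geometry = y$geometry, channels = y$channels, stain = sm,
             registration = y$registration, phantom = spec,
             recovery = y$recovery, seed = as.integer(y$seed))
  validatePipelineConfig(cfg)
  cfg
}
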