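#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of one of the package classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("vertexColors", function(x) standardGeneric("vertexColors"))
#' @rdname accessors
#' @export
setGeneric("volArray", function(x) standardGeneric("volArray"))
#' @rdname accessors
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))
#' @rdname accessors
#' @export
setGeneric("originUm", function(x) standardGeneric("originUm"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
#' @rdname accessors
#' @export
setGeneric("sectionPixels", function(x) standardGeneric("sectionPixels"))
#' @rdname accessors
#' @export
setGeneric("sections", function(x) standardGeneric("sections"))
#' @rdname accessors
#' @export
setGeneric("alignmentTransforms", function(x) standardGeneric("alignmentTransforms"))
#' @rdname accessors
#' @export
setGeneric("odMatrix", function(x) standardGeneric("odMatrix"))
#' @rdname accessors
#' @export
setGeneric("gtEdges", function(x) standardGeneric("gtEdges"))
#' @rdname accessors
#' @export
setGeneric("gtNodes", function(x) standardGeneric("gtNodes"))

#' @rdname accessors
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
setMethod("vertexColors", "SurfaceMesh", function(x) x@vertexColors)
#' @rdname accessors
setMethod("volArray", "ChannelVolume", function(x) x@values)
#' @rdname accessors
setMethod("spacingUm", "ChannelVolume", function(x) x@spacingUm)
#' @rdname accessors
setMethod("originUm", "ChannelVolume", function(x) x@originUm)
#' @rdname accessors
setMethod("channelLabel", "ChannelVolume", function(x) x@channel)
#' @rdname accessors
setMethod("channelLabel", "SurfaceMesh", function(x) x@channel)
#' @rdname accessors
setMethod("sectionPixels", "SectionImage", function(x) x@pixels)
#' @rdname accessors
setMethod("sections", "SectionStack", function(x) x@sections)
#' @rdname accessors
setMethod("alignmentTransforms", "StackAlignment", function(x) x@transforms)
#' @rdname accessors
setMethod("odMatrix", "StainModel", function(x) x@odMatrix)
#' @rdname accessors
setMethod("gtEdges", "PhantomGroundTruth", function(x) x@edges)
#' @rdname accessors
setMethod("gtNodes", "PhantomGroundTruth", function(x) x@nodes)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d faces%s\n",
              object@channel, nrow(object@vertices), nrow(object@faces),
              if (nrow(object@vertexColors) > 0) ", colored" else ""))
  if (nrow(object@vertices) > 0) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox um: [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
})

setMethod("show", "ChannelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ChannelVolume [%s, %s]: %d x %d x %d voxels @ (%.2g, %.2g, %.2g) um\n",
              object@channel, object@provenance, d[2], d[1], d[3],
              object@spacingUm[1], object@spacingUm[2], object@spacingUm[3]))
})

setMethod("show", "SectionStack", function(object) {
  cat(sprintf("SectionStack: %d sections, thickness %.3g um%s\n",
              length(object@sections), object@thicknessUm,
              if (length(object@lostSections)) paste0(", lost: ",
                paste(object@lostSections, collapse = ",")) else ""))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf("PhantomGroundTruth: %d nodes, %d edges, %d sheaths, %d B cells\n",
              nrow(object@nodes), nrow(object@edges), length(object@sheaths),
              nrow(object@bcells)))
  if (nrow(object@edges) > 0) {
    tab <- table(object@edges$class)
    cat("  edges by class:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "StackAlignment", function(object) {
  tr <- object@transforms
  cat(sprintf("StackAlignment: %d sections, reference %d\n",
              nrow(tr), object@referenceIndex))
  cat(sprintf("  |t| range %.2f..%.2f px, |theta| max %.3f deg\n",
              min(sqrt(tr$tx^2 + tr$ty^2)), max(sqrt(tr$tx^2 + tr$ty^2)),
              max(abs(tr$theta)) * 180 / pi))
})

setMethod("show", "RecoveryReport", function(object) {
  cat("RecoveryReport\n")
  cat(sprintf("  sheath detection:       %.2f\n", object@sheathDetectionRate))
  cat(sprintf("  side-branch detection:  %.2f\n", object@sideBranchDetectionRate))
  cat(sprintf("  bypass capillaries:     %d / %d\n", object@bypassCount,
              object@bypassTruth))
  cat(sprintf("  venule contacts:        %d / %d\n", object@venuleContactCount,
              object@venuleContactTruth))
  if (nrow(object@geodesicUm) > 0) {
    with(object@geodesicUm, cat(sprintf(
      "  geodesic entry-to-exit: measured %.1f um vs true %.1f um\n",
      measured, truth)))
  }
})
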