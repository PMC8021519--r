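#' Taubin mesh smoothing
#'
#' Alternating lambda/mu umbrella-Laplacian steps (defaults lambda = 0.5,
#' mu = -0.53), which smooth without the shrinkage of plain Laplacian
#' smoothing.  Topology is unchanged.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param iterations number of lambda+mu pairs, default 10.
#' @param lambda,mu step sizes.
#' @return the smoothed \linkS4class{SurfaceMesh}.
#' @export
taubinSmooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  if (iterations == 0 || nrow(mesh@faces) == 0) return(mesh)
  out <- mesh
  out@vertices <- cpp_taubin(mesh@vertices, mesh@faces, lambda, mu,
                             as.integer(iterations))
  out
}

# connected components of a mesh: list of vertex-id vectors
meshComponentIds <- function(mesh) {
  cpp_mesh_components(nrow(mesh@vertices), mesh@faces)
}

#' Remove small disconnected components
#'
#' Deletes connected components whose bounding-box diagonal is below
#' \code{fraction} of the whole mesh's main (bounding-box) diagonal.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param fraction threshold fraction in (0, 1).
#' @return the filtered \linkS4class{SurfaceMesh}.
#' @export
removeSmallComponents <- function(mesh, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(mesh@faces) == 0) return(mesh)
  comp <- meshComponentIds(mesh)
  mainDiag <- bboxDiagonal(mesh@vertices)
  keep <- logical(length(comp))
  for (cid in unique(comp)) {
    sel <- comp == cid
    keep[sel] <- bboxDiagonal(mesh@vertices[sel, , drop = FALSE]) >=
      fraction * mainDiag
  }
  subsetMeshByVertices(mesh, keep)
}

#' Quadric-error-metric mesh decimation
#'
#' Edge collapses ordered by quadric error until the face count is at most
#' \code{keepFraction} of the input; collapses that would pinch the mesh or
#' flip surviving faces are rejected, so manifoldness is preserved.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param keepFraction target face fraction in (0, 1].
#' @return the decimated \linkS4class{SurfaceMesh}.
#' @export
quadricDecimate <- function(mesh, keepFraction) {
  stopifnot(keepFraction > 0, keepFraction <= 1)
  if (keepFraction == 1 || nrow(mesh@faces) == 0) return(mesh)
  target <- floor(keepFraction * nrow(mesh@faces))
  if (target < 4) {
    warning("decimation target below a minimal closed mesh; clamped to 4 faces")
    target <- 4L
  }
  m <- cpp_quadric_decimate(mesh@vertices, mesh@faces, as.integer(target))
  makeMesh(m$vertices, m$faces, mesh@channel)
}

#' Highlight mesh vertices near another mesh
#'
#' Computes the exact point-to-surface (point-to-triangle, not vertex-only)
#' distance from every source vertex to the target mesh and highlights the
#' vertices strictly closer than the threshold.  Highlighted vertices are
#' painted white, the rest blue, matching the arteriole-highlight rendering
#' of smooth-muscle proximity on the capillary mesh.
#'
#' @param source source \linkS4class{SurfaceMesh} (e.g. CD34 capillaries).
#' @param target target \linkS4class{SurfaceMesh} (e.g. SMA smooth muscle).
#' @param thresholdUm strict highlight distance, default 8.75 um.
#' @return a \linkS4class{ProximityPaint}.
#' @export
paintByProximity <- function(source, target, thresholdUm = 8.75) {
  if (nrow(source@vertices) == 0) stop("empty source mesh")
  if (nrow(target@faces) == 0) {
    d <- rep(Inf, nrow(source@vertices))
  } else {
    cell <- max(thresholdUm, bboxDiagonal(target@vertices) / 128)
    d <- cpp_mesh_distance(source@vertices, target@vertices, target@faces, cell)
  }
  hl <- d < thresholdUm
  cols <- matrix(0, nrow(source@vertices), 3)
  cols[hl, ] <- 255
  cols[!hl, 3] <- 255
  painted <- source
  painted@vertexColors <- cols
  new("ProximityPaint", mesh = painted, thresholdUm = thresholdUm,
      highlighted = hl, distancesUm = d)
}

#' Prune cell components by size and reference proximity
#'
#' Removes connected components of a cell mesh whose bounding-sphere
#' diameter is below \code{minDiameterUm}, and (when \code{maxDistanceUm}
#' is finite) components farther than \code{maxDistanceUm} from every
#' reference mesh - an automated stand-in for the manual selection step of
#' the original workflow.
#'
#' @param cellMesh the B-cell \linkS4class{SurfaceMesh}.
#' @param referenceMeshes list of reference meshes (e.g. CD271 sheaths).
#' @param maxDistanceUm maximum allowed distance to any reference mesh.
#' @param minDiameterUm minimum component diameter, default 10 um.
#' @return the pruned \linkS4class{SurfaceMesh}.
#' @export
pruneCellComponents <- function(cellMesh, referenceMeshes = list(),
                                maxDistanceUm = Inf, minDiameterUm = 10) {
  if (nrow(cellMesh@faces) == 0) return(cellMesh)
  comp <- meshComponentIds(cellMesh)
  keep <- logical(length(comp))
  for (cid in unique(comp)) {
    sel <- comp == cid
    P <- cellMesh@vertices[sel, , drop = FALSE]
    if (2 * boundingSphere(P)$radius < minDiameterUm) next
    ok <- TRUE
    if (is.finite(maxDistanceUm) && length(referenceMeshes) > 0) {
      dmin <- Inf
      for (ref in referenceMeshes) {
        if (nrow(ref@faces) == 0) next
        cell <- max(maxDistanceUm, bboxDiagonal(ref@vertices) / 128)
        dmin <- min(dmin, min(cpp_mesh_distance(P, ref@vertices, ref@faces, cell)))
        if (dmin <= maxDistanceUm) break
      }
      ok <- dmin <= maxDistanceUm
    }
    keep[sel] <- ok
  }
  subsetMeshByVertices(cellMesh, keep)
}

#' On-surface geodesic path length between two points
#'
#' Snaps both points to the nearest mesh vertex and measures the shortest
#' path on a refined edge graph (mesh edges plus edge-midpoint links within
#' every triangle, which removes most of the overestimation of pure
#' edge-graph paths).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param from,to 3-vectors in world micrometers (on or near the surface).
#' @return geodesic length in micrometers.
#' @export
geodesicPathLength <- function(mesh, from, to) {
  V <- mesh@vertices
  if (nrow(V) == 0) stop("empty mesh")
  vi <- which.min(colSums((t(V) - from)^2))
  vj <- which.min(colSums((t(V) - to)^2))
  comp <- meshComponentIds(mesh)
  if (comp[vi] != comp[vj])
    stop("no on-surface path: points lie on different components")
  if (vi == vj) return(0)

  F <- mesh@faces
  nv <- nrow(V)
  # midpoint node ids per undirected edge
  ekey <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
  e1 <- ekey(F[, 1], F[, 2]); e2 <- ekey(F[, 2], F[, 3]); e3 <- ekey(F[, 1], F[, 3])
  allk <- c(e1, e2, e3)
  uk <- unique(allk)
  mid <- match(allk, uk)
  m1 <- mid[seq_len(nrow(F))]
  m2 <- mid[nrow(F) + seq_len(nrow(F))]
  m3 <- mid[2 * nrow(F) + seq_len(nrow(F))]
  midPos <- matrix(0, length(uk), 3)
  midPos[m1, ] <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE]) / 2
  midPos[m2, ] <- (V[F[, 2], , drop = FALSE] + V[F[, 3], , drop = FALSE]) / 2
  midPos[m3, ] <- (V[F[, 1], , drop = FALSE] + V[F[, 3], , drop = FALSE]) / 2
  P <- rbind(V, midPos)
  mids <- nv + cbind(m1, m2, m3)
  ends <- rbind(cbind(F[, 1], F[, 2]), cbind(F[, 2], F[, 3]),
                cbind(F[, 1], F[, 3]),
                cbind(F[, 1], mids[, 1]), cbind(mids[, 1], F[, 2]),
                cbind(F[, 2], mids[, 2]), cbind(mids[, 2], F[, 3]),
                cbind(F[, 1], mids[, 3]), cbind(mids[, 3], F[, 3]),
                cbind(mids[, 1], mids[, 2]), cbind(mids[, 2], mids[, 3]),
                cbind(mids[, 1], mids[, 3]))
  w <- sqrt(rowSums((P[ends[, 1], , drop = FALSE] -
                       P[ends[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::E(g)$weight <- w
  as.numeric(igraph::distances(g, v = vi, to = vj,
                               algorithm = "dijkstra"))
}
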