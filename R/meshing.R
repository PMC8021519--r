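#' Iso-surface extraction from a channel volume
#'
#' Marching-cubes-family extraction on the voxel-center grid with linear
#' edge interpolation of the iso-crossing; grid values exactly equal to the
#' iso-value count as inside.  Face ambiguities are resolved by a fixed
#' rule applied per grid face, which makes the triangulation crack-free;
#' surfaces remain open only where the inside set touches the volume
#' boundary (the behavior watertight repair exists to fix).  Vertex
#' coordinates are world micrometers via the volume's spacing and origin.
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param iso iso-value in (0, 255).
#' @param padBoundary pad the grid with one zero layer so structures cut by
#'   the block boundary are capped; FALSE reproduces the raw open behavior.
#' @return a \linkS4class{SurfaceMesh} (possibly empty).
#' @export
isosurface <- function(volume, iso, padBoundary = TRUE) {
  if (iso <= 0 || iso >= 255) stop("iso must lie in (0, 255)")
  v <- volume@values
  if (!any(v >= iso)) return(emptyMesh(volume@channel))
  origin <- volume@originUm
  if (padBoundary) {
    # one layer of zeros caps structures cut by the ROI boundary, so the
    # extracted surface bounds a solid even at the block faces
    d <- dim(v)
    vp <- array(0, d + 2L)
    vp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
    v <- vp
    origin <- origin - volume@spacingUm
  }
  m <- cpp_isosurface(v, iso, volume@spacingUm, origin)
  makeMesh(m$vertices, m$faces, volume@channel)
}

#' Watertight octree-style mesh repair
#'
#' Rasterizes the mesh into a cubic grid of 2^depth cells spanning its
#' bounding cube, flood-fills the exterior from the grid boundary, and
#' extracts the closed boundary surface of the occupied-plus-enclosed cell
#' set.  The output is a closed 2-manifold (every edge shared by exactly
#' two faces); open tubes cut by the ROI boundary are capped.  For inputs
#' that are already closed, the symmetric Hausdorff distance to the input
#' is bounded by about two cell sizes.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param octreeDepth grid resolution exponent, 4..10 (cells = 2^depth).
#' @return the repaired \linkS4class{SurfaceMesh}.
#' @export
repairWatertight <- function(mesh, octreeDepth) {
  if (octreeDepth < 4 || octreeDepth > 10)
    stop("octreeDepth must lie in [4, 10]")
  if (nrow(mesh@faces) == 0) return(mesh)
  n <- as.integer(2^octreeDepth)
  bb <- apply(mesh@vertices, 2, range)
  ext <- max(bb[2, ] - bb[1, ])
  if (ext <= 0) return(mesh)
  cell <- ext / (n - 4)  # two empty padding cells on every side
  center <- colMeans(bb)
  origin <- center - n * cell / 2
  grid <- cpp_voxelize_mesh(mesh@vertices, mesh@faces, n, origin, cell)
  occ <- cpp_fill_occupancy(grid, n)
  m <- cpp_isosurface_raw(occ, c(n, n, n), 0.5, rep(cell, 3), origin)
  makeMesh(m$vertices, m$faces, mesh@channel)
}

#' Sampled symmetric Hausdorff distance between two meshes
#'
#' Maximum over sampled surface points (vertices, edge midpoints and face
#' centroids) of the exact point-to-surface distance, taken in both
#' directions.
#'
#' @param a,b \linkS4class{SurfaceMesh} objects.
#' @return distance in micrometers.
#' @export
hausdorffDistance <- function(a, b) {
  one <- function(src, dst) {
    V <- src@vertices; F <- src@faces
    P <- rbind(V,
               (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
                  V[F[, 3], , drop = FALSE]) / 3,
               (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE]) / 2,
               (V[F[, 2], , drop = FALSE] + V[F[, 3], , drop = FALSE]) / 2,
               (V[F[, 1], , drop = FALSE] + V[F[, 3], , drop = FALSE]) / 2)
    cell <- max(bboxDiagonal(dst@vertices) / 64, 1e-6)
    max(cpp_mesh_distance(P, dst@vertices, dst@faces, cell))
  }
  max(one(a, b), one(b, a))
}
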