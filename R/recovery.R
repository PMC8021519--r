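# sample points along a segment at roughly `step` um spacing (ends included)
segSamples <- function(a, b, step = 2.5) {
  L <- sqrt(sum((b - a)^2))
  n <- max(2, ceiling(L / step) + 1)
  t <- seq(0, 1, length.out = n)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

# ring of 4 points around center `p`, perpendicular to direction `d`
ringSamples <- function(p, d, radius) {
  d <- d / max(sqrt(sum(d^2)), 1e-9)
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  rbind(p + radius * u, p - radius * u, p + radius * v, p - radius * v)
}

# distance of points to a mesh (Inf for empty meshes)
meshDist <- function(P, mesh, cell = NULL) {
  if (nrow(mesh@faces) == 0) return(rep(Inf, nrow(P)))
  if (is.null(cell)) cell <- max(bboxDiagonal(mesh@vertices) / 96, 1e-6)
  cpp_mesh_distance(P, mesh@vertices, mesh@faces, cell)
}

# is each point inside (or within tol of) a closed mesh?  Filtered channel
# volumes produce thick solids, so interior points can be far from the
# *surface*; coverage therefore combines a voxelized inside test with a
# surface-distance fallback.
meshCovers <- function(P, mesh, tol, n = 192L) {
  if (nrow(mesh@faces) == 0) return(rep(FALSE, nrow(P)))
  bb <- apply(mesh@vertices, 2, range)
  ext <- max(bb[2, ] - bb[1, ])
  cell <- ext / (n - 4)
  origin <- colMeans(bb) - n * cell / 2
  occ <- cpp_fill_occupancy(cpp_voxelize_mesh(mesh@vertices, mesh@faces,
                                              n, origin, cell), n)
  ix <- floor((P[, 1] - origin[1]) / cell)
  iy <- floor((P[, 2] - origin[2]) / cell)
  iz <- floor((P[, 3] - origin[3]) / cell)
  ok <- ix >= 0 & ix < n & iy >= 0 & iy < n & iz >= 0 & iz < n
  inside <- logical(nrow(P))
  idx <- iy[ok] + n * (ix[ok] + n * iz[ok]) + 1
  inside[ok] <- as.integer(occ[idx]) > 0
  inside | meshDist(P, mesh) <= tol
}

#' Score reconstructed meshes against phantom ground truth
#'
#' Quantifies, with known ground truth, the structures that the original
#' workflow identified by expert labeling in virtual reality: capillary
#' sheaths (sampled on their mid-shell surface against the CD271 mesh),
#' open-ended side branches (free tip against the CD34 mesh), bypass
#' capillaries and capillary-venule contacts (centerline sampling against
#' the CD34 mesh), plus the entry-to-exit geodesic length of the designed
#' multi-bifurcation sheathed path measured on the CD34 mesh surface.
#'
#' @param meshes named list of final \linkS4class{SurfaceMesh} objects
#'   (CD34, CD271 at minimum).
#' @param gt the \linkS4class{PhantomGroundTruth}.
#' @param toleranceUm match tolerance in micrometers.
#' @param frame optional rigid frame mapping ground-truth coordinates into
#'   mesh coordinates: list(theta, tUm, centerUm) applied in the x/y plane
#'   (the registered stack lives in the reference section's frame).
#' @return a \linkS4class{RecoveryReport}.
#' @export
recoverTopology <- function(meshes, gt, toleranceUm = 4, frame = NULL) {
  mapPts <- function(P) {
    if (is.null(frame)) return(P)
    xy <- rigid_apply(P[, 1:2, drop = FALSE], frame$theta, frame$tUm,
                      frame$centerUm)
    cbind(xy, P[, 3])
  }
  nodes <- gt@nodes
  e <- gt@edges
  cd34 <- meshes$CD34
  cd271 <- meshes$CD271

  # sheaths: fraction of mid-shell ring samples covered by the CD271 mesh
  sheathHit <- logical(length(gt@sheaths))
  if (length(gt@sheaths) > 0) {
    pts <- NULL
    who <- integer(0)
    for (si in seq_along(gt@sheaths)) {
      s <- gt@sheaths[[si]]
      rmid <- (s$innerRadiusUm + s$outerRadiusUm) / 2
      for (ei in s$edges) {
        a <- nodes[e$from[ei], ]; b <- nodes[e$to[ei], ]
        ctr <- segSamples(a, b, step = 4)
        d <- b - a
        for (k in seq_len(nrow(ctr))) {
          pts <- rbind(pts, ringSamples(ctr[k, ], d, rmid))
          who <- c(who, rep(si, 4))
        }
      }
    }
    cov <- meshCovers(mapPts(pts), cd271, toleranceUm)
    sheathHit <- as.logical(tapply(cov, who, mean) >= 0.5)
  }

  # open-ended side branches: the free tip must be captured by CD34
  sbe <- which(e$class == "side_branch_open")
  sideHit <- logical(length(sbe))
  if (length(sbe) > 0) {
    deg <- tabulate(c(e$from, e$to), nbins = nrow(nodes))
    tips <- t(vapply(sbe, function(ei) {
      tip <- if (deg[e$to[ei]] == 1) e$to[ei] else e$from[ei]
      nodes[tip, ]
    }, numeric(3)))
    dd <- meshDist(mapPts(tips), cd34)
    sideHit <- dd <= toleranceUm + e$radiusUm[sbe]
  }

  # chains of a class: connected components of the class-restricted subgraph
  chainsOf <- function(idx) {
    if (length(idx) == 0) return(list())
    sub <- igraph::graph_from_edgelist(
      cbind(as.character(e$from[idx]), as.character(e$to[idx])),
      directed = FALSE)
    memb <- igraph::components(sub)$membership
    split(idx, memb[as.character(e$from[idx])])
  }
  chainDetected <- function(idx, minFrac = 0.7) {
    pts <- do.call(rbind, lapply(idx, function(ei)
      segSamples(nodes[e$from[ei], ], nodes[e$to[ei], ])))
    dd <- meshDist(mapPts(pts), cd34)
    mean(dd <= toleranceUm + max(e$radiusUm[idx])) >= minFrac
  }
  bypassChains <- chainsOf(which(e$class == "bypass_capillary"))
  bypassDet <- sum(vapply(bypassChains, chainDetected, logical(1)))
  contactIdx <- which(e$venuleContact)
  contactDet <- sum(vapply(contactIdx, function(ei) chainDetected(ei),
                           logical(1)))

  geo <- data.frame(truth = numeric(0), measured = numeric(0),
                    centerline = numeric(0))
  if (length(gt@heroPath) > 0 && nrow(cd34@faces) > 0) {
    entry <- mapPts(nodes[gt@heroPath$entry, , drop = FALSE])
    exitp <- mapPts(nodes[gt@heroPath$exit, , drop = FALSE])
    measured <- tryCatch(
      geodesicPathLength(cd34, as.numeric(entry), as.numeric(exitp)),
      error = function(err) NA_real_)
    ref <- heroReferenceGeodesic(gt)
    geo <- data.frame(truth = ref$geodesicUm, measured = measured,
                      centerline = ref$centerlineUm)
  }

  new("RecoveryReport",
      sheathDetectionRate = if (length(sheathHit)) mean(sheathHit) else NA_real_,
      sideBranchDetectionRate = if (length(sideHit)) mean(sideHit) else NA_real_,
      bypassCount = as.integer(bypassDet),
      bypassTruth = length(bypassChains),
      venuleContactCount = as.integer(contactDet),
      venuleContactTruth = length(contactIdx),
      geodesicUm = geo)
}
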