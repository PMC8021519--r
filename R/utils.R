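# internal helpers shared across modules

# run fn with a temporary RNG state seeded by `seed`, restoring the caller's
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# derive a per-stage 31-bit seed from a master seed (fixed fan-out)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

# 2-D rigid transform p' = R(theta) (p - c) + c + t, points as n x 2 (x, y)
rigid_apply <- function(p, theta, t, center) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(sweep(p, 2, center) %*% t(R), 2, center + t, "+")
}

rigid_invert <- function(theta, t) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  list(theta = -theta, t = as.numeric(-t(R) %*% t))
}

# compose a after b: T(p) = a(b(p)); both about the same center
rigid_compose <- function(thetaA, tA, thetaB, tB) {
  RA <- matrix(c(cos(thetaA), sin(thetaA), -sin(thetaA), cos(thetaA)), 2, 2)
  list(theta = thetaA + thetaB, t = as.numeric(RA %*% tB + tA))
}

#' Surface area of a triangle mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return total area in square micrometers.
#' @export
meshArea <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed triangle mesh
#'
#' Computed by the divergence theorem; meaningful for closed surfaces.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return absolute enclosed volume in cubic micrometers.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

#' Edge manifoldness audit
#'
#' Counts mesh edges by the number of incident faces.  A closed 2-manifold
#' has every edge shared by exactly two faces.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return named integer vector (open, closed, nonmanifold).
#' @export
meshEdgeAudit <- function(mesh) {
  if (nrow(mesh@faces) == 0)
    return(c(open = 0L, closed = 0L, nonmanifold = 0L))
  v <- cpp_edge_face_count(mesh@faces)
  c(open = v[1], closed = v[2], nonmanifold = v[3])
}

#' Is a mesh a closed 2-manifold surface (by edges)?
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return TRUE iff every edge is shared by exactly two faces.
#' @export
isClosedMesh <- function(mesh) {
  a <- meshEdgeAudit(mesh)
  a["open"] == 0 && a["nonmanifold"] == 0 && a["closed"] > 0
}

# construct a SurfaceMesh, dropping unreferenced vertices
makeMesh <- function(vertices, faces, channel = "generic", colors = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (is.null(colors)) colors <- matrix(numeric(0), 0, 3)
  new("SurfaceMesh", vertices = vertices, faces = faces,
      vertexColors = colors, channel = channel)
}

emptyMesh <- function(channel = "generic") {
  makeMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3), channel)
}

# subset a mesh to the faces whose vertices all satisfy `keepVertex`
subsetMeshByVertices <- function(mesh, keepVertex) {
  keepFace <- keepVertex[mesh@faces[, 1]] & keepVertex[mesh@faces[, 2]] &
    keepVertex[mesh@faces[, 3]]
  F <- mesh@faces[keepFace, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  F2 <- matrix(remap[F], ncol = 3)
  cols <- if (nrow(mesh@vertexColors) > 0)
    mesh@vertexColors[used, , drop = FALSE] else NULL
  makeMesh(mesh@vertices[used, , drop = FALSE], F2, mesh@channel, cols)
}

# squared distance from point p to segment [a, b]
pointSegD2 <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
  t <- min(max(t, 0), 1)
  sum((p - a - t * ab)^2)
}

# bounding-box main diagonal length
bboxDiagonal <- function(V) {
  if (nrow(V) == 0) return(0)
  r <- apply(V, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

# Ritter's approximate minimal bounding sphere; returns list(center, radius)
boundingSphere <- function(P) {
  if (nrow(P) == 0) return(list(center = c(0, 0, 0), radius = 0))
  x <- P[1, ]
  d <- rowSums(sweep(P, 2, x)^2)
  y <- P[which.max(d), ]
  d <- rowSums(sweep(P, 2, y)^2)
  z <- P[which.max(d), ]
  c0 <- (y + z) / 2
  r <- sqrt(max(d)) / 2
  for (i in seq_len(nrow(P))) {
    di <- sqrt(sum((P[i, ] - c0)^2))
    if (di > r) {
      r <- (r + di) / 2
      c0 <- c0 + (di - r) / di * (P[i, ] - c0)
    }
  }
  list(center = c0, radius = r)
}
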