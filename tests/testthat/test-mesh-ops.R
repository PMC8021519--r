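test_that("taubin smoothing respects its fixed points and beats shrinkage", {
  sp <- sphereMesh(radius = 10, subdiv = 3)
  expect_identical(taubinSmooth(sp, 0), sp)

  # flat patch: interior vertices of a planar grid mesh do not move
  n <- 8
  V <- as.matrix(expand.grid(x = 1:n, y = 1:n))
  V <- cbind(V, 0)
  F <- NULL
  for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
    a <- (j - 1) * n + i
    F <- rbind(F, c(a, a + 1, a + n), c(a + 1, a + n + 1, a + n))
  }
  patch <- makeMesh(V, F, "t")
  sm <- taubinSmooth(patch, 5)
  expect_lt(max(abs(meshVertices(sm)[, 3])), 1e-9)

  # volume preserved far better than pure Laplacian smoothing
  v0 <- meshVolume(sp)
  vT <- meshVolume(taubinSmooth(sp, 10))
  vL <- meshVolume(taubinSmooth(sp, 10, lambda = 0.5, mu = 0))
  expect_lt(abs(vT - v0), abs(vL - v0))
})

test_that("small-component removal follows the diagonal-fraction rule", {
  big <- sphereMesh(radius = 50, center = c(0, 0, 0), subdiv = 2)
  small <- sphereMesh(radius = 0.5, center = c(120, 0, 0), subdiv = 1)
  single <- removeSmallComponents(big, 0.05)
  expect_equal(nrow(meshFaces(single)), nrow(meshFaces(big)))

  both <- makeMesh(rbind(meshVertices(big), meshVertices(small)),
                   rbind(meshFaces(big), meshFaces(small) + nrow(meshVertices(big))),
                   "t")
  out <- removeSmallComponents(both, 0.05)
  expect_equal(nrow(meshVertices(out)), nrow(meshVertices(big)))

  # monotone: components removed at f are a subset of those removed at f' > f
  mid <- sphereMesh(radius = 10, center = c(0, 120, 0), subdiv = 1)
  tri <- makeMesh(rbind(meshVertices(big), meshVertices(small), meshVertices(mid)),
                  rbind(meshFaces(big), meshFaces(small) + nrow(meshVertices(big)),
                        meshFaces(mid) + nrow(meshVertices(big)) + nrow(meshVertices(small))),
                  "t")
  survivors <- function(f) nrow(meshVertices(removeSmallComponents(tri, f)))
  s <- vapply(c(0.01, 0.08, 0.3), survivors, numeric(1))
  expect_true(all(diff(s) <= 0))
})

test_that("quadric decimation hits its budget and keeps shape and manifoldness", {
  sp <- sphereMesh(radius = 10, subdiv = 4)
  expect_identical(quadricDecimate(sp, 1), sp)
  out <- quadricDecimate(sp, 0.1)
  expect_lte(nrow(meshFaces(out)), 0.1 * nrow(meshFaces(sp)))
  expect_lt(abs(meshArea(out) / meshArea(sp) - 1), 0.05)
  expect_true(isClosedMesh(out))
  expect_warning(quadricDecimate(sphereMesh(subdiv = 1), 0.01), "clamp")
})

test_that("proximity painting matches plane fixtures and the brute-force oracle", {
  src <- planeMesh(0)
  near <- planeMesh(5)
  far <- planeMesh(20)
  expect_true(all(paintByProximity(src, near, 8.75)@highlighted))
  expect_false(any(paintByProximity(src, far, 8.75)@highlighted))

  set.seed(12)
  for (i in 1:4) {
    a <- sphereMesh(radius = runif(1, 5, 9),
                    center = runif(3, 0, 10), subdiv = 2)
    b <- sphereMesh(radius = runif(1, 4, 8),
                    center = runif(3, 5, 20), subdiv = 2)
    paint <- paintByProximity(a, b, 8.75)
    dbrute <- splenvas:::cpp_tri_dist_brute(meshVertices(a), meshVertices(b),
                                            meshFaces(b))
    expect_identical(paint@highlighted, dbrute < 8.75)
    expect_equal(paint@distancesUm, dbrute, tolerance = 1e-12)
    # colors follow the labels
    cols <- vertexColors(paint@mesh)
    expect_true(all(cols[paint@highlighted, ] == 255))
    expect_true(all(cols[!paint@highlighted, 1] == 0))
  }
})

test_that("cell pruning enforces diameter and reference-distance rules", {
  ref <- sphereMesh(radius = 10, center = c(0, 0, 0), subdiv = 2)
  nearSmall <- sphereMesh(radius = 3.5, center = c(14, 0, 0), subdiv = 1)  # d=7
  nearBig <- sphereMesh(radius = 6.5, center = c(0, 18, 0), subdiv = 1)    # d=13
  farBig <- sphereMesh(radius = 7, center = c(60, 60, 60), subdiv = 1)
  glue <- function(ms) {
    V <- NULL; F <- NULL
    for (m in ms) {
      F <- rbind(F, meshFaces(m) + if (is.null(V)) 0 else nrow(V))
      V <- rbind(V, meshVertices(m))
    }
    makeMesh(V, F, "CD20")
  }
  cells <- glue(list(nearSmall, nearBig, farBig))
  out <- pruneCellComponents(cells, list(ref), maxDistanceUm = 15,
                             minDiameterUm = 10)
  # diameter 7 removed, far component removed, near big kept
  expect_equal(nrow(meshVertices(out)), nrow(meshVertices(nearBig)))

  # result invariant to component ordering
  out2 <- pruneCellComponents(glue(list(farBig, nearBig, nearSmall)),
                              list(ref), maxDistanceUm = 15, minDiameterUm = 10)
  expect_equal(sort(meshVertices(out)[, 1]), sort(meshVertices(out2)[, 1]))

  # size rule in isolation: diameter < 10 um removed even with no references
  out3 <- pruneCellComponents(cells, list(), maxDistanceUm = Inf,
                              minDiameterUm = 10)
  expect_equal(nrow(meshVertices(out3)),
               nrow(meshVertices(nearBig)) + nrow(meshVertices(farBig)))
})

test_that("geodesic lengths satisfy metric bounds and the cylinder oracle", {
  cyl <- openCylinderMesh(radius = 5, length = 300, nseg = 36, nz = 120)
  expect_equal(geodesicPathLength(cyl, c(5, 0, 0), c(5, 0, 300)), 300,
               tolerance = 0.03 * 300)
  expect_equal(geodesicPathLength(cyl, c(5, 0, 150), c(5, 0, 150)), 0)

  sp <- sphereMesh(radius = 10, subdiv = 3)
  set.seed(13)
  for (i in 1:5) {
    p <- runif(3, -1, 1); p <- 10 * p / sqrt(sum(p^2))
    q <- runif(3, -1, 1); q <- 10 * q / sqrt(sum(q^2))
    g <- geodesicPathLength(sp, p, q)
    expect_gte(g + 1e-9, sqrt(sum((p - q)^2)) * 0.999)
    # and no longer than a great-circle bound with discretization slack
    expect_lte(g, pi * 10 * 1.05)
  }

  # disconnected components refuse a path
  two <- makeMesh(rbind(meshVertices(sp), meshVertices(sp) + 100),
                  rbind(meshFaces(sp), meshFaces(sp) + nrow(meshVertices(sp))),
                  "t")
  expect_error(geodesicPathLength(two, c(0, 0, 10), c(100, 100, 110)),
               "different components")
})

test_that("component filtering and decimation commute on separated components", {
  big <- sphereMesh(radius = 40, subdiv = 3)
  small <- sphereMesh(radius = 1, center = c(90, 0, 0), subdiv = 1)
  both <- makeMesh(rbind(meshVertices(big), meshVertices(small)),
                   rbind(meshFaces(big), meshFaces(small) + nrow(meshVertices(big))),
                   "t")
  a <- quadricDecimate(removeSmallComponents(both, 0.05), 0.5)
  b <- removeSmallComponents(quadricDecimate(both, 0.5), 0.05)
  compSizes <- function(m) sort(table(splenvas:::meshComponentIds(m)))
  expect_equal(length(compSizes(a)), 1)
  expect_equal(length(compSizes(b)), 1)
  expect_equal(abs(meshVolume(a) / meshVolume(b) - 1), 0, tolerance = 0.05)
})
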