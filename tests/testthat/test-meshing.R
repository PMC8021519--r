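test_that("iso-surfacing handles degenerate inputs and iso bounds", {
  v <- new("ChannelVolume", values = array(0, c(8, 8, 8)),
           spacingUm = c(1, 1, 1), originUm = c(0, 0, 0),
           channel = "t", provenance = "raw")
  expect_equal(nrow(meshFaces(isosurface(v, 100))), 0)
  expect_error(isosurface(v, 0), "iso")
  expect_error(isosurface(v, 255), "iso")
})

test_that("partial-volume digitized balls mesh to analytic area and volume", {
  m <- isosurface(ballVolume(binary = FALSE), 100)
  expect_true(isClosedMesh(m))
  expect_lt(abs(meshArea(m) / (4 * pi * 400) - 1), 0.05)
  expect_lt(abs(meshVolume(m) / (4 / 3 * pi * 8000) - 1), 0.05)
})

test_that("binary balls mesh closed with accurate volume and known area bias", {
  m <- isosurface(ballVolume(binary = TRUE), 100)
  expect_true(isClosedMesh(m))
  expect_lt(abs(meshVolume(m) / (4 / 3 * pi * 8000) - 1), 0.05)
  # staircase metrication bias of binary-input marching cubes: the surface
  # area runs ~8-10% above the smooth sphere; pin the known behavior
  ratio <- meshArea(m) / (4 * pi * 400)
  expect_gt(ratio, 1.03)
  expect_lt(ratio, 1.15)
})

test_that("thresholding before meshing leaves the topology unchanged", {
  set.seed(11)
  arr <- array(0, c(20, 20, 20))
  arr[5:16, 5:16, 5:16] <- runif(12^3) * 255
  v <- new("ChannelVolume", values = arr, spacingUm = c(1, 1, 1),
           originUm = c(0, 0, 0), channel = "t", provenance = "raw")
  thr <- arr
  thr[] <- ifelse(arr >= 100, 255, 0)
  vt <- v; vt@values <- thr
  mA <- isosurface(v, 100)
  mB <- isosurface(vt, 100)
  euler <- function(m) {
    e <- rbind(m@faces[, 1:2], m@faces[, 2:3], m@faces[, c(1, 3)])
    e <- unique(t(apply(e, 1, sort)))
    nrow(m@vertices) - nrow(e) + nrow(m@faces)
  }
  expect_equal(euler(mA), euler(mB))
})

test_that("boundary-cut structures are capped by the zero-padding rule", {
  arr <- array(0, c(12, 12, 12))
  arr[5:8, 5:8, ] <- 255   # tube through the whole z extent
  v <- new("ChannelVolume", values = arr, spacingUm = c(1, 1, 1),
           originUm = c(0, 0, 0), channel = "t", provenance = "raw")
  expect_true(isClosedMesh(isosurface(v, 100)))
  open <- isosurface(v, 100, padBoundary = FALSE)
  expect_gt(meshEdgeAudit(open)["open"], 0)
})

test_that("watertight repair closes meshes within the Hausdorff bound", {
  sp <- sphereMesh(radius = 12, center = c(20, 20, 20))
  for (depth in c(7, 8)) {
    rep <- repairWatertight(sp, depth)
    expect_true(isClosedMesh(rep))
    cell <- (2 * 12) / (2^depth - 4)
    expect_lt(hausdorffDistance(rep, sp), 2 * cell)
  }
  # higher depth achieves at most the coarse depth's error
  e6 <- hausdorffDistance(repairWatertight(sp, 6), sp)
  e8 <- hausdorffDistance(repairWatertight(sp, 8), sp)
  expect_lte(e8, e6)
  expect_error(repairWatertight(sp, 3), "octreeDepth")
})

test_that("open cylinders come back closed from repair", {
  cyl <- openCylinderMesh()
  expect_gt(meshEdgeAudit(cyl)["open"], 0)
  rep <- repairWatertight(cyl, 7)
  expect_true(isClosedMesh(rep))
  # shape preserved within a couple of cells
  cell <- 40 / (2^7 - 4)
  expect_lt(hausdorffDistance(rep, cyl), 3 * cell)
})

test_that("empty meshes pass through repair unchanged", {
  em <- splenvas:::emptyMesh("t")
  expect_identical(repairWatertight(em, 8), em)
})
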