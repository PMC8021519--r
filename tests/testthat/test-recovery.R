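# build meshes straight from ground-truth occupancy (no imaging), the
# perfect-data limit of the reconstruction
gtMeshes <- function(gt, spacing = c(0.7, 0.7, 1.4)) {
  occ <- voxelizeGroundTruth(gt, spacing, soft = TRUE)
  mk <- function(a, ch) {
    v <- new("ChannelVolume", values = a * 255, spacingUm = spacing,
             originUm = c(0, 0, 0), channel = ch, provenance = "raw")
    isosurface(v, 127)
  }
  list(CD34 = mk(occ$CD34, "CD34"), CD271 = mk(occ$CD271, "CD271"),
       SMA = mk(occ$SMA, "SMA"), CD20 = mk(occ$CD20, "CD20"))
}

test_that("perfect-data recovery detects every structure", {
  gt <- buildPhantom(phantomSpec(seed = 21L))
  rep <- recoverTopology(gtMeshes(gt), gt, toleranceUm = 4)
  expect_equal(rep@sheathDetectionRate, 1)
  expect_equal(rep@sideBranchDetectionRate, 1)
  expect_equal(rep@bypassCount, rep@bypassTruth)
  expect_equal(rep@bypassTruth, 3L)
  expect_equal(rep@venuleContactCount, rep@venuleContactTruth)
  expect_gt(rep@geodesicUm$truth, 300)
  expect_lt(abs(rep@geodesicUm$measured / rep@geodesicUm$truth - 1), 0.05)
})

test_that("missing meshes drive detection to zero, not to errors", {
  gt <- buildPhantom(tinySpec(seed = 22L))
  m <- gtMeshes(gt)
  m$CD271 <- splenvas:::emptyMesh("CD271")
  rep <- recoverTopology(m, gt, toleranceUm = 4)
  expect_equal(rep@sheathDetectionRate, 0)
  expect_equal(rep@sideBranchDetectionRate, 1)  # CD34 intact
})

test_that("detection degrades monotonically with pixel noise", {
  # render-unmix-mesh without registration (no jitter) at raising noise;
  # sheath detection against a high tolerance exposes the degradation
  rateAt <- function(noise) {
    spec <- phantomSpec(domainSizeUm = c(80, 80, 112), nArterioles = 1L,
                        branchesPerArteriole = c(1L, 1L),
                        sheathBifurcationDepth = c(2L, 2L),
                        nBypassCapillaries = 0L, nVenuleContacts = 0L,
                        bcellDensity = 0, noiseSd = noise,
                        jitterTranslationPx = 0, jitterRotationDeg = 0,
                        seed = 30L)
    gt <- buildPhantom(spec)
    sm <- stainModel()
    stack <- renderSections(gt, sm, spec)
    vols <- unmixStack(stack, sm)
    red <- flowInterpolateZ(vols$CD271, 7)
    m <- isosurface(filterChannelVolume(red, "CD271"), 160)
    rep <- recoverTopology(list(CD34 = splenvas:::emptyMesh("CD34"),
                                CD271 = m), gt, toleranceUm = 2)
    rep@sheathDetectionRate
  }
  rates <- vapply(c(0, 40, 120), rateAt, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("the reference geodesic exceeds 300 um by construction", {
  for (seed in c(2L, 3L)) {
    gt <- buildPhantom(phantomSpec(seed = seed))
    ref <- heroReferenceGeodesic(gt)
    expect_gt(ref$geodesicUm, 300)
    expect_gt(ref$centerlineUm, ref$geodesicUm)  # inner-riding shortening
  }
})
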