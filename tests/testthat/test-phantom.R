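test_that("phantom spec validation rejects impossible geometry", {
  expect_error(phantomSpec(sheathBifurcationDepth = c(1L, 5L)), "exceed 4")
  expect_error(phantomSpec(pixelSizeUm = 0), "positive")
  expect_error(phantomSpec(radiiUm = c(stem = -1, branch = 4.5, sheathed = 3.5,
                                       side = 2, network = 3, bypass = 2.5,
                                       venule = 10, sheathInner = 4.5,
                                       sheathOuter = 10, bcell = 3.5)),
               "positive")
  expect_error(buildPhantom(phantomSpec(domainSizeUm = c(30, 30, 336))),
               "infeasible")
})

test_that("empty phantom yields an empty graph", {
  gt <- buildPhantom(phantomSpec(nArterioles = 0L, nVenuleContacts = 0L,
                                 bcellDensity = 0))
  expect_equal(nrow(gtNodes(gt)), 0)
  expect_equal(nrow(gtEdges(gt)), 0)
  expect_length(gt@sheaths, 0)
  expect_equal(nrow(gt@bcells), 0)
})

test_that("a forced unbranched arteriole is one straight 200 um tube", {
  gt <- buildPhantom(phantomSpec(nArterioles = 1L,
                                 branchesPerArteriole = c(0L, 0L),
                                 nBypassCapillaries = 0L, nVenuleContacts = 0L,
                                 bcellDensity = 0, stemLengthUm = 200))
  expect_equal(nrow(gtNodes(gt)), 2)
  expect_equal(nrow(gtEdges(gt)), 1)
  len <- sqrt(sum((gtNodes(gt)[2, ] - gtNodes(gt)[1, ])^2))
  expect_equal(len, 200)
})

test_that("structure-class counts match an independent graph walk", {
  for (seed in c(1:20, 101:120)) {
    gt <- buildPhantom(phantomSpec(seed = as.integer(seed)))
    tal <- tallyGroundTruth(gt)
    e <- gtEdges(gt)
    # recount directly from the edge table
    expect_identical(tal$edgesByClass, as.list(table(e$class)), info = seed)
    expect_equal(tal$nBypassEdges, sum(e$class == "bypass_capillary"))
    expect_equal(tal$nVenuleContacts, 2)
    expect_equal(tal$nSheaths, length(gt@sheaths))
    # spec ranges respected
    expect_true(all(vapply(gt@sheaths, function(s) s$nBifurcations, numeric(1))
                    %in% 1:4))
  }
})

test_that("phantom build is deterministic for a fixed seed", {
  a <- buildPhantom(phantomSpec(seed = 42L))
  b <- buildPhantom(phantomSpec(seed = 42L))
  expect_identical(gtNodes(a), gtNodes(b))
  expect_identical(gtEdges(a), gtEdges(b))
})

test_that("open side branches end free near their sheath surface", {
  for (seed in c(3L, 9L)) {
    gt <- buildPhantom(phantomSpec(seed = seed))
    e <- gtEdges(gt)
    deg <- tabulate(c(e$from, e$to), nbins = nrow(gtNodes(gt)))
    sb <- which(e$class == "side_branch_open")
    expect_gt(length(sb), 0)
    for (ei in sb) {
      tip <- if (deg[e$to[ei]] == 1) e$to[ei] else e$from[ei]
      expect_equal(deg[tip], 1)
      s <- gt@sheaths[[e$sheath[ei]]]
      # distance from tip to the covered centerline within outer radius + one
      # capillary radius
      dmin <- Inf
      for (mi in s$edges) {
        dmin <- min(dmin, sqrt(splenvas:::pointSegD2(
          gtNodes(gt)[tip, ], gtNodes(gt)[e$from[mi], ], gtNodes(gt)[e$to[mi], ])))
      }
      expect_lte(dmin, s$outerRadiusUm + e$radiusUm[ei] + 1e-6)
    }
  }
})

test_that("voxelized spheres and capsules match analytic volumes", {
  gt0 <- buildPhantom(phantomSpec(nArterioles = 0L, nVenuleContacts = 0L,
                                  bcellDensity = 0))
  vox <- voxelizeGroundTruth(gt0, c(1, 1, 1), extentUm = c(40, 40, 40))
  expect_true(all(vapply(vox, function(v) all(v == 0), logical(1))))

  blank <- array(0, c(80, 80, 80))
  # sphere radius 8 at fine spacing
  seg <- matrix(c(20, 20, 20, 20, 20, 20, 8), 1)
  occ <- splenvas:::cpp_rasterize_capsules(blank, seg, c(0.5, 0.5, 0.5),
                                           c(0, 0, 0), FALSE)
  expect_lt(abs(sum(occ) * 0.125 - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.1)
  # capsule radius 4, length 20
  seg <- matrix(c(10, 20, 20, 30, 20, 20, 4), 1)
  occ <- splenvas:::cpp_rasterize_capsules(blank, seg, c(0.5, 0.5, 0.5),
                                           c(0, 0, 0), FALSE)
  ana <- pi * 16 * 20 + 4 / 3 * pi * 64
  expect_lt(abs(sum(occ) * 0.125 - ana) / ana, 0.1)
})

test_that("voxelization warns when spacing is coarser than the radii", {
  gt <- buildPhantom(tinySpec())
  expect_warning(voxelizeGroundTruth(gt, c(4, 4, 4)), "coarser")
})

test_that("rendering an empty phantom gives pure background", {
  spec <- phantomSpec(domainSizeUm = c(24, 24, 21), nArterioles = 0L,
                      nVenuleContacts = 0L, bcellDensity = 0, noiseSd = 0,
                      jitterTranslationPx = 0, jitterRotationDeg = 0)
  stack <- renderSections(buildPhantom(spec), stainModel(), spec)
  for (s in sections(stack)) expect_equal(max(abs(sectionPixels(s) - 255)), 0)
})

test_that("rendered colors follow the Beer-Lambert forward model", {
  sm <- stainModel()
  A <- c(0, 0.6, 0)  # pure blue column density
  rgb <- splenvas:::beerLambertRgb(matrix(A, 1), odMatrix(sm))
  expect_equal(as.numeric(rgb),
               unname(256 * 10^(-0.6 * odMatrix(sm)[2, ]) - 1),
               tolerance = 1e-12)
})

test_that("no-jitter renders coincide with voxelized ground truth", {
  spec <- tinySpec(noiseSd = 0, jitterTranslationPx = 0, jitterRotationDeg = 0,
                   seed = 4L)
  gt <- buildPhantom(spec)
  stack <- renderSections(gt, stainModel(), spec)
  occ <- suppressWarnings(
    voxelizeGroundTruth(gt, c(0.5, 0.5, spec@sectionThicknessUm)))
  # CD34 support: dark pixels where the slab contains vessel, background 255
  k <- 5
  img <- sectionPixels(sections(stack)[[k]])
  stained <- img[, , 2] < 250  # any stain darkens green
  gtsup <- occ$CD34[, , k] > 0.5 | occ$SMA[, , k] > 0.5
  inter <- sum(stained & gtsup)
  expect_gt(inter / sum(gtsup), 0.9)
})

test_that("section alternation carries CD271 on even and CD20 on odd indices", {
  spec <- tinySpec(seed = 2L)
  stack <- renderSections(buildPhantom(spec), stainModel(), spec)
  for (s in sections(stack)) {
    expect_true(all(c("SMA", "CD34") %in% s@stainSet))
    expect_equal("CD271" %in% s@stainSet, s@sectionIndex %% 2 == 0)
    expect_equal("CD20" %in% s@stainSet, s@sectionIndex %% 2 == 1)
  }
})

test_that("section artifacts remove lost sections and blur defocused ones", {
  spec <- tinySpec(seed = 3L)
  stack <- renderSections(buildPhantom(spec), stainModel(), spec)
  n <- length(sections(stack))

  expect_error(applySectionArtifacts(stack, lostSectionIndices = 999L),
               "out of range")
  same <- applySectionArtifacts(stack)
  expect_equal(length(sections(same)), n)
  expect_equal(sectionPixels(sections(same)[[2]]),
               sectionPixels(sections(stack)[[2]]))

  out <- applySectionArtifacts(stack, lostSectionIndices = c(3L, 7L),
                               defocusIndices = 5L, defocusSigma = 3)
  expect_equal(length(sections(out)), n - 2)
  expect_equal(out@lostSections, c(3L, 7L))
  idx <- vapply(sections(out), function(s) s@sectionIndex, integer(1))
  expect_false(any(c(3L, 7L) %in% idx))
  # z preserved for survivors
  expect_equal(vapply(sections(out), function(s) s@zUm, numeric(1)),
               idx * spec@sectionThicknessUm)

  # defocused section loses high-frequency energy relative to neighbors
  hf <- function(img) {
    g <- img[, , 2]
    sp <- Mod(stats::fft(g))^2
    n2 <- nrow(g)
    sum(sp[(n2 / 4):(3 * n2 / 4), (n2 / 4):(3 * n2 / 4)])
  }
  blurred <- sections(out)[[which(idx == 5L)]]
  expect_false(blurred@focusOk)
  expect_lt(hf(sectionPixels(blurred)),
            hf(sectionPixels(sections(out)[[which(idx == 4L)]])))
})
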