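test_that("background subtraction removes gray casts and guards black images", {
  px <- array(255, c(20, 20, 3))
  px[5:8, 5:8, ] <- 40
  out <- subtractBackground(px)
  expect_lte(max(abs(out - px)), 1)

  cast <- px * 0.9
  out <- subtractBackground(cast)
  expect_lte(abs(out[1, 1, 1] - 255), 1)

  # percentile 1 with a single pure-white pixel: exact white point
  px2 <- array(200, c(10, 10, 3))
  px2[1, 1, ] <- 255
  out2 <- subtractBackground(px2, percentile = 1)
  expect_equal(max(out2), 255)

  expect_error(subtractBackground(array(0, c(5, 5, 3))), "background")
})

test_that("color deconvolution inverts Beer-Lambert mixing exactly", {
  sm <- stainModel()
  M <- odMatrix(sm)
  # pure white
  white <- array(255, c(1, 1, 3))
  expect_equal(as.numeric(colorDeconvolve(white, sm)), c(0, 0, 0))
  # single blue stain at density 0.6
  px <- array(splenvas:::beerLambertRgb(matrix(c(0, 0.6, 0), 1), M), c(1, 1, 3))
  d <- as.numeric(colorDeconvolve(px, sm))
  expect_equal(d[2], 0.6, tolerance = 1e-9)
  expect_lt(max(abs(d[c(1, 3)])), 1e-6)
  # brown 0.3 + red 0.4 mix
  px <- array(splenvas:::beerLambertRgb(matrix(c(0.3, 0, 0.4), 1), M), c(1, 1, 3))
  d <- as.numeric(colorDeconvolve(px, sm, clip = FALSE))
  expect_equal(d, c(0.3, 0, 0.4), tolerance = 1e-9)
  # singular matrix fails
  bad <- M; bad[3, ] <- bad[1, ]
  expect_error(stainModel(odMatrix = bad), "singular")
})

test_that("deconvolution is linear in stain mixtures", {
  set.seed(6)
  sm <- stainModel()
  M <- odMatrix(sm)
  for (i in 1:20) {
    d1 <- runif(3, 0, 0.5) * c(1, 0, 0)
    d2 <- runif(3, 0, 0.5) * c(0, 1, 1)
    pxMix <- array(splenvas:::beerLambertRgb(matrix(d1 + d2, 1), M), c(1, 1, 3))
    rec <- as.numeric(colorDeconvolve(pxMix, sm, clip = FALSE))
    expect_equal(rec, d1 + d2, tolerance = 1e-9)
  }
})

test_that("channel intensities stretch, respect endpoints and stay monotone", {
  sm <- stainModel()
  z <- matrix(0, 4, 4)
  expect_true(all(channelToIntensity(z, "blue", sm) == 0))

  d <- matrix(c(0.8, 0.4, 0.1, 0), 2, 2)
  for (ch in c("blue", "brown", "red")) {
    v <- channelToIntensity(d, ch, sm)
    expect_equal(max(v), 255)  # stretch endpoint
    expect_equal(min(v), 0)
    # monotone: ordering of densities preserved
    expect_true(all(order(as.vector(d)) == order(as.vector(v))))
  }

  # two-pixel closed-form oracle for the blue channel
  M <- odMatrix(sm)
  d2 <- matrix(c(0.5, 0.25), 1, 2)
  raw <- 255 - 255 * 10^(-d2 * M[2, 2])  # negated green of the re-rendering
  expe <- (raw - min(raw)) / (max(raw) - min(raw)) * 255
  got <- channelToIntensity(d2, "blue", sm)
  expect_equal(as.numeric(got), as.numeric(expe), tolerance = 1e-9)

  # red channel equals the CMYK magenta formula
  d3 <- matrix(c(0.7, 0.2), 1, 2)
  rgb <- 255 * 10^(-outer(as.numeric(d3), M[3, ]))
  K <- 1 - apply(rgb, 1, max) / 255
  mag <- 255 * (1 - rgb[, 2] / 255 - K) / (1 - K)
  expe <- (mag - min(mag)) / (max(mag) - min(mag)) * 255
  expect_equal(as.numeric(channelToIntensity(d3, "red", sm)),
               as.numeric(expe), tolerance = 1e-9)
})

test_that("unmixed stacks recover ground-truth stain support", {
  spec <- tinySpec(noiseSd = 0, jitterTranslationPx = 0, jitterRotationDeg = 0,
                   seed = 6L)
  gt <- buildPhantom(spec)
  sm <- stainModel()
  stack <- renderSections(gt, sm, spec)
  vols <- unmixStack(stack, sm)

  expect_equal(channelLabel(vols$CD34), "CD34")
  expect_equal(spacingUm(vols$CD34)[3], 7)
  expect_equal(spacingUm(vols$CD271)[3], 14)
  expect_equal(spacingUm(vols$CD20)[3], 14)

  occ <- voxelizeGroundTruth(gt, c(0.5, 0.5, 1), soft = TRUE)
  slab <- function(vol, k, nsub = 7) {
    idx <- ((k - 1) * nsub + 1):(k * nsub)
    Reduce(`+`, lapply(idx, function(j) vol[, , j])) / nsub
  }
  jacc <- function(a, b) sum(a & b) / sum(a | b)
  # the 10%-of-max intensity contour corresponds to a slab occupancy of
  # about 0.06 under the configured stain amplitudes (monotone mapping)
  k <- 10
  sup <- volArray(vols$CD34)[, , k] > 0.1 * max(volArray(vols$CD34))
  gtp <- slab(occ$CD34, k) > 0.06
  expect_gt(jacc(sup, gtp), 0.95)
  # CD271 lives on even 0-based sections: raw slice j covers section 2(j-1)
  j <- 5
  sup <- volArray(vols$CD271)[, , j] > 0.1 * max(volArray(vols$CD271))
  gtp <- slab(occ$CD271, 2 * (j - 1) + 1) > 0.06
  expect_gt(jacc(sup, gtp), 0.95)
})
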