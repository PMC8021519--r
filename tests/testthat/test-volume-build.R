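mkVol <- function(arr, spacing = c(0.5, 0.5, 7), channel = "CD34") {
  new("ChannelVolume", values = arr, spacingUm = spacing,
      originUm = c(0, 0, 0), channel = channel, provenance = "raw")
}

test_that("flow interpolation honors its slice-count and endpoint contract", {
  set.seed(7)
  v <- mkVol(array(runif(32 * 32 * 4) * 255, c(32, 32, 4)))
  expect_identical(flowInterpolateZ(v, 1), v)
  expect_error(flowInterpolateZ(v, 0), "factor")

  out <- flowInterpolateZ(v, 7)
  expect_equal(dim(volArray(out))[3], (4 - 1) * 7 + 1)
  expect_equal(spacingUm(out)[3], 1)
  for (k in 1:4)
    expect_identical(volArray(out)[, , (k - 1) * 7 + 1], volArray(v)[, , k])
  # world z of original slices preserved through the origin shift
  z0 <- originUm(v)[3] + (1:4 - 0.5) * 7
  z1 <- originUm(out)[3] + ((1:4 - 1) * 7 + 0.5) * 1
  expect_equal(z0, z1)
})

test_that("two identical slices interpolate to identical copies", {
  m <- matrix(runif(30 * 30) * 255, 30)
  v <- mkVol(array(c(m, m), c(30, 30, 2)))
  out <- volArray(flowInterpolateZ(v, 7))
  for (k in 1:8) expect_equal(out[, , k], m)
})

test_that("a translating disk moves linearly through interpolated slices", {
  mk <- function(cx) {
    m <- matrix(0, 96, 96)
    for (x in 1:96) for (y in 1:96)
      if ((x - cx)^2 + (y - 48)^2 <= 64) m[y, x] <- 200
    m
  }
  v <- mkVol(array(c(mk(40), mk(54)), c(96, 96, 2)))
  out <- volArray(flowInterpolateZ(v, 7))
  cents <- vapply(1:8, function(k) {
    m <- out[, , k]
    sum(col(m) * m) / sum(m)
  }, numeric(1))
  lin <- seq(cents[1], cents[8], length.out = 8)
  expect_lt(max(abs(cents - lin)), 1)
})

test_that("nearest-neighbor resize repeats slices without new values", {
  v <- mkVol(array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3)),
             spacing = c(0.5, 0.5, 14), channel = "CD20")
  expect_identical(nnResizeZ(v, 1), v)
  out <- nnResizeZ(v, 2)
  expect_equal(dim(volArray(out))[3], 6)
  for (k in 1:3) {
    expect_identical(volArray(out)[, , 2 * k - 1], volArray(v)[, , k])
    expect_identical(volArray(out)[, , 2 * k], volArray(v)[, , k])
  }
  expect_true(all(volArray(out) %in% volArray(v)))
  # histogram scales by the factor
  expect_equal(as.vector(table(volArray(out))),
               2 * as.vector(table(volArray(v))))
})

test_that("constant volumes are fixed points of every channel recipe", {
  v <- mkVol(array(120, c(20, 20, 20)), spacing = c(1, 1, 1))
  for (ch in c("CD34", "SMA", "CD271", "CD20")) {
    out <- filterChannelVolume(v, ch)
    expect_equal(volArray(out), volArray(v), tolerance = 1e-9)
  }
  expect_error(filterChannelVolume(v, "CD99"), "unknown")
})

test_that("the CD20 channel passes through bit-identically", {
  set.seed(8)
  v <- mkVol(array(runif(15^3) * 255, c(15, 15, 15)), channel = "CD20")
  expect_identical(volArray(filterChannelVolume(v)), volArray(v))
})

test_that("single-voxel dilation support matches the digital ellipsoid", {
  v <- array(0, c(33, 33, 33))
  v[17, 17, 17] <- 255
  out <- splenvas:::cpp_morph3d(v, 8, 8, 2, TRUE)
  idx <- which(out > 0, arr.ind = TRUE)
  off <- sweep(idx, 2, c(17, 17, 17))
  inside <- (off[, 1] / 8)^2 + (off[, 2] / 8)^2 + (off[, 3] / 2)^2 <= 1
  expect_true(all(inside))
  # every ellipsoid offset is reached
  expect_equal(nrow(idx), sum(outer(outer((-8:8 / 8)^2, (-8:8 / 8)^2, "+"),
                                    (-2:2 / 2)^2, "+") <= 1))
  # closing adds nothing to this convex blob
  closed <- splenvas:::cpp_morph3d(out, 8, 8, 2, FALSE)
  reopened <- splenvas:::cpp_morph3d(closed, 8, 8, 2, TRUE)
  expect_equal(sum(splenvas:::cpp_morph3d(reopened, 8, 8, 2, FALSE) > 0),
               sum(closed > 0))
})

test_that("grayscale morphology is monotone and dilation extensive", {
  set.seed(9)
  for (i in 1:5) {
    a <- array(runif(11^3) * 255, c(11, 11, 11))
    b <- a + array(runif(11^3) * 50, c(11, 11, 11))
    r <- sample(1:3, 3, TRUE)
    da <- splenvas:::cpp_morph3d(a, r[1], r[2], r[3], TRUE)
    db <- splenvas:::cpp_morph3d(b, r[1], r[2], r[3], TRUE)
    expect_true(all(da >= a))           # extensive
    expect_true(all(db >= da - 1e-12))  # monotone
    # agreement with the brute-force oracle
    expect_equal(da, splenvas:::cpp_morph3d_brute(a, r[1], r[2], r[3], TRUE))
    ea <- splenvas:::cpp_morph3d(a, r[1], r[2], r[3], FALSE)
    expect_equal(ea, splenvas:::cpp_morph3d_brute(a, r[1], r[2], r[3], FALSE))
    expect_true(all(ea <= a))
  }
})

test_that("volume crop keeps world coordinates consistent", {
  set.seed(10)
  v <- mkVol(array(runif(40 * 40 * 3), c(40, 40, 3)))
  out <- cropVolumeXy(v, 20)
  expect_equal(dim(volArray(out))[1:2], c(20, 20))
  expect_equal(originUm(out)[1:2], c(10 * 0.5, 10 * 0.5))
  expect_identical(volArray(out)[1, 1, 1], volArray(v)[11, 11, 1])
  expect_error(cropVolumeXy(v, 50), "crop larger")
})
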