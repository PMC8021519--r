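mkSection <- function(px) {
  new("SectionImage", pixels = px, pixelSizeUm = 0.5, sectionIndex = 0L,
      zUm = 0, stainSet = c("SMA", "CD34", "CD271"), focusOk = TRUE)
}

test_that("reinhard normalization is a fixed point on matching statistics", {
  set.seed(1)
  px <- array(runif(32 * 32 * 3, 60, 220), c(32, 32, 3))
  img <- mkSection(px)
  ref <- labStats(img)
  out <- reinhardNormalize(img, ref)
  expect_lte(max(abs(sectionPixels(out) - px)), 1)
})

test_that("constant images map to the reference means", {
  img <- mkSection(array(128, c(16, 16, 3)))
  ref <- list(mean = c(1.5, 0.02, -0.01), sd = c(0.2, 0.05, 0.05))
  out <- reinhardNormalize(img, ref)
  st <- labStats(out)
  expect_equal(unname(st$mean), ref$mean, tolerance = 0.02)
  # constant in, constant out
  expect_lt(max(apply(sectionPixels(out), 3, sd)), 1e-8)
})

test_that("normalization transfers two-tone statistics exactly", {
  px <- array(0, c(20, 20, 3))
  px[, 1:10, 1] <- 150; px[, 1:10, 2] <- 90; px[, 1:10, 3] <- 60
  px[, 11:20, 1] <- 80; px[, 11:20, 2] <- 180; px[, 11:20, 3] <- 210
  img <- mkSection(px)
  ref <- list(mean = c(1.8, 0.05, 0.02), sd = c(0.3, 0.04, 0.03))
  out <- reinhardNormalize(img, ref)
  st <- labStats(out)
  # recomputed stats match the reference (after one 8-bit-free round trip the
  # only error is the RGB clip, negligible here)
  expect_equal(unname(st$mean), ref$mean, tolerance = 1e-3)
  expect_equal(unname(st$sd), ref$sd, tolerance = 1e-3)
})

test_that("normalization is idempotent up to rounding", {
  set.seed(2)
  px <- array(runif(24 * 24 * 3, 40, 240), c(24, 24, 3))
  img <- mkSection(px)
  ref <- list(mean = c(1.9, 0.03, 0.01), sd = c(0.25, 0.05, 0.04))
  once <- reinhardNormalize(img, ref)
  twice <- reinhardNormalize(once, ref)
  expect_lte(max(abs(sectionPixels(twice) - sectionPixels(once))), 1)
})

test_that("registration channel isolates the blue stain", {
  sm <- stainModel()
  # background-only image
  bg <- mkSection(array(255, c(40, 40, 3)))
  ch <- extractRegistrationChannel(bg, sm)
  expect_lt(max(abs(ch)), 0.02)

  # one blue disk and one brown disk
  den <- array(0, c(64, 64, 3))
  for (x in 1:64) for (y in 1:64) {
    if ((x - 18)^2 + (y - 32)^2 <= 36) den[y, x, 2] <- 0.8  # blue
    if ((x - 46)^2 + (y - 32)^2 <= 36) den[y, x, 1] <- 0.8  # brown
  }
  rgb <- splenvas:::beerLambertRgb(matrix(den, ncol = 3), odMatrix(sm))
  img <- mkSection(array(rgb, c(64, 64, 3)))
  ch <- extractRegistrationChannel(img, sm, sigma = 6)
  expect_gt(ch[32, 18], 10 * ch[32, 46])

  # sigma 0 returns the raw deconvolved blue density
  ch0 <- extractRegistrationChannel(img, sm, sigma = 0)
  expect_equal(ch0, colorDeconvolve(img, sm)[, , 2])
})

test_that("a stack of identical images registers to the identity", {
  set.seed(3)
  base <- matrix(0, 128, 128)
  pts <- cbind(runif(25, 20, 108), runif(25, 20, 108))
  for (p in seq_len(nrow(pts)))
    base[round(pts[p, 2]) + (-1:1), round(pts[p, 1]) + (-1:1)] <- 1
  dim(base) <- c(128, 128, 1)
  base <- splenvas:::cpp_gauss3d(base, c(6, 6, 0))
  dim(base) <- c(128, 128)
  al <- registerStack(replicate(8, base, simplify = FALSE), seed = 1)
  tr <- alignmentTransforms(al)
  expect_lt(max(abs(tr$tx)), 1e-3)
  expect_lt(max(abs(tr$ty)), 1e-3)
  expect_lt(max(abs(tr$theta)) * 64, 1e-3)
})

test_that("known rigid warps are recovered and compose consistently", {
  set.seed(4)
  base <- matrix(0, 160, 160)
  pts <- cbind(runif(40, 25, 135), runif(40, 25, 135))
  for (p in seq_len(nrow(pts)))
    base[round(pts[p, 2]) + (-1:1), round(pts[p, 1]) + (-1:1)] <- 1
  dim(base) <- c(160, 160, 1)
  base <- splenvas:::cpp_gauss3d(base, c(6, 6, 0))
  dim(base) <- c(160, 160)
  jit <- data.frame(theta = runif(6, -0.02, 0.02), tx = runif(6, -8, 8),
                    ty = runif(6, -8, 8))
  chans <- lapply(1:6, function(k)
    splenvas:::cpp_warp_rigid(base, jit$theta[k], jit$tx[k], jit$ty[k], 0))
  al <- registerStack(chans, seed = 1)
  ri <- al@referenceIndex
  tr <- alignmentTransforms(al)
  P <- cbind(runif(100, -60, 60), runif(100, -60, 60))
  for (k in 1:6) {
    inv <- splenvas:::rigid_invert(jit$theta[k], c(jit$tx[k], jit$ty[k]))
    ex <- splenvas:::rigid_compose(jit$theta[ri], c(jit$tx[ri], jit$ty[ri]),
                                   inv$theta, inv$t)
    a <- splenvas:::rigid_apply(P, ex$theta, ex$t, c(0, 0))
    b <- splenvas:::rigid_apply(P, tr$theta[k], c(tr$tx[k], tr$ty[k]), c(0, 0))
    expect_lt(sqrt(mean(rowSums((a - b)^2))), 0.25)
  }
  # composition: relative transform 1->3 equals (1->2) o (2->3)
  rel <- function(i, j) {
    inv <- splenvas:::rigid_invert(tr$theta[j], c(tr$tx[j], tr$ty[j]))
    splenvas:::rigid_compose(inv$theta, inv$t, tr$theta[i], c(tr$tx[i], tr$ty[i]))
  }
  r13 <- rel(1, 3)
  r12 <- rel(1, 2); r23 <- rel(2, 3)
  comp <- splenvas:::rigid_compose(r23$theta, r23$t, r12$theta, r12$t)
  expect_equal(r13$theta, comp$theta, tolerance = 1e-3)
  expect_equal(r13$t, comp$t, tolerance = 0.3)
})

test_that("registration is gauge invariant under a common rigid shift", {
  set.seed(5)
  base <- matrix(0, 128, 128)
  pts <- cbind(runif(30, 25, 103), runif(30, 25, 103))
  for (p in seq_len(nrow(pts)))
    base[round(pts[p, 2]) + (-1:1), round(pts[p, 1]) + (-1:1)] <- 1
  dim(base) <- c(128, 128, 1)
  base <- splenvas:::cpp_gauss3d(base, c(6, 6, 0))
  dim(base) <- c(128, 128)
  jit <- data.frame(theta = runif(5, -0.02, 0.02), tx = runif(5, -5, 5),
                    ty = runif(5, -5, 5))
  chans <- lapply(1:5, function(k)
    splenvas:::cpp_warp_rigid(base, jit$theta[k], jit$tx[k], jit$ty[k], 0))
  chansShift <- lapply(chans, function(ch)
    splenvas:::cpp_warp_rigid(ch, 0, 4, -3, 0))
  alA <- registerStack(chans, seed = 1)
  alB <- registerStack(chansShift, seed = 1)
  # relative transforms between sections are unchanged by a common shift
  relOf <- function(al, i, j) {
    tr <- alignmentTransforms(al)
    inv <- splenvas:::rigid_invert(tr$theta[j], c(tr$tx[j], tr$ty[j]))
    splenvas:::rigid_compose(inv$theta, inv$t, tr$theta[i],
                             c(tr$tx[i], tr$ty[i]))
  }
  for (i in c(1, 2, 4)) {
    ra <- relOf(alA, i, 3)
    rb <- relOf(alB, i, 3)
    expect_equal(ra$theta, rb$theta, tolerance = 2e-3)
    expect_equal(ra$t, rb$t, tolerance = 0.35)
  }
})

test_that("registration fails loudly without features or matches", {
  flat <- matrix(0, 64, 64)
  expect_error(registerStack(list(flat, flat), seed = 1), "features")
  expect_error(registerStack(list(flat), seed = 1), "at least two")
})

test_that("alignment application moves structures as prescribed and crops", {
  px <- array(255, c(64, 64, 3))
  px[29:35, 29:35, ] <- 0
  stack <- new("SectionStack",
               sections = list(new("SectionImage", pixels = px,
                                   pixelSizeUm = 0.5, sectionIndex = 0L,
                                   zUm = 0, stainSet = "CD34", focusOk = TRUE)),
               thicknessUm = 7, jitter = data.frame(), lostSections = integer(0),
               meta = list())
  idal <- new("StackAlignment",
              transforms = data.frame(theta = 0, tx = 0, ty = 0),
              referenceIndex = 1L, residuals = data.frame())
  out <- applyAlignment(stack, idal)
  expect_equal(sectionPixels(sections(out)[[1]]), px)

  # translation by (5, 0): structure centroid moves by +5 in x (the transform
  # maps raw into the common frame)
  tral <- new("StackAlignment",
              transforms = data.frame(theta = 0, tx = 0, ty = 0),
              referenceIndex = 1L, residuals = data.frame())
  tral@transforms <- data.frame(theta = 0, tx = 5, ty = 0)
  # bypass validity gauge check by setting reference elsewhere
  tral@referenceIndex <- 1L
  tral@transforms[1, ] <- c(0, 5, 0)
  out2 <- stack
  img <- sectionPixels(sections(stack)[[1]])[, , 1]
  warped <- splenvas:::cpp_warp_rigid(img, 0, 5, 0, 255)
  cen <- function(m) {
    w <- 255 - m
    c(sum(col(m) * w), sum(row(m) * w)) / sum(w)
  }
  expect_equal(cen(warped)[1] - cen(img)[1], 5, tolerance = 0.2)
  expect_equal(cen(warped)[2] - cen(img)[2], 0, tolerance = 0.2)

  # central crop
  cropped <- applyAlignment(stack, idal, cropPx = 48)
  expect_equal(dim(sectionPixels(sections(cropped)[[1]])), c(48, 48, 3))
  expect_error(applyAlignment(stack, idal, cropPx = 100), "crop larger")
})
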