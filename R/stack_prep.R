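# Reinhard color normalization works in the perceptual l-alpha-beta space:
# RGB -> LMS cone space -> log10 -> decorrelated l-alpha-beta.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lab_a <- matrix(c(1 / sqrt(3), 0, 0,
                   0, 1 / sqrt(6), 0,
                   0, 0, 1 / sqrt(2)), 3, 3, byrow = TRUE) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)

rgbToLab <- function(px) {
  lms <- px %*% t(.rgb2lms)
  lms[lms < 1e-4] <- 1e-4
  log10(lms) %*% t(.lab_a)
}

labToRgb <- function(lab) {
  lms <- 10^(lab %*% t(solve(.lab_a)))
  rgb <- lms %*% t(solve(.rgb2lms))
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  rgb
}

#' Per-channel statistics of an image in l-alpha-beta space
#'
#' @param image a \linkS4class{SectionImage}.
#' @return list with numeric vectors mean and sd (length 3).
#' @export
labStats <- function(image) {
  lab <- rgbToLab(matrix(image@pixels, ncol = 3))
  list(mean = colMeans(lab), sd = apply(lab, 2, stats::sd))
}

#' Reinhard color normalization to reference statistics
#'
#' Transfers per-channel mean and standard deviation in l-alpha-beta space:
#' x' = (x - mu_img) * sd_ref / sd_img + mu_ref, then converts back to RGB
#' and clips to 0..255.  A channel with zero spread in the image is set to
#' the reference mean (degenerate rule).
#'
#' @param image a \linkS4class{SectionImage}.
#' @param referenceStats list(mean, sd) as returned by \code{\link{labStats}}
#'   on the chosen standard image.
#' @return the normalized \linkS4class{SectionImage}.
#' @export
reinhardNormalize <- function(image, referenceStats) {
  stopifnot(all(is.finite(referenceStats$mean)),
            all(is.finite(referenceStats$sd)), all(referenceStats$sd > 0))
  d <- dim(image@pixels)
  lab <- rgbToLab(matrix(image@pixels, ncol = 3))
  mu <- colMeans(lab)
  sd <- apply(lab, 2, stats::sd)
  for (c in 1:3) {
    if (sd[c] < 1e-12) {
      lab[, c] <- referenceStats$mean[c]
    } else {
      lab[, c] <- (lab[, c] - mu[c]) * (referenceStats$sd[c] / sd[c]) +
        referenceStats$mean[c]
    }
  }
  out <- image
  out@pixels <- array(labToRgb(lab), d)
  out
}

#' Extract the blurred blue-stain registration channel
#'
#' Color-deconvolves the section with the configured stain matrix, keeps the
#' blue (CD34) density map, and blurs it with a Gaussian (default sigma 6
#' pixels).  The result guides transform estimation only; the recovered
#' transforms are later applied to the original unblurred images.
#'
#' @param image a \linkS4class{SectionImage}.
#' @param stain a \linkS4class{StainModel}.
#' @param sigma blur sigma in pixels; 0 skips the blur.
#' @return an H x W numeric matrix of blurred blue densities.
#' @export
extractRegistrationChannel <- function(image, stain, sigma = 6) {
  den <- colorDeconvolve(image@pixels, stain)
  blue <- den[, , 2]
  if (sigma > 0) {
    dim(blue) <- c(dim(blue), 1)
    blue <- cpp_gauss3d(blue, c(sigma, sigma, 0))
    dim(blue) <- dim(blue)[1:2]
  }
  blue
}

# detect blob features on a registration channel: local maxima of the
# (already blurred) density with subpixel quadratic refinement, plus a
# normalized patch descriptor
detectFeatures <- function(ch, maxFeatures = 400, patch = 10) {
  thr <- mean(ch) + 0.1 * stats::sd(ch)
  pts <- cpp_local_maxima(ch, 3, thr)
  if (nrow(pts) == 0) return(list(xy = matrix(0, 0, 2), desc = NULL))
  o <- order(pts[, 3], decreasing = TRUE)
  pts <- pts[o[seq_len(min(maxFeatures, nrow(pts)))], , drop = FALSE]
  H <- nrow(ch); W <- ncol(ch)
  # quadratic subpixel refinement along x and y (points are 0-based and at
  # least the detection radius away from the border)
  refine <- function(x, y) {
    f0 <- ch[y + 1, x + 1]
    fxm <- ch[y + 1, x]; fxp <- ch[y + 1, x + 2]
    fym <- ch[y, x + 1]; fyp <- ch[y + 2, x + 1]
    dx <- if (fxm - 2 * f0 + fxp < 0) 0.5 * (fxm - fxp) / (fxm - 2 * f0 + fxp) else 0
    dy <- if (fym - 2 * f0 + fyp < 0) 0.5 * (fym - fyp) / (fym - 2 * f0 + fyp) else 0
    c(x + max(-0.5, min(0.5, dx)), y + max(-0.5, min(0.5, dy)))
  }
  xy <- t(apply(pts[, 1:2, drop = FALSE], 1, function(p) refine(p[1], p[2])))
  keep <- xy[, 1] > patch & xy[, 1] < W - 1 - patch &
    xy[, 2] > patch & xy[, 2] < H - 1 - patch
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) == 0) return(list(xy = matrix(0, 0, 2), desc = NULL))
  off <- as.matrix(expand.grid(dx = -patch:patch, dy = -patch:patch))
  desc <- t(apply(xy, 1, function(p) {
    v <- ch[cbind(pmin(pmax(round(p[2] + off[, "dy"]), 0), H - 1) + 1,
                  pmin(pmax(round(p[1] + off[, "dx"]), 0), W - 1) + 1)]
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }))
  list(xy = xy, desc = desc)
}

# candidate matches under a position prior (serial sections cannot move far)
# with a loose appearance gate; the rigid consensus step picks the
# geometrically consistent subset out of these candidates
matchFeatures <- function(fa, fb, simMin = 0.6, maxDistPx = 45) {
  if (is.null(fa$desc) || is.null(fb$desc) ||
      nrow(fa$xy) < 3 || nrow(fb$xy) < 3)
    return(matrix(0L, 0, 2))
  sim <- fa$desc %*% t(fb$desc)
  d2 <- outer(rowSums(fa$xy^2), rowSums(fb$xy^2), "+") -
    2 * fa$xy %*% t(fb$xy)
  idx <- which(sim >= simMin & d2 <= maxDistPx^2, arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2)
}

# rigid 2-D Procrustes fit q ~ R p + t from point sets (n x 2)
fitRigid <- function(p, q) {
  mp <- colMeans(p); mq <- colMeans(q)
  pc <- sweep(p, 2, mp); qc <- sweep(q, 2, mq)
  s <- svd(t(pc) %*% qc)
  R <- s$v %*% diag(c(1, det(s$v %*% t(s$u)))) %*% t(s$u)
  list(theta = atan2(R[2, 1], R[1, 1]), t = as.numeric(mq - R %*% mp), R = R)
}

# RANSAC rigid pair estimation; returns inlier match indices + transform
ransacRigid <- function(p, q, tol = 3, iters = 500) {
  n <- nrow(p)
  if (n < 3) return(NULL)
  best <- NULL; bestIn <- 0
  for (it in seq_len(iters)) {
    i <- sample(n, 2)
    dp <- p[i[2], ] - p[i[1], ]; dq <- q[i[2], ] - q[i[1], ]
    if (sum(dp^2) < 25) next
    th <- atan2(dq[2], dq[1]) - atan2(dp[2], dp[1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t <- q[i[1], ] - as.numeric(R %*% p[i[1], ])
    res <- q - (p %*% t(R) + matrix(t, n, 2, byrow = TRUE))
    inl <- rowSums(res^2) < tol^2
    if (sum(inl) > bestIn) {
      bestIn <- sum(inl)
      best <- inl
    }
  }
  if (is.null(best) || bestIn < 3) return(NULL)
  fit <- fitRigid(p[best, , drop = FALSE], q[best, , drop = FALSE])
  res <- q - (p %*% t(fit$R) + matrix(fit$t, n, 2, byrow = TRUE))
  inl <- rowSums(res^2) < tol^2
  if (sum(inl) < 3) return(NULL)
  list(inliers = which(inl), fit = fitRigid(p[inl, , drop = FALSE],
                                            q[inl, , drop = FALSE]))
}

#' Sparse global registration of a section stack
#'
#' Detects blob features on each registration channel, matches every section
#' to its k nearest neighbors in z (ratio-test filtering, RANSAC rigid
#' consensus per pair), then jointly minimizes the Huber-weighted sum of
#' squared reprojection residuals of all retained matches over all
#' per-section rigid transforms (Gauss-Newton, reference section fixed to
#' the identity).  Coordinates are pixel units about the image center.
#'
#' @param channels list of registration-channel matrices
#'   (\code{\link{extractRegistrationChannel}} output).
#' @param k number of forward z-neighbors each section is matched against.
#' @param referenceIndex 1-based gauge-fixing section, default the middle.
#' @param maxFeatures feature budget per section.
#' @param seed seed for the RANSAC sampling.
#' @param minMatches minimum retained matches a section must have to any
#'   neighbor; failure names the offending section.
#' @param longRangeOffsets additional z offsets matched beyond the k nearest
#'   neighbors; structures persisting across many sections anchor the
#'   low-frequency drift that neighbor-only matching cannot constrain.
#' @return a \linkS4class{StackAlignment}.
#' @export
registerStack <- function(channels, k = 2, referenceIndex = NULL,
                          maxFeatures = 400, seed = 1, minMatches = 4,
                          longRangeOffsets = c(4L, 6L, 8L, 12L, 16L, 24L, 32L)) {
  n <- length(channels)
  if (n < 2) stop("need at least two sections to register")
  if (is.null(referenceIndex)) referenceIndex <- (n + 1) %/% 2
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  ctr <- c((W - 1) / 2, (H - 1) / 2)

  with_seed(seed, function() {
    feats <- lapply(channels, detectFeatures, maxFeatures = maxFeatures)
    nfeat <- vapply(feats, function(f) nrow(f$xy), integer(1))
    if (any(nfeat < 3))
      stop("no detectable features in section(s) ",
           paste(which(nfeat < 3), collapse = ", "))

    pairs <- list()
    for (i in seq_len(n)) {
      for (off in seq_len(k)) {
        j <- i + off
        if (j > n) next
        m <- matchFeatures(feats[[i]], feats[[j]])
        if (nrow(m) < 3) next
        p <- sweep(feats[[i]]$xy[m[, 1], , drop = FALSE], 2, ctr)
        q <- sweep(feats[[j]]$xy[m[, 2], , drop = FALSE], 2, ctr)
        rr <- ransacRigid(p, q)
        if (is.null(rr)) next
        pairs[[length(pairs) + 1]] <- list(
          i = i, j = j,
          p = p[rr$inliers, , drop = FALSE],
          q = q[rr$inliers, , drop = FALSE],
          fit = rr$fit)
      }
    }
    matched <- rep(0L, n)
    for (pr in pairs) {
      matched[pr$i] <- matched[pr$i] + nrow(pr$p)
      matched[pr$j] <- matched[pr$j] + nrow(pr$p)
    }
    if (any(matched < minMatches))
      stop("registration failure: section(s) ",
           paste(which(matched < minMatches), collapse = ", "),
           " have fewer than ", minMatches, " matches to any neighbor")

    # initialize by chaining adjacent pairwise fits outward from the reference
    theta <- numeric(n); tx <- numeric(n); ty <- numeric(n)
    adj <- vector("list", n)
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      if (pr$j == pr$i + 1) adj[[pr$i]] <- pr
    }
    if (referenceIndex < n) {
      for (i in referenceIndex:(n - 1)) {
        pr <- adj[[i]]
        if (is.null(pr)) next
        # fit maps section i coords -> section i+1 coords; alignment of i+1
        # is alignment of i composed with the inverse pair transform
        inv <- rigid_invert(pr$fit$theta, pr$fit$t)
        cmp <- rigid_compose(theta[i], c(tx[i], ty[i]), inv$theta, inv$t)
        theta[i + 1] <- cmp$theta; tx[i + 1] <- cmp$t[1]; ty[i + 1] <- cmp$t[2]
      }
    }
    if (referenceIndex > 1) {
      for (i in referenceIndex:2) {
        pr <- adj[[i - 1]]
        if (is.null(pr)) next
        cmp <- rigid_compose(theta[i], c(tx[i], ty[i]), pr$fit$theta, pr$fit$t)
        theta[i - 1] <- cmp$theta; tx[i - 1] <- cmp$t[1]; ty[i - 1] <- cmp$t[2]
      }
    }

    # global Gauss-Newton with Huber weights on all retained matches
    huber <- 3.0
    free <- setdiff(seq_len(n), referenceIndex)
    pidx <- function(i) {
      w <- match(i, free)
      if (is.na(w)) NULL else (3 * (w - 1) + 1):(3 * w)
    }
    solveGN <- function(pairs) for (iter in 1:12) {
      A <- matrix(0, 3 * (n - 1), 3 * (n - 1))
      b <- numeric(3 * (n - 1))
      for (pr in pairs) {
        i <- pr$i; j <- pr$j
        Ti <- rigid_apply(pr$p, theta[i], c(tx[i], ty[i]), c(0, 0))
        Tj <- rigid_apply(pr$q, theta[j], c(tx[j], ty[j]), c(0, 0))
        r <- Tj - Ti
        rn <- sqrt(rowSums(r^2))
        # redescending Tukey biweight: matches on drifting content (tubes
        # crossing the block obliquely move coherently between sections and
        # would bias a monotone M-estimator) lose all influence beyond c
        w <- ifelse(rn < huber, (1 - (rn / huber)^2)^2, 0)
        # Jacobians: d(T p)/dtheta = (-R p)_perp rotated; for small blocks
        # assemble per match
        Ji <- pidx(i); Jj <- pidx(j)
        cols <- c(Ji, Jj)
        for (m in seq_len(nrow(r))) {
          J <- matrix(0, 2, length(cols))
          off <- 0
          if (!is.null(Ji)) {
            dth <- c(-sin(theta[i]) * pr$p[m, 1] - cos(theta[i]) * pr$p[m, 2],
                     cos(theta[i]) * pr$p[m, 1] - sin(theta[i]) * pr$p[m, 2])
            J[, 1:3] <- -cbind(dth, diag(2))
            off <- 3
          }
          if (!is.null(Jj)) {
            dth <- c(-sin(theta[j]) * pr$q[m, 1] - cos(theta[j]) * pr$q[m, 2],
                     cos(theta[j]) * pr$q[m, 1] - sin(theta[j]) * pr$q[m, 2])
            J[, off + (1:3)] <- cbind(dth, diag(2))
          }
          A[cols, cols] <- A[cols, cols] + w[m] * crossprod(J)
          b[cols] <- b[cols] - w[m] * as.numeric(crossprod(J, r[m, ]))
        }
      }
      dx <- tryCatch(solve(A + 1e-9 * diag(nrow(A)), b),
                     error = function(e) rep(0, length(b)))
      for (i in free) {
        ix <- pidx(i)
        theta[i] <<- theta[i] + dx[ix[1]]
        tx[i] <<- tx[i] + dx[ix[2]]
        ty[i] <<- ty[i] + dx[ix[3]]
      }
      if (max(abs(dx)) < 1e-8) break
    }
    solveGN(pairs)

    # alignment-guided re-matching with a shrinking search radius: with the
    # current transforms, pair up mutual nearest features in the common
    # frame, now also across long z offsets (persistent structures such as
    # terminal arteries anchor the low-frequency drift that neighbor-only
    # matching cannot constrain), then re-solve
    offsets <- sort(unique(c(seq_len(k), longRangeOffsets)))
    offsets <- offsets[offsets < n]
    for (radius in c(15, 8, 5, 3, 2, 1.5)) {
      pairs2 <- list()
      for (i in seq_len(n)) {
        for (off in offsets) {
          j <- i + off
          if (j > n) next
          pa <- rigid_apply(sweep(feats[[i]]$xy, 2, ctr), theta[i],
                            c(tx[i], ty[i]), c(0, 0))
          pb <- rigid_apply(sweep(feats[[j]]$xy, 2, ctr), theta[j],
                            c(tx[j], ty[j]), c(0, 0))
          d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
          # mutual nearest neighbors within the search radius
          nnA <- apply(d2, 1, which.min)
          nnB <- apply(d2, 2, which.min)
          ia <- which(nnB[nnA] == seq_len(nrow(pa)) &
                        d2[cbind(seq_len(nrow(pa)), nnA)] < radius^2)
          if (length(ia) < 3) next
          pairs2[[length(pairs2) + 1]] <- list(
            i = i, j = j,
            p = sweep(feats[[i]]$xy[ia, , drop = FALSE], 2, ctr),
            q = sweep(feats[[j]]$xy[nnA[ia], , drop = FALSE], 2, ctr))
        }
      }
      if (length(pairs2) > 0) {
        pairs <- pairs2
        solveGN(pairs)
      }
    }

    resid <- do.call(rbind, lapply(pairs, function(pr) {
      Ti <- rigid_apply(pr$p, theta[pr$i], c(tx[pr$i], ty[pr$i]), c(0, 0))
      Tj <- rigid_apply(pr$q, theta[pr$j], c(tx[pr$j], ty[pr$j]), c(0, 0))
      data.frame(i = pr$i, j = pr$j, n = nrow(pr$p),
                 rms = sqrt(mean(rowSums((Tj - Ti)^2))))
    }))
    new("StackAlignment",
        transforms = data.frame(theta = theta, tx = tx, ty = ty),
        referenceIndex = as.integer(referenceIndex),
        residuals = resid)
  })
}

#' Resample sections into the common stack frame
#'
#' Applies the per-section transforms (bilinear resampling, white background
#' fill) and optionally crops centrally.
#'
#' @param stack a \linkS4class{SectionStack}.
#' @param alignment a \linkS4class{StackAlignment} covering all sections.
#' @param cropPx optional central crop size in pixels (square).
#' @return the registered (and cropped) \linkS4class{SectionStack}.
#' @export
applyAlignment <- function(stack, alignment, cropPx = NULL) {
  n <- length(stack@sections)
  if (nrow(alignment@transforms) != n)
    stop("alignment does not cover all sections")
  secs <- stack@sections
  for (i in seq_len(n)) {
    tr <- alignment@transforms[i, ]
    img <- secs[[i]]@pixels
    if (max(abs(unlist(tr))) > 1e-12) {
      for (c in 1:3)
        img[, , c] <- cpp_warp_rigid(img[, , c], tr$theta, tr$tx, tr$ty, 255)
    }
    if (!is.null(cropPx)) {
      H <- dim(img)[1]; W <- dim(img)[2]
      if (cropPx > H || cropPx > W) stop("crop larger than image")
      y0 <- floor((H - cropPx) / 2); x0 <- floor((W - cropPx) / 2)
      img <- img[(y0 + 1):(y0 + cropPx), (x0 + 1):(x0 + cropPx), , drop = FALSE]
    }
    secs[[i]]@pixels <- img
  }
  out <- stack
  out@sections <- secs
  if (!is.null(cropPx))
    out@meta$cropOffsetPx <- c(floor((dim(stack@sections[[1]]@pixels)[2] - cropPx) / 2),
                               floor((dim(stack@sections[[1]]@pixels)[1] - cropPx) / 2))
  out
}
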