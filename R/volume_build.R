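#' Optical-flow z interpolation of a channel volume
#'
#' Estimates dense optical flow between each consecutive slice pair (both
#' directions, coarse-to-fine Lucas-Kanade) and synthesizes factor - 1
#' intermediate slices per pair by blending the two flow-compensated warps:
#' at fraction a the result is (1-a) * warp(A, a of the A-to-B motion) +
#' a * warp(B, (1-a) of the B-to-A motion).  Original slices are kept
#' bit-exactly at indices k * factor; the output has (Z-1) * factor + 1
#' slices and z spacing divided by factor (world slice centers preserved via
#' the origin).
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param factor integer upsampling factor (>= 1).
#' @param levels,iters,winSigma optical-flow controls (pyramid levels,
#'   iterations per level, integration window sigma in pixels).
#' @return the interpolated \linkS4class{ChannelVolume}.
#' @export
flowInterpolateZ <- function(volume, factor, levels = 4, iters = 4,
                             winSigma = 4) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  v <- volume@values
  Z <- dim(v)[3]
  if (factor == 1) return(volume)
  if (Z < 2) stop("need at least two slices to interpolate")
  out <- array(0, c(dim(v)[1], dim(v)[2], (Z - 1) * factor + 1))
  for (k in seq_len(Z)) out[, , (k - 1) * factor + 1] <- v[, , k]
  for (k in seq_len(Z - 1)) {
    A <- v[, , k]; B <- v[, , k + 1]
    if (identical(A, B)) {
      for (j in seq_len(factor - 1)) out[, , (k - 1) * factor + 1 + j] <- A
      next
    }
    fAB <- cpp_flow_lk(A, B, levels, iters, winSigma)  # A(p) ~ B(p + fAB)
    fBA <- cpp_flow_lk(B, A, levels, iters, winSigma)
    # normalized-convolution fill-in: flow is only observable on content, so
    # propagate it across empty background (otherwise un-moved source pixels
    # ghost into the interpolated slices)
    fAB <- fillFlow(fAB, A + 1e-3)  # fAB lives on A's frame
    fBA <- fillFlow(fBA, B + 1e-3)
    for (j in seq_len(factor - 1)) {
      a <- j / factor
      wA <- cpp_warp_flow(A, fBA[, , 1], fBA[, , 2], a)
      wB <- cpp_warp_flow(B, fAB[, , 1], fAB[, , 2], 1 - a)
      out[, , (k - 1) * factor + 1 + j] <- (1 - a) * wA + a * wB
    }
  }
  new("ChannelVolume", values = out,
      spacingUm = volume@spacingUm / c(1, 1, factor),
      originUm = volume@originUm +
        c(0, 0, (volume@spacingUm[3] - volume@spacingUm[3] / factor) / 2),
      channel = volume@channel, provenance = "interpolated")
}

# content-weighted (normalized-convolution) smoothing of a flow field:
# regions without image structure inherit the motion of nearby structures
fillFlow <- function(flow, w, sigma = 12) {
  g <- function(m) {
    dim(m) <- c(dim(m), 1)
    out <- cpp_gauss3d(m, c(sigma, sigma, 0))
    dim(out) <- dim(out)[1:2]
    out
  }
  wg <- g(w)
  out <- flow
  out[, , 1] <- g(flow[, , 1] * w) / wg
  out[, , 2] <- g(flow[, , 2] * w) / wg
  out
}

#' Nearest-neighbor z resize of a channel volume
#'
#' Repeats each slice \code{factor} times; no new intensity values are
#' introduced.  Used for the B-cell channel, where single round cells need
#' no shape-connecting interpolation.
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param factor integer repetition factor (>= 1).
#' @return the resized \linkS4class{ChannelVolume}.
#' @export
nnResizeZ <- function(volume, factor) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1) return(volume)
  v <- volume@values
  out <- v[, , rep(seq_len(dim(v)[3]), each = factor), drop = FALSE]
  # repeated slices tile each original slab exactly, so the origin is kept
  new("ChannelVolume", values = out,
      spacingUm = volume@spacingUm / c(1, 1, factor),
      originUm = volume@originUm,
      channel = volume@channel, provenance = "interpolated")
}

# the per-channel grayscale recipes applied after interpolation; radii are
# x-y-z half-axes in voxels of the digital-ellipsoid structuring element
channelMorphology <- function(channel) {
  switch(channel,
    CD34 = list(list(op = "close", r = c(7, 7, 7)),
                list(op = "gauss", sigma = 1)),
    SMA = list(list(op = "dilate", r = c(7, 7, 4)),
               list(op = "close", r = c(8, 8, 4)),
               list(op = "gauss", sigma = 2)),
    CD271 = list(list(op = "dilate", r = c(8, 8, 2)),
                 list(op = "close", r = c(5, 5, 5)),
                 list(op = "gauss", sigma = 1)),
    CD20 = list(),
    stop("unknown channel: ", channel))
}

#' Channel-specific grayscale filtering of a volume
#'
#' Applies the channel's operator sequence with anisotropic digital-ellipsoid
#' structuring elements: CD34 gets a closing of uniform radius 7 and a
#' Gaussian blur of sigma 1; SMA a dilation 7-7-4, closing 8-8-4 and
#' Gaussian sigma 2; CD271 a dilation 8-8-2, closing 5-5-5 and Gaussian
#' sigma 1; CD20 passes through untouched.
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param channel override of the volume's channel label.
#' @return the filtered \linkS4class{ChannelVolume}.
#' @export
filterChannelVolume <- function(volume, channel = channelLabel(volume)) {
  recipe <- channelMorphology(channel)
  v <- volume@values
  for (step in recipe) {
    v <- switch(step$op,
      dilate = cpp_morph3d(v, step$r[1], step$r[2], step$r[3], TRUE),
      close = cpp_morph3d(cpp_morph3d(v, step$r[1], step$r[2], step$r[3], TRUE),
                          step$r[1], step$r[2], step$r[3], FALSE),
      gauss = cpp_gauss3d(v, rep(step$sigma, 3)))
  }
  new("ChannelVolume", values = v, spacingUm = volume@spacingUm,
      originUm = volume@originUm, channel = channel,
      provenance = if (length(recipe)) "filtered" else volume@provenance)
}

#' Central crop of a channel volume in x/y
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param cropPx target square size in pixels.
#' @return the cropped volume with its world origin advanced accordingly.
#' @export
cropVolumeXy <- function(volume, cropPx) {
  d <- dim(volume@values)
  if (cropPx > d[1] || cropPx > d[2]) stop("crop larger than volume")
  y0 <- floor((d[1] - cropPx) / 2)
  x0 <- floor((d[2] - cropPx) / 2)
  v <- volume@values[(y0 + 1):(y0 + cropPx), (x0 + 1):(x0 + cropPx), , drop = FALSE]
  new("ChannelVolume", values = v, spacingUm = volume@spacingUm,
      originUm = volume@originUm +
        c(x0 * volume@spacingUm[1], y0 * volume@spacingUm[2], 0),
      channel = volume@channel, provenance = volume@provenance)
}
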