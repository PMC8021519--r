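#' Estimate and remove the background white point
#'
#' Estimates the per-channel white point as a high percentile of pixel
#' intensities and rescales the image so background maps to pure white
#' before optical-density conversion.
#'
#' @param image a \linkS4class{SectionImage} or an H x W x 3 array.
#' @param percentile white-point percentile, default 0.99; 1 uses the
#'   channel maximum.
#' @return same type as the input, background-corrected.
#' @export
subtractBackground <- function(image, percentile = 0.99) {
  px <- if (is(image, "SectionImage")) image@pixels else image
  wp <- apply(px, 3, stats::quantile, probs = percentile, names = FALSE)
  if (any(wp < 5))
    stop("no background estimable: white point near black in channel(s) ",
         paste(which(wp < 5), collapse = ", "))
  for (c in 1:3) px[, , c] <- pmin(255, px[, , c] * (255 / wp[c]))
  if (is(image, "SectionImage")) {
    image@pixels <- px
    image
  } else px
}

#' Color deconvolution into per-stain density maps
#'
#' Converts transmitted RGB to optical density, OD = -log10((I + 1) / 256)
#' (the +1 guards log(0) and makes the phantom's forward rendering exactly
#' invertible), and solves the configured stain system rowwise:
#' densities = OD %*% M^-1.  Negative densities are clipped to zero.
#'
#' @param image a \linkS4class{SectionImage} or H x W x 3 array (0..255).
#' @param stain a \linkS4class{StainModel}.
#' @param clip clip negative densities to zero (default TRUE).
#' @return an H x W x 3 array of densities (brown, blue, red).
#' @export
colorDeconvolve <- function(image, stain, clip = TRUE) {
  px <- if (is(image, "SectionImage")) image@pixels else image
  M <- stain@odMatrix
  od <- rgbToOd(matrix(px, ncol = 3))
  den <- od %*% solve(M)
  if (clip) den[den < 0] <- 0
  array(den, dim(px))
}

#' Convert a single-stain density map to the 8-bit intensity representation
#'
#' Re-renders the stain's density through Beer-Lambert with its own OD
#' vector and reduces the rendering to one channel the way the original
#' workflow did: blue takes 255 minus the green channel, brown takes 255
#' minus the blue channel, red takes the CMYK magenta component (naive
#' conversion, K = 1 - max(RGB)/255, M = (1 - G/255 - K)/(1 - K)).  The
#' result is then linearly stretched over \code{range} (normally the
#' stack-wide min/max) to fill 0..255.
#'
#' @param density H x W matrix of stain densities.
#' @param channel one of "brown", "blue", "red".
#' @param stain a \linkS4class{StainModel}.
#' @param range optional c(min, max) used for the linear stretch; NULL
#'   stretches over this map alone.  An all-constant map returns zeros
#'   (degenerate stretch rule).
#' @return H x W numeric matrix in 0..255.
#' @export
channelToIntensity <- function(density, channel = c("blue", "brown", "red"),
                               stain, range = NULL) {
  channel <- match.arg(channel)
  raw <- rawChannelIntensity(density, channel, stain)
  if (is.null(range)) range <- c(min(raw), max(raw))
  if (diff(range) < 1e-12) return(matrix(0, nrow(density), ncol(density)))
  out <- (raw - range[1]) / (range[2] - range[1]) * 255
  pmin(pmax(out, 0), 255)
}

# unstretched single-channel rendering used by channelToIntensity and by the
# stack-wide range computation
rawChannelIntensity <- function(density, channel, stain) {
  M <- stain@odMatrix
  row <- c(brown = 1, blue = 2, red = 3)[[channel]]
  d <- as.vector(density)
  rgb <- 255 * 10^(-outer(d, M[row, ]))
  v <- switch(channel,
    blue = 255 - rgb[, 2],
    brown = 255 - rgb[, 3],
    red = {
      K <- 1 - pmax(rgb[, 1], rgb[, 2], rgb[, 3]) / 255
      m <- ifelse(K >= 1 - 1e-12, 0, (1 - rgb[, 2] / 255 - K) / (1 - K))
      255 * m
    })
  matrix(v, nrow(density), ncol(density))
}

#' Unmix a registered stack into per-channel intensity volumes
#'
#' Background-subtracts and color-deconvolves every section, converts each
#' stain density to its 8-bit intensity representation with a stack-wide
#' stretch, and assembles raw channel volumes.  The red stain identity
#' follows section parity (even 0-based indices CD271, odd CD20); z spacing
#' of the red channels is twice the section thickness.
#'
#' @param stack a registered \linkS4class{SectionStack}.
#' @param stain a \linkS4class{StainModel}.
#' @param backgroundPercentile forwarded to \code{\link{subtractBackground}}.
#' @return named list of \linkS4class{ChannelVolume}: SMA, CD34, CD271, CD20.
#' @export
unmixStack <- function(stack, stain, backgroundPercentile = 0.99) {
  secs <- stack@sections
  n <- length(secs)
  if (n == 0) stop("empty stack")
  th <- stack@thicknessUm
  px <- secs[[1]]@pixelSizeUm

  dens <- lapply(secs, function(s)
    colorDeconvolve(subtractBackground(s, backgroundPercentile), stain))

  idx <- vapply(secs, function(s) s@sectionIndex, integer(1))
  chanOf <- ifelse(idx %% 2 == 0, "CD271", "CD20")

  # stack-wide stretch ranges per output channel
  collect <- function(which, stainName) {
    maps <- lapply(which, function(i) dens[[i]][, , c(brown = 1, blue = 2, red = 3)[[stainName]]])
    maps
  }
  stretchRange <- function(maps, channel) {
    rng <- c(Inf, -Inf)
    for (m in maps) {
      raw <- rawChannelIntensity(m, channel, stain)
      rng <- c(min(rng[1], min(raw)), max(rng[2], max(raw)))
    }
    rng
  }

  buildVol <- function(which, stainName, channel, label, zspacing, z0) {
    maps <- collect(which, stainName)
    rng <- stretchRange(maps, channel)
    arr <- array(0, c(dim(maps[[1]]), length(maps)))
    for (i in seq_along(maps))
      arr[, , i] <- channelToIntensity(maps[[i]], channel, stain, rng)
    new("ChannelVolume", values = arr, spacingUm = c(px, px, zspacing),
        originUm = c(0, 0, z0), channel = label, provenance = "raw")
  }

  evens <- which(idx %% 2 == 0)
  odds <- which(idx %% 2 == 1)
  out <- list(
    SMA = buildVol(seq_len(n), "brown", "brown", "SMA", th, 0),
    CD34 = buildVol(seq_len(n), "blue", "blue", "CD34", th, 0))
  if (length(evens) > 0)
    out$CD271 <- buildVol(evens, "red", "red", "CD271", 2 * th,
                          z0 = idx[evens[1]] * th - th / 2)
  if (length(odds) > 0)
    out$CD20 <- buildVol(odds, "red", "red", "CD20", 2 * th,
                         z0 = idx[odds[1]] * th - th / 2)
  out
}
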