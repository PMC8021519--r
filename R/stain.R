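#' Default stain optical-density vectors
#'
#' Published unmixing vectors for the chromogen set used in the triple
#' staining: DAB (brown), alkaline-phosphatase Fast Blue, and
#' alkaline-phosphatase Fast Red.  Rows are unit OD vectors (R, G, B
#' columns) in the order brown, blue, red.
#'
#' @return a 3x3 numeric matrix with unit-norm rows.
#' @export
defaultStainVectors <- function() {
  m <- rbind(
    brown = c(0.26814753, 0.57031375, 0.77642715),  # DAB
    blue  = c(0.74890292, 0.60624161, 0.26731082),  # AP Fast Blue
    red   = c(0.21393921, 0.85112669, 0.47794022)   # AP Fast Red
  )
  colnames(m) <- c("R", "G", "B")
  m / sqrt(rowSums(m^2))
}

#' Construct a stain model
#'
#' @param odMatrix 3x3 matrix of stain OD vectors (rows brown, blue, red);
#'   rows are renormalized to unit length.
#' @param backgroundRgb transmitted background color, default white.
#' @param concentrationScale named OD amplitudes per phantom structure class;
#'   defaults chosen so stained structures are well above the iso-values
#'   after 8-bit stretching.
#' @return a \linkS4class{StainModel}.
#' @examples
#' sm <- stainModel()
#' odMatrix(sm)
#' @export
stainModel <- function(odMatrix = defaultStainVectors(),
                       backgroundRgb = c(255, 255, 255),
                       concentrationScale = c(
                         SMA = 0.9, CD34 = 0.9, CD271 = 0.9, CD20 = 0.9)) {
  odMatrix <- odMatrix / sqrt(rowSums(odMatrix^2))
  new("StainModel", odMatrix = odMatrix, backgroundRgb = backgroundRgb,
      concentrationScale = concentrationScale)
}

# Beer-Lambert forward rendering shared by the phantom renderer and the
# single-stain re-rendering in channelToIntensity.
#
# densities: n x 3 matrix of per-stain column densities (brown, blue, red).
# Returns n x 3 RGB in 0..255.  The +1/256 transmittance convention matches
# the optical-density formula used by colorDeconvolve, so rendering followed
# by deconvolution is exact to machine precision.
beerLambertRgb <- function(densities, odMatrix) {
  od <- densities %*% odMatrix
  256 * 10^(-od) - 1
}

# optical density of RGB values in 0..255 (the unmixer's fixed convention)
rgbToOd <- function(rgb) {
  -log10((rgb + 1) / 256)
}
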