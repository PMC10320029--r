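#' @import methods
NULL

#' Shearlet filter bank
#'
#' Frequency-domain filters of a non-subsampled shearlet system for images of
#' a fixed size: one radial low-pass filter, one radial band-pass filter per
#' scale (Meyer-type smooth windows), and per scale a set of angular shear
#' windows with trapezoidal (constant shear coordinate) frequency supports.
#' Analysis filters sum to one at every frequency, so reconstruction is the
#' plain sum of sub-bands.
#'
#' @slot lowpass Real H x W matrix, the low-pass frequency response.
#' @slot bandpass List of `scales` real H x W matrices, radial band-pass
#'   responses ordered coarse to fine.
#' @slot shear List of `scales` lists; element `[[j]][[k]]` is the k-th
#'   angular shear window at scale j (real H x W matrix). The windows of a
#'   scale sum to one at every frequency.
#' @slot scales Integer, number of band-pass scales.
#' @slot directions Integer vector of length `scales`: directional windows
#'   per scale, coarse to fine; each entry even and at least 2.
#' @slot dims Integer vector (height, width).
#'
#' @seealso [shearletFilterBank()], [nsstDecompose()],
#'   [partitionOfUnityError()]
#' @exportClass ShearletFilterBank
setClass("ShearletFilterBank",
  representation(lowpass = "matrix", bandpass = "list", shear = "list",
                 scales = "integer", directions = "integer",
                 dims = "integer"))

setValidity("ShearletFilterBank", function(object) {
  msg <- NULL
  d <- object@dims
  if (length(d) != 2L || any(d < 1L))
    msg <- c(msg, "dims must be two positive integers")
  if (length(object@bandpass) != object@scales)
    msg <- c(msg, "one band-pass filter required per scale")
  if (length(object@shear) != object@scales)
    msg <- c(msg, "one shear-filter set required per scale")
  if (length(object@directions) != object@scales)
    msg <- c(msg, "directions must have one entry per scale")
  for (j in seq_along(object@shear))
    if (length(object@shear[[j]]) != object@directions[j])
      msg <- c(msg, sprintf("scale %d: %d shear windows, expected %d",
                            j, length(object@shear[[j]]),
                            object@directions[j]))
  if (!identical(dim(object@lowpass), d))
    msg <- c(msg, "low-pass filter dimension mismatch")
  if (is.null(msg)) TRUE else msg
})

#' Shearlet decomposition of an image
#'
#' Full-resolution sub-bands of a non-subsampled shearlet decomposition: one
#' low-frequency sub-band plus, per scale, a list of directional
#' high-frequency sub-bands. Because the transform is non-subsampled every
#' band has the resolution of the input, and the input is recovered exactly
#' as the sum of all bands.
#'
#' @slot lfs Real H x W matrix, the low-frequency sub-band.
#' @slot hfs List over scales (coarse to fine) of lists over directions of
#'   real H x W matrices.
#' @slot directions Integer vector, directional band count per scale.
#' @slot dims Integer vector (height, width).
#'
#' @seealso [nsstDecompose()], [nsstReconstruct()], [lowFreq()], [highFreq()]
#' @exportClass ShearletDecomposition
setClass("ShearletDecomposition",
  representation(lfs = "matrix", hfs = "list", directions = "integer",
                 dims = "integer"))

setValidity("ShearletDecomposition", function(object) {
  msg <- NULL
  d <- object@dims
  if (!identical(dim(object@lfs), d))
    msg <- c(msg, "low-frequency band dimension mismatch")
  if (length(object@hfs) != length(object@directions))
    msg <- c(msg, "hfs must hold one list per scale")
  for (j in seq_along(object@hfs)) {
    if (length(object@hfs[[j]]) != object@directions[j])
      msg <- c(msg, sprintf("scale %d: wrong number of directional bands", j))
    for (b in object@hfs[[j]])
      if (!identical(dim(b), d))
        msg <- c(msg, sprintf("scale %d: band dimension mismatch", j))
  }
  if (is.null(msg)) TRUE else msg
})

#' Intensity/chroma representation of a color image
#'
#' The three planes of the linear IHS transform used for fusion: an
#' intensity plane I = (R + G + B) / 3 and two chroma carriers on fixed
#' orthogonal axes, (R - G) / sqrt(2) and (R + G - 2B) / sqrt(6). The
#' transform is exactly invertible; an achromatic pixel (R = G = B = v) maps
#' to intensity v with both chroma planes zero.
#'
#' @slot intensity Real H x W matrix.
#' @slot chroma1 Real H x W matrix, the (R - G) / sqrt(2) axis.
#' @slot chroma2 Real H x W matrix, the (R + G - 2B) / sqrt(6) axis.
#'
#' @seealso [rgbToIHS()], [ihsToRGB()], [substituteIntensity()]
#' @exportClass IHSImage
setClass("IHSImage",
  representation(intensity = "matrix", chroma1 = "matrix",
                 chroma2 = "matrix"))

setValidity("IHSImage", function(object) {
  d <- dim(object@intensity)
  if (!identical(dim(object@chroma1), d) ||
      !identical(dim(object@chroma2), d))
    "intensity and chroma planes must share one shape"
  else TRUE
})

#' Principal-component fusion weights for a band pair
#'
#' The 2 x 2 covariance analysis behind the high-frequency fusion rule: both
#' bands are flattened into the columns of a two-column data matrix, the
#' population covariance matrix is eigen-decomposed, and the components of
#' the principal eigenvector, normalized to sum to one, become the fusion
#' weights.
#'
#' @slot weights Numeric length 2, nonnegative, summing to one.
#' @slot values Numeric length 2, eigenvalues in decreasing order.
#' @slot vectors 2 x 2 matrix of eigenvectors (columns), as decomposed.
#' @slot cov 2 x 2 population covariance matrix of the two flattened bands.
#' @slot means Numeric length 2, the two band means.
#'
#' @seealso [pcaWeights()], [fuseHighpassPCA()]
#' @exportClass PCAWeights
setClass("PCAWeights",
  representation(weights = "numeric", values = "numeric",
                 vectors = "matrix", cov = "matrix", means = "numeric"))

setValidity("PCAWeights", function(object) {
  msg <- NULL
  if (length(object@weights) != 2L)
    msg <- c(msg, "weights must have length 2")
  else {
    if (abs(sum(object@weights) - 1) > 1e-12)
      msg <- c(msg, "weights must sum to 1")
    if (any(object@weights < -1e-12 | object@weights > 1 + 1e-12))
      msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Result of fusing a functional/structural image pair
#'
#' Holds the fused color image before final clipping (intensity substitution
#' can push values outside [0, 1]; clipping happens only when writing), the
#' configuration used, and an audit log with the intensity densities of the
#' low-frequency rule and the per-band principal-component weights.
#'
#' @slot fused Real H x W x 3 array, the fused image (unclipped).
#' @slot config The [fusionConfig()] list used for the run.
#' @slot log List: `idFunctional`, `idStructural` (low-frequency intensity
#'   densities), `alpha`, and `pcaWeights` (data frame with one row per
#'   scale/direction band pair).
#'
#' @seealso [fusePair()], [fusedImage()], [fusionLog()]
#' @exportClass FusionResult
setClass("FusionResult",
  representation(fused = "array", config = "list", log = "list"))

setValidity("FusionResult", function(object) {
  d <- dim(object@fused)
  if (length(d) != 3L || d[3] != 3L)
    "fused must be an H x W x 3 array"
  else TRUE
})
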