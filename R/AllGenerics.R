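#' Accessors for shearlet objects
#'
#' `lowFreq()` returns the low-frequency sub-band of a decomposition;
#' `highFreq()` returns one directional high-frequency band (or the list of
#' bands at a scale when `direction` is missing); `nScales()` and
#' `nDirections()` report the geometry of a decomposition or filter bank.
#'
#' @param x A [ShearletDecomposition-class] or [ShearletFilterBank-class].
#' @param scale Integer scale index, 1 = coarsest.
#' @param direction Integer direction index within the scale; if missing,
#'   the whole list of bands at `scale` is returned.
#' @return `lowFreq()`: a matrix. `highFreq()`: a matrix, or a list of
#'   matrices. `nScales()`: integer. `nDirections()`: integer vector, one
#'   entry per scale.
#' @examples
#' bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
#' dec <- nsstDecompose(matrix(runif(32 * 32), 32), bank)
#' dim(lowFreq(dec))
#' nDirections(dec)
#' @name shearlet-accessors
NULL

#' @rdname shearlet-accessors
#' @export
setGeneric("lowFreq", function(x) standardGeneric("lowFreq"))

#' @rdname shearlet-accessors
#' @export
setGeneric("highFreq",
           function(x, scale, direction) standardGeneric("highFreq"))

#' @rdname shearlet-accessors
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' @rdname shearlet-accessors
#' @export
setGeneric("nDirections", function(x) standardGeneric("nDirections"))

#' @rdname shearlet-accessors
setMethod("lowFreq", "ShearletDecomposition", function(x) x@lfs)

#' @rdname shearlet-accessors
setMethod("highFreq", "ShearletDecomposition",
  function(x, scale, direction) {
    if (scale < 1L || scale > length(x@hfs))
      stopConfig("scale index out of range")
    if (missing(direction)) return(x@hfs[[scale]])
    if (direction < 1L || direction > x@directions[scale])
      stopConfig("direction index out of range")
    x@hfs[[scale]][[direction]]
  })

#' @rdname shearlet-accessors
setMethod("nScales", "ShearletDecomposition",
          function(x) length(x@hfs))

#' @rdname shearlet-accessors
setMethod("nDirections", "ShearletDecomposition",
          function(x) x@directions)

#' @rdname shearlet-accessors
setMethod("nScales", "ShearletFilterBank", function(x) x@scales)

#' @rdname shearlet-accessors
setMethod("nDirections", "ShearletFilterBank", function(x) x@directions)

#' Accessors for IHS planes
#'
#' Extract the intensity plane or one of the two chroma planes of an
#' [IHSImage-class].
#'
#' @param x An [IHSImage-class].
#' @param which Chroma axis, 1 or 2.
#' @return A real matrix.
#' @examples
#' img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
#' trip <- rgbToIHS(img)
#' range(intensityPlane(trip))
#' @name ihs-accessors
NULL

#' @rdname ihs-accessors
#' @export
setGeneric("intensityPlane", function(x) standardGeneric("intensityPlane"))

#' @rdname ihs-accessors
#' @export
setGeneric("chromaPlane", function(x, which = 1L) standardGeneric("chromaPlane"))

#' @rdname ihs-accessors
setMethod("intensityPlane", "IHSImage", function(x) x@intensity)

#' @rdname ihs-accessors
setMethod("chromaPlane", "IHSImage", function(x, which = 1L) {
  if (which == 1L) x@chroma1
  else if (which == 2L) x@chroma2
  else stopConfig("which must be 1 or 2")
})

#' Accessors for fusion results
#'
#' `fusedImage()` returns the fused H x W x 3 array (clipped to [0, 1] when
#' `clip = TRUE`, the default for display/writing; unclipped values carry
#' the raw result of intensity substitution). `fusionLog()` returns the
#' audit log (intensity densities, alpha, per-band PCA weights) and
#' `fusionSettings()` the configuration used.
#'
#' @param x A [FusionResult-class].
#' @param clip Clip values into [0, 1]?
#' @return `fusedImage()`: an H x W x 3 array; `fusionLog()`,
#'   `fusionSettings()`: lists.
#' @name fusion-accessors
NULL

#' @rdname fusion-accessors
#' @export
setGeneric("fusedImage", function(x, clip = TRUE) standardGeneric("fusedImage"))

#' @rdname fusion-accessors
#' @export
setGeneric("fusionLog", function(x) standardGeneric("fusionLog"))

#' @rdname fusion-accessors
#' @export
setGeneric("fusionSettings", function(x) standardGeneric("fusionSettings"))

#' @rdname fusion-accessors
setMethod("fusedImage", "FusionResult", function(x, clip = TRUE) {
  if (clip) clip01(x@fused) else x@fused
})

#' @rdname fusion-accessors
setMethod("fusionLog", "FusionResult", function(x) x@log)

#' @rdname fusion-accessors
setMethod("fusionSettings", "FusionResult", function(x) x@config)

setMethod("show", "ShearletFilterBank", function(object) {
  cat(sprintf("ShearletFilterBank: %d x %d, %d scale(s), directions [%s]\n",
              object@dims[1], object@dims[2], object@scales,
              paste(object@directions, collapse = ", ")))
})

setMethod("show", "ShearletDecomposition", function(object) {
  cat(sprintf(
    "ShearletDecomposition: %d x %d, %d scale(s), directions [%s]\n",
    object@dims[1], object@dims[2], length(object@hfs),
    paste(object@directions, collapse = ", ")))
  cat(sprintf("  low-frequency band range: [%.4g, %.4g]\n",
              min(object@lfs), max(object@lfs)))
})

setMethod("show", "IHSImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("IHSImage: %d x %d, intensity range [%.4g, %.4g]\n",
              d[1], d[2], min(object@intensity), max(object@intensity)))
})

setMethod("show", "PCAWeights", function(object) {
  cat(sprintf("PCAWeights: w = (%.4f, %.4f), eigenvalues (%.4g, %.4g)\n",
              object@weights[1], object@weights[2],
              object@values[1], object@values[2]))
})

setMethod("show", "FusionResult", function(object) {
  d <- dim(object@fused)
  cat(sprintf("FusionResult: %d x %d x 3 fused image\n", d[1], d[2]))
  cat(sprintf("  alpha = %g, scales = %d, directions [%s]\n",
              object@config$alpha, object@config$scales,
              paste(object@config$directions, collapse = ", ")))
  cat(sprintf("  value range before clipping: [%.4g, %.4g]\n",
              min(object@fused), max(object@fused)))
})

# shared helper: clip into the displayable range
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
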