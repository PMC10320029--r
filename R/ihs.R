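# Linear IHS transform. The forward matrix is a fixed constant of the
# package; rows are the intensity and the two orthogonal chroma axes.
# Intensity is the channel mean, so it is symmetric under any permutation
# of (R, G, B), and both chroma axes annihilate achromatic pixels.
.IHS_FORWARD <- rbind(
  intensity = c(1, 1, 1) / 3,
  chroma1   = c(1, -1, 0) / sqrt(2),
  chroma2   = c(1, 1, -2) / sqrt(6))

.IHS_INVERSE <- solve(.IHS_FORWARD)

#' Linear IHS color transform
#'
#' `rgbToIHS()` maps an RGB image to an intensity plane plus two chroma
#' carriers via a fixed invertible 3 x 3 matrix; `ihsToRGB()` is its exact
#' inverse. The intensity is I = (R + G + B) / 3 and the chroma axes are
#' (R - G) / sqrt(2) and (R + G - 2B) / sqrt(6), both orthogonal to the
#' achromatic direction, so the round trip reproduces the input to machine
#' precision and gray pixels carry zero chroma.
#'
#' `ihsToRGB()` does not clip: after intensity substitution the output may
#' leave [0, 1] and is clipped only when an image file is written.
#'
#' @param img H x W x 3 numeric array (R, G, B), finite values. An H x W
#'   matrix is accepted and treated as an achromatic image (replicated to
#'   three identical channels).
#' @param trip An [IHSImage-class].
#' @return `rgbToIHS()`: an [IHSImage-class]. `ihsToRGB()`: an H x W x 3
#'   array.
#' @examples
#' x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
#' max(abs(ihsToRGB(rgbToIHS(x)) - x))   # ~1e-16
#' @seealso [substituteIntensity()]
#' @export
rgbToIHS <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stopShape("expected an H x W x 3 array, got dimensions [",
              paste(d, collapse = ", "), "]")
  checkFinite(img, "color image")
  flat <- matrix(img, ncol = 3L)            # pixels x channels
  comp <- flat %*% t(.IHS_FORWARD)          # pixels x components
  new("IHSImage",
      intensity = matrix(comp[, 1L], d[1], d[2]),
      chroma1   = matrix(comp[, 2L], d[1], d[2]),
      chroma2   = matrix(comp[, 3L], d[1], d[2]))
}

#' @rdname rgbToIHS
#' @export
ihsToRGB <- function(trip) {
  stopifnot(is(trip, "IHSImage"))
  d <- dim(trip@intensity)
  comp <- cbind(as.vector(trip@intensity), as.vector(trip@chroma1),
                as.vector(trip@chroma2))
  flat <- comp %*% t(.IHS_INVERSE)
  array(flat, dim = c(d, 3L))
}

#' Replace the intensity plane of an IHS triple
#'
#' Returns a triple whose intensity plane is `fusedI` while both chroma
#' planes are carried over untouched — the substitution step of IHS fusion,
#' where the fused intensity takes the place of the functional image's own
#' intensity and the color information is preserved.
#'
#' @param trip An [IHSImage-class].
#' @param fusedI Real matrix of the same shape as the triple's planes.
#' @return An [IHSImage-class].
#' @examples
#' x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
#' trip <- rgbToIHS(x)
#' flat <- substituteIntensity(trip, matrix(0.5, 8, 8))
#' identical(chromaPlane(flat, 1), chromaPlane(trip, 1))
#' @export
substituteIntensity <- function(trip, fusedI) {
  stopifnot(is(trip, "IHSImage"))
  if (!identical(dim(fusedI), dim(trip@intensity)))
    stopShape("substituted intensity plane has shape [",
              paste(dim(fusedI), collapse = ", "),
              "], expected [", paste(dim(trip@intensity), collapse = ", "),
              "]")
  new("IHSImage", intensity = fusedI,
      chroma1 = trip@chroma1, chroma2 = trip@chroma2)
}

#' The IHS transform matrix
#'
#' The fixed 3 x 3 forward matrix of the package's linear IHS transform
#' (rows: intensity, chroma1, chroma2; columns: R, G, B), exposed so the
#' color convention is auditable.
#'
#' @return A 3 x 3 numeric matrix.
#' @export
ihsMatrix <- function() .IHS_FORWARD
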