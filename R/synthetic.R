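# Seeded phantom generator: registered functional/structural image pairs
# emulating PET(SPECT)-MRI brain pairs. The structural image carries an
# elliptical "skull" rim, smooth tissue gradients, oriented sinusoidal
# ridges (high-frequency texture) and additive Gaussian noise; the
# functional image is a smooth nonnegative activity field — some blobs
# share coordinates with structural features, some do not, so the
# modalities carry complementary information — rendered through a fixed
# hot-body pseudo-color map. All coordinates are drawn once and shared, so
# the pair is registered by construction, and the generator is
# deterministic per seed.

# hot-body pseudo-color map: black -> red -> yellow -> white
hotColormap <- function(v) {
  v <- clip01(v)
  cbind(r = clip01(3 * v), g = clip01(3 * v - 1), b = clip01(3 * v - 2))
}

#' Generate a registered functional/structural phantom pair
#'
#' Produces a pseudo-color functional image and a grayscale structural
#' image of identical geometry, deterministic for a given seed. The
#' structural image mimics an anatomical (MRI-like) slice: an elliptical
#' skull rim, smooth interior gradients, `nRidges` oriented sinusoidal
#' texture patches, plus additive Gaussian noise of standard deviation
#' `noiseSd`, clipped to [0, 1]. The functional image mimics a metabolic
#' (PET/SPECT-like) map: `nBlobs` smooth Gaussian activity blobs — about
#' half centered on structural ridge locations, the rest elsewhere —
#' normalized to [0, 1] and rendered through a fixed hot-body color map.
#'
#' @param size Image size, a single integer or (height, width); default
#'   256, the registration size of typical atlas pairs.
#' @param nRidges Number of structural texture ridges (default 8).
#' @param nBlobs Number of activity blobs (default 5).
#' @param noiseSd Standard deviation of the structural additive noise
#'   (default 0.01, on the [0, 1] intensity scale).
#' @param seed Integer seed; the same seed and parameters give bit-identical
#'   output.
#' @return List with elements `functional` (H x W x 3 array in [0, 1]),
#'   `structural` (H x W matrix in [0, 1]) and `spec` (the generating
#'   parameters).
#' @examples
#' p <- phantomPair(size = 64, seed = 7)
#' dim(p$functional)
#' @seealso [grayscaleTwinPair()]
#' @export
phantomPair <- function(size = 256L, nRidges = 8L, nBlobs = 5L,
                        noiseSd = 0.01, seed = 1L) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 16L)) stopConfig("size must be at least 16")
  if (noiseSd < 0) stopConfig("noiseSd must be nonnegative")
  nRidges <- as.integer(nRidges); nBlobs <- as.integer(nBlobs)
  if (nRidges < 0L || nBlobs < 0L)
    stopConfig("feature counts must be nonnegative")
  H <- size[1]; W <- size[2]

  withr::with_seed(as.integer(seed), {
    X <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    Y <- matrix(seq(-1, 1, length.out = H), H, W)
    re <- sqrt((X / 0.82)^2 + (Y / 0.92)^2)
    head_mask <- 1 - meyerRamp((re - 0.9) / 0.1)
    skull <- exp(-((re - 0.97) / 0.035)^2)

    # broad tissue gradients
    grad <- matrix(0, H, W)
    for (i in 1:3) {
      cx <- stats::runif(1, -0.4, 0.4); cy <- stats::runif(1, -0.4, 0.4)
      sg <- stats::runif(1, 0.3, 0.6); amp <- stats::runif(1, 0.1, 0.25)
      grad <- grad + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    }

    # oriented sinusoidal ridges: localized high-frequency texture
    ridge <- matrix(0, H, W)
    ridgeCenters <- matrix(0, max(nRidges, 1L), 2L)
    if (nRidges > 0L) for (i in seq_len(nRidges)) {
      cx <- stats::runif(1, -0.5, 0.5); cy <- stats::runif(1, -0.5, 0.5)
      ridgeCenters[i, ] <- c(cx, cy)
      th <- stats::runif(1, 0, pi)
      fr <- stats::runif(1, 15, 35)
      ph <- stats::runif(1, 0, 2 * pi)
      sg <- stats::runif(1, 0.15, 0.3)
      ridge <- ridge + 0.1 *
        cos(fr * (X * cos(th) + Y * sin(th)) + ph) *
        exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    }

    structural <- clip01(head_mask * (0.18 + grad + ridge) + 0.85 * skull)
    if (noiseSd > 0)
      structural <- clip01(structural + stats::rnorm(H * W, sd = noiseSd))

    # activity blobs: share ridge coordinates for overlap, fresh draws for
    # complementary (functional-only) foci
    act <- matrix(0, H, W)
    if (nBlobs > 0L) for (i in seq_len(nBlobs)) {
      if (nRidges > 0L && i <= ceiling(nBlobs / 2)) {
        cx <- ridgeCenters[(i - 1L) %% nRidges + 1L, 1L]
        cy <- ridgeCenters[(i - 1L) %% nRidges + 1L, 2L]
      } else {
        cx <- stats::runif(1, -0.55, 0.55); cy <- stats::runif(1, -0.55, 0.55)
      }
      sg <- stats::runif(1, 0.08, 0.2); amp <- stats::runif(1, 0.5, 1)
      act <- act + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    }
    act <- act * head_mask
    if (max(act) > 0) act <- act / max(act)

    rgb <- hotColormap(as.vector(act))
    functional <- array(rgb, dim = c(H, W, 3L))

    list(functional = functional, structural = structural,
         spec = list(size = c(H, W), nRidges = nRidges, nBlobs = nBlobs,
                     noiseSd = noiseSd, seed = as.integer(seed),
                     colormap = "hot"))
  })
}

#' Grayscale-twin phantom pair
#'
#' A degenerate fixture for end-to-end idempotence checks: the structural
#' image of [phantomPair()] paired with a "functional" image that is the
#' same structural image replicated to three channels. Fusing this pair
#' must return the structural image unchanged (both fusion rules are
#' idempotent on identical bands and the transform reconstructs exactly).
#'
#' @inheritParams phantomPair
#' @return List as in [phantomPair()]; `functional[ , , c]` equals
#'   `structural` for every channel.
#' @export
grayscaleTwinPair <- function(size = 256L, nRidges = 8L, nBlobs = 5L,
                              noiseSd = 0.01, seed = 1L) {
  p <- phantomPair(size = size, nRidges = nRidges, nBlobs = nBlobs,
                   noiseSd = noiseSd, seed = seed)
  p$functional <- array(rep(p$structural, 3L),
                        dim = c(dim(p$structural), 3L))
  p$spec$twin <- TRUE
  p
}
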