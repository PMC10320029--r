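# Non-subsampled shearlet transform, built entirely in the 2-D discrete
# frequency plane: Meyer-windowed radial band-pass filters times angular
# shear windows with trapezoidal supports. All analysis filters sum to one
# at every frequency, so the inverse transform is the plain sum of bands
# and reconstruction is exact up to FFT round-off. Filtering is circular
# (periodic boundaries), which makes shift covariance exact.

# Meyer's C^3 polynomial ramp: 0 on t <= 0, 1 on t >= 1, and
# meyerRamp(t) + meyerRamp(1 - t) = 1 — the identity that makes both the
# radial and the angular windows partition unity.
meyerRamp <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# angular frequencies of an n-point DFT, in (-pi, pi]
fftOmega <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / n
}

# smooth radial low-pass: 1 below cutoff/2, 0 above cutoff
radialLowpass <- function(r, cutoff) 1 - meyerRamp(2 * r / cutoff - 1)

# Pseudo-polar shear coordinate with period 4. On the horizontal cone
# (|wx| >= |wy|) it is the shear slope wy/wx; on the vertical cone it is
# 2 - wx/wy. Continuous across cone boundaries and invariant under
# frequency negation, so shear windows built from it are real-symmetric.
shearCoordinate <- function(WX, WY) {
  hor <- abs(WX) >= abs(WY)
  s <- ifelse(hor, WY / WX, 2 - WX / WY)
  s[!is.finite(s)] <- 0      # DC point; band-pass filters vanish there
  s %% 4
}

# one angular window: a Meyer-smoothed bump of half-width delta around
# center, in the periodic shear coordinate; adjacent windows overlap so
# that each scale's windows sum to one everywhere
shearWindow <- function(xi, center, delta) {
  d <- abs((xi - center + 2) %% 4 - 2)     # wrapped distance, in [0, 2]
  cos(pi / 2 * meyerRamp(d / delta))^2
}

#' Build a non-subsampled shearlet filter bank
#'
#' Constructs the frequency-domain filters for images of the given size:
#' a radial Meyer-type low-pass filter, one radial band-pass filter per
#' scale (octave cutoffs, coarse to fine), and per scale an even number of
#' angular shear windows with trapezoidal frequency supports. By
#' construction the low-pass plus all band-pass x shear composites sum to
#' one at every frequency, which is what makes [nsstReconstruct()] an exact
#' inverse of [nsstDecompose()].
#'
#' @param height,width Image dimensions in pixels, each at least 16.
#' @param scales Number of band-pass scales (default 3, the setting the
#'   fusion pipeline performs best at).
#' @param directions Integer vector of length `scales`: directional windows
#'   per scale, coarse to fine; each entry even and >= 2. Default
#'   `c(4, 8, 16)`, doubling with scale in keeping with the parabolic
#'   scaling of the shearlet dilation.
#' @return A [ShearletFilterBank-class].
#' @examples
#' bank <- shearletFilterBank(64, 64, scales = 2, directions = c(4, 8))
#' partitionOfUnityError(bank)   # ~1e-16
#' @export
shearletFilterBank <- function(height, width, scales = 3L,
                               directions = c(4L, 8L, 16L)) {
  height <- as.integer(height); width <- as.integer(width)
  scales <- as.integer(scales); directions <- as.integer(directions)
  if (height < 16L || width < 16L)
    stopConfig("image must be at least 16 x 16 for the filter support")
  if (scales < 1L)
    stopConfig("scales must be >= 1")
  if (length(directions) != scales)
    stopConfig("directions must have one entry per scale")
  if (any(directions < 2L) || any(directions %% 2L != 0L))
    stopConfig("each direction count must be even and >= 2")

  wy <- fftOmega(height); wx <- fftOmega(width)
  WY <- matrix(wy, height, width)
  WX <- matrix(wx, height, width, byrow = TRUE)
  r <- sqrt(WX^2 + WY^2)
  xi <- shearCoordinate(WX, WY)

  # octave radial cutoffs: scale `scales` (finest) transitions over
  # [pi/2, pi], each coarser scale one octave down; telescoping the
  # low-pass differences makes the radial filters sum to one exactly
  bandpass <- vector("list", scales)
  prev <- matrix(1, height, width)
  for (j in scales:1) {
    cutoff <- pi * 2^(j - scales)
    lp <- radialLowpass(r, cutoff)
    bandpass[[j]] <- prev - lp
    prev <- lp
  }
  lowpass <- prev

  # Symmetrize each window under index negation k -> -k (mod n). Away
  # from the Nyquist row/column this is a no-op (the shear coordinate is
  # already even), but at the Nyquist frequencies of an even-sized grid
  # +pi and -pi alias to the same sample, and averaging the two window
  # values there restores exact Hermitian symmetry — so filtered real
  # images stay real. Summing preserves the partition of unity.
  negIdx <- function(n) c(1L, n:2L)
  symmetrize <- function(w) (w + w[negIdx(height), negIdx(width)]) / 2

  shear <- vector("list", scales)
  for (j in seq_len(scales)) {
    k <- directions[j]
    delta <- 4 / k
    shear[[j]] <- lapply(seq_len(k) - 1L, function(i)
      symmetrize(shearWindow(xi, i * delta, delta)))
  }

  new("ShearletFilterBank", lowpass = lowpass, bandpass = bandpass,
      shear = shear, scales = scales, directions = directions,
      dims = c(height, width))
}

#' Partition-of-unity error of a filter bank
#'
#' Maximum absolute deviation from one of the summed composite frequency
#' responses (low-pass plus band-pass times shear over all scales and
#' directions), plus the largest per-scale deviation of the shear windows
#' alone. Both are zero up to floating-point round-off for any bank built
#' by [shearletFilterBank()].
#'
#' @param bank A [ShearletFilterBank-class].
#' @return Named numeric vector with elements `total` and `shear`.
#' @export
partitionOfUnityError <- function(bank) {
  stopifnot(is(bank, "ShearletFilterBank"))
  total <- bank@lowpass
  shearErr <- 0
  for (j in seq_len(bank@scales)) {
    angsum <- Reduce(`+`, bank@shear[[j]])
    shearErr <- max(shearErr, max(abs(angsum - 1)))
    total <- total + bank@bandpass[[j]] * angsum
  }
  c(total = max(abs(total - 1)), shear = shearErr)
}

ifft2Real <- function(z) Re(stats::fft(z, inverse = TRUE)) / length(z)

#' Decompose an image into shearlet sub-bands
#'
#' Applies every filter of the bank to the image by pointwise
#' multiplication in the frequency domain (circular convolution): the
#' low-pass filter yields the low-frequency sub-band, each band-pass x
#' shear composite one directional high-frequency sub-band. All bands keep
#' the full input resolution, the map is linear in the image, and real
#' input gives real bands because the filters are symmetric under
#' frequency negation.
#'
#' @param img Real numeric matrix, same size as the bank.
#' @param bank A [ShearletFilterBank-class] built for `dim(img)`.
#' @return A [ShearletDecomposition-class].
#' @examples
#' bank <- shearletFilterBank(64, 64)
#' x <- matrix(runif(64 * 64), 64)
#' dec <- nsstDecompose(x, bank)
#' max(abs(nsstReconstruct(dec) - x))   # ~1e-15
#' @seealso [nsstReconstruct()]
#' @export
nsstDecompose <- function(img, bank) {
  stopifnot(is(bank, "ShearletFilterBank"))
  if (!is.matrix(img))
    stopShape("expected a single-channel image matrix")
  if (!identical(dim(img), bank@dims))
    stopShape("image is ", paste(dim(img), collapse = " x "),
              " but the filter bank was built for ",
              paste(bank@dims, collapse = " x "))
  checkFinite(img, "image")

  F <- stats::fft(img)
  lfs <- ifft2Real(F * bank@lowpass)
  hfs <- vector("list", bank@scales)
  for (j in seq_len(bank@scales)) {
    Bj <- F * bank@bandpass[[j]]
    hfs[[j]] <- lapply(bank@shear[[j]], function(w) ifft2Real(Bj * w))
  }
  new("ShearletDecomposition", lfs = lfs, hfs = hfs,
      directions = bank@directions, dims = bank@dims)
}

#' Reconstruct an image from shearlet sub-bands
#'
#' The pixel-wise sum of the low-frequency band and every directional
#' high-frequency band. Because the analysis filters partition unity this
#' is the exact inverse of [nsstDecompose()].
#'
#' @param bands A [ShearletDecomposition-class].
#' @return A real matrix of the decomposition's dimensions.
#' @export
nsstReconstruct <- function(bands) {
  stopifnot(is(bands, "ShearletDecomposition"))
  d <- bands@dims
  out <- bands@lfs
  for (scale in bands@hfs) for (b in scale) {
    if (!identical(dim(b), d))
      stopShape("inconsistent band shapes in decomposition")
    out <- out + b
  }
  out
}
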