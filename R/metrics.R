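# Fusion-quality metrics. All operate on [0, 1] images but report on the
# conventional 8-bit scale: SD and the SSIM stabilizers use the 0-255
# dynamic range and entropy uses a 256-bin histogram of the image
# quantized to 8 bits, so values are comparable with the image-fusion
# literature.

#' Standard deviation of an image
#'
#' Population standard deviation of the pixel intensities, reported on the
#' 0-255 scale. Larger values indicate more intensity variation (contrast)
#' in the fused image.
#'
#' @param img Nonempty numeric matrix with values in [0, 1].
#' @return Scalar >= 0.
#' @examples
#' imageSD(matrix(c(0, 1), 16, 16))   # 127.5
#' @export
imageSD <- function(img) {
  if (length(img) == 0L) stopValue("empty image")
  checkFinite(img, "image")
  x <- as.vector(img) * 255
  sqrt(mean((x - mean(x))^2))
}

#' Shannon entropy of an image
#'
#' Entropy in bits of the 256-bin gray-level histogram after quantizing the
#' image to 8 bits (values clipped to [0, 1], then rounded to 0..255).
#' Zero for a constant image; 8 bits when all 256 levels are equally
#' frequent. A histogram-only statistic: invariant under any permutation of
#' gray levels.
#'
#' @param img Nonempty numeric matrix.
#' @return Scalar in [0, 8].
#' @examples
#' imageEntropy(matrix(0.5, 8, 8))               # 0
#' imageEntropy(matrix((0:255) / 255, 16, 16))   # 8
#' @export
imageEntropy <- function(img) {
  if (length(img) == 0L) stopValue("empty image")
  checkFinite(img, "image")
  q <- as.integer(round(clip01(img) * 255))
  p <- tabulate(q + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# normalized 11-tap Gaussian, sigma 1.5 — the standard SSIM window
.ssimKernel <- local({
  k <- exp(-(-5:5)^2 / (2 * 1.5^2))
  k / sum(k)
})

# 'valid' correlation of a matrix with a separable symmetric 1-D kernel
filterValid <- function(x, k) {
  m <- length(k)
  down <- function(z) {                 # along rows (down each column)
    n <- nrow(z)
    out <- matrix(0, n - m + 1L, ncol(z))
    for (t in seq_len(m))
      out <- out + k[t] * z[t:(n - m + t), , drop = FALSE]
    out
  }
  t(down(t(down(x))))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM between two images with the standard 11 x 11 Gaussian
#' window (sigma 1.5) and stabilizers K1 = 0.01, K2 = 0.03 on the 0-255
#' dynamic range. Local means, variances and covariance are
#' Gaussian-weighted with no sample-size correction, and the mean is taken
#' over the region where the window fits entirely inside the image (valid
#' region), matching the reference formulation. Symmetric in its
#' arguments, bounded above by 1, and equal to 1 iff the images coincide.
#'
#' @param imgA,imgB Numeric matrices of identical shape, at least 11 x 11,
#'   values on the [0, 1] scale.
#' @return Scalar in [-1, 1].
#' @examples
#' x <- matrix(runif(256), 16)
#' imageSSIM(x, x)   # 1
#' @export
imageSSIM <- function(imgA, imgB) {
  if (!identical(dim(imgA), dim(imgB)))
    stopShape("images differ in shape")
  if (any(dim(imgA) < 11L))
    stopValue("images must be at least 11 x 11 for the SSIM window")
  checkFinite(imgA, "image"); checkFinite(imgB, "image")
  x <- imgA * 255; y <- imgB * 255
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  k <- .ssimKernel
  mx <- filterValid(x, k);  my <- filterValid(y, k)
  vx <- filterValid(x * x, k) - mx^2
  vy <- filterValid(y * y, k) - my^2
  cxy <- filterValid(x * y, k) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Structural content (SC)
#'
#' The classical energy ratio sum(ref^2) / sum(fused^2). Equal to 1 when
#' the fused image reproduces the reference's energy; values below 1 mean
#' the fused image carries more energy than the reference.
#'
#' @param ref,fused Numeric matrices of identical shape; `fused` must not
#'   be identically zero.
#' @return Scalar > 0.
#' @examples
#' x <- matrix(runif(64), 8)
#' structuralContent(x, x)       # 1
#' structuralContent(x, 2 * x)   # 0.25
#' @export
structuralContent <- function(ref, fused) {
  if (!identical(dim(ref), dim(fused)))
    stopShape("images differ in shape")
  checkFinite(ref, "image"); checkFinite(fused, "image")
  denom <- sum(fused^2)
  if (denom == 0) stopValue("fused image has zero energy")
  sum(ref^2) / denom
}

#' Quality report for a fused image
#'
#' Computes the four fusion metrics on the fused intensity plane (channel
#' mean of the fused color image, clipped to [0, 1]): standard deviation
#' and entropy of the fused image itself, and SSIM and structural content
#' against each source — the structural image and the intensity plane of
#' the functional image — plus their means. How a single-number SSIM/SC
#' should combine the two sources is a convention, so all variants are
#' reported.
#'
#' @param fused H x W x 3 array (or [FusionResult-class]).
#' @param functional H x W x 3 array, the functional source image.
#' @param structural H x W matrix, the structural source image.
#' @return Nested list: `sd`, `entropy`, `ssim$structural`,
#'   `ssim$functional`, `ssim$mean`, `sc$structural`, `sc$functional`,
#'   `sc$mean`.
#' @export
qualityReport <- function(fused, functional, structural) {
  if (is(fused, "FusionResult")) fused <- fusedImage(fused)
  fI <- clip01((fused[, , 1] + fused[, , 2] + fused[, , 3]) / 3)
  if (is.matrix(functional))
    functional <- array(rep(functional, 3L), dim = c(dim(functional), 3L))
  srcI <- (functional[, , 1] + functional[, , 2] + functional[, , 3]) / 3
  ssimS <- imageSSIM(fI, structural)
  ssimF <- imageSSIM(fI, srcI)
  scS <- structuralContent(structural, fI)
  scF <- structuralContent(srcI, fI)
  list(sd = imageSD(fI),
       entropy = imageEntropy(fI),
       ssim = list(structural = ssimS, functional = ssimF,
                   mean = (ssimS + ssimF) / 2),
       sc = list(structural = scS, functional = scF,
                 mean = (scS + scF) / 2))
}
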