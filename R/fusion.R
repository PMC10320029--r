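# The two fusion rules. Low-frequency sub-bands carry background and
# texture and are fused by structural-information weights
# exp(alpha * |band - ID|), where ID = mean + median of the band is its
# intensity density: pixels deviating from the band's typical level are
# taken to carry structure and get exponentially more weight, with alpha
# modulating how sharply. High-frequency directional sub-bands are fused
# by the normalized components of the principal eigenvector of the band
# pair's 2 x 2 covariance matrix, so the band contributing more coefficient
# variance dominates.

#' Intensity density of a sub-band
#'
#' The scalar mean(band) + median(band), the reference level of the
#' structural-information rule. Deviation from it flags pixels that carry
#' texture or background structure. The median uses the midpoint convention
#' for even pixel counts.
#'
#' @param band Nonempty numeric matrix (or vector) of finite values.
#' @return A scalar.
#' @examples
#' intensityDensity(matrix(0.5, 4, 4))   # 1.0: mean = median = 0.5
#' @export
intensityDensity <- function(band) {
  if (length(band) == 0L) stopValue("empty band")
  checkFinite(band, "band")
  mean(band) + stats::median(band)
}

#' Structural-information weights
#'
#' The element-wise weight map exp(alpha * |band - idVal|): strictly
#' positive everywhere, identically one when alpha = 0, and growing
#' exponentially with a pixel's deviation from the band's intensity
#' density.
#'
#' @param band Numeric matrix.
#' @param idVal Scalar intensity density, usually [intensityDensity()] of
#'   the band.
#' @param alpha Nonnegative modulation parameter; the pipeline default is 4.
#' @return Matrix of the same shape, values >= 1 attained at
#'   `band == idVal`.
#' @export
structuralInformation <- function(band, idVal, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stopConfig("alpha must be a nonnegative scalar")
  exp(alpha * abs(band - idVal))
}

#' Fuse two low-frequency sub-bands by structural information
#'
#' Per-pixel weighted mean (SI_a * a + SI_b * b) / (SI_a + SI_b), with each
#' band's weight map from [structuralInformation()] against its own
#' intensity density. The weights are strictly positive, so there is no
#' division hazard and every fused pixel lies between the two input values.
#' With alpha = 0 the rule reduces to the plain average.
#'
#' @param lfsA,lfsB Numeric matrices of identical shape.
#' @param alpha Nonnegative modulation parameter (default 4).
#' @return Matrix of the fused low-frequency sub-band.
#' @examples
#' a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
#' f <- fuseLowpassSI(a, b, alpha = 4)
#' all(f >= pmin(a, b) & f <= pmax(a, b))
#' @export
fuseLowpassSI <- function(lfsA, lfsB, alpha = 4) {
  if (!identical(dim(lfsA), dim(lfsB)))
    stopShape("low-frequency bands differ in shape")
  siA <- structuralInformation(lfsA, intensityDensity(lfsA), alpha)
  siB <- structuralInformation(lfsB, intensityDensity(lfsB), alpha)
  (siA * lfsA + siB * lfsB) / (siA + siB)
}

#' Principal-component weights of a band pair
#'
#' Flattens the two bands into the columns of a data matrix, forms their
#' 2 x 2 population covariance matrix, eigen-decomposes it, and normalizes
#' the components of the eigenvector of the largest eigenvalue to sum to
#' one. The eigenvector sign is chosen to make both components nonnegative;
#' if strong negative correlation leaves the components with mixed signs,
#' their absolute values are normalized instead. Two constant bands (zero
#' covariance matrix) fall back to equal weights (0.5, 0.5).
#'
#' @param bandA,bandB Numeric matrices of identical shape, >= 2 pixels.
#' @return A [PCAWeights-class].
#' @examples
#' a <- matrix(rnorm(64), 8)
#' pcaWeights(a, a)   # identical bands: weights (0.5, 0.5)
#' @export
pcaWeights <- function(bandA, bandB) {
  if (!identical(dim(bandA), dim(bandB)))
    stopShape("bands differ in shape")
  if (length(bandA) < 2L) stopValue("bands must hold at least 2 pixels")
  x1 <- as.vector(bandA); x2 <- as.vector(bandB)
  m1 <- mean(x1); m2 <- mean(x2)
  d1 <- x1 - m1; d2 <- x2 - m2
  n <- length(x1)
  cm <- matrix(c(sum(d1 * d1), sum(d1 * d2),
                 sum(d1 * d2), sum(d2 * d2)) / n, 2L, 2L)

  if (max(abs(cm)) < .Machine$double.eps) {
    # both bands constant: no principal direction, split evenly
    return(new("PCAWeights", weights = c(0.5, 0.5), values = c(0, 0),
               vectors = diag(2), cov = cm, means = c(m1, m2)))
  }
  e <- eigen(cm, symmetric = TRUE)          # values in decreasing order
  v <- e$vectors[, 1L]
  if (all(v <= 0)) v <- -v
  if (any(v < 0)) v <- abs(v)               # mixed signs: documented fallback
  s <- sum(v)
  w <- if (s > 0) v / s else c(0.5, 0.5)
  new("PCAWeights", weights = w, values = e$values, vectors = e$vectors,
      cov = cm, means = c(m1, m2))
}

#' Fuse two high-frequency sub-bands by PCA eigenweights
#'
#' The convex combination w1 * bandA + w2 * bandB with weights from
#' [pcaWeights()]. Applied independently to every matching (scale,
#' direction) band pair by the pipeline.
#'
#' @param bandA,bandB Numeric matrices of identical shape.
#' @param weights Optional precomputed [PCAWeights-class]; computed from
#'   the pair when missing (the pipeline passes pooled weights here when
#'   configured for global PCA).
#' @return Matrix of the fused band.
#' @export
fuseHighpassPCA <- function(bandA, bandB, weights = NULL) {
  if (!identical(dim(bandA), dim(bandB)))
    stopShape("bands differ in shape")
  if (is.null(weights)) weights <- pcaWeights(bandA, bandB)
  stopifnot(is(weights, "PCAWeights"))
  weights@weights[1L] * bandA + weights@weights[2L] * bandB
}
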