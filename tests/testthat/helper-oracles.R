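# Shared fixtures and independent oracles. The oracles re-derive each
# fusion rule from its defining formulas by a different route than the
# package (explicit loops / closed forms), so agreement is evidence, not
# tautology.

randImage <- function(h, w = h) matrix(stats::runif(h * w), h, w)

randColorImage <- function(h, w = h) {
  array(stats::runif(h * w * 3), dim = c(h, w, 3L))
}

relL2 <- function(x, y) sqrt(sum((x - y)^2) / sum(y^2))

# Brute-force structural-information fusion: mean by explicit sum, median
# by sorting with the midpoint convention, then the per-pixel weighted mean
# evaluated scalar by scalar.
oracleFuseSI <- function(a, b, alpha) {
  idOf <- function(m) {
    v <- sort(as.vector(m))
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    sum(v) / n + med
  }
  ida <- idOf(a); idb <- idOf(b)
  out <- a
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    wa <- exp(alpha * abs(a[i, j] - ida))
    wb <- exp(alpha * abs(b[i, j] - idb))
    out[i, j] <- (wa * a[i, j] + wb * b[i, j]) / (wa + wb)
  }
  out
}

# From-scratch PCA fusion: population covariance by explicit sums and a
# closed-form 2x2 eigen solve (quadratic formula), independent of eigen().
oraclePCAWeights <- function(a, b) {
  x <- as.vector(a); y <- as.vector(b)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cxx <- sum((x - mx)^2) / n
  cyy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  if (max(abs(c(cxx, cxy, cyy))) < .Machine$double.eps)
    return(c(0.5, 0.5))
  lam <- ((cxx + cyy) + sqrt((cxx - cyy)^2 + 4 * cxy^2)) / 2
  v <- if (abs(cxy) > 1e-300) c(lam - cyy, cxy)
       else if (cxx >= cyy) c(1, 0) else c(0, 1)
  if (all(v <= 0)) v <- -v
  if (any(v < 0)) v <- abs(v)
  v / sum(v)
}

oracleFusePCA <- function(a, b) {
  w <- oraclePCAWeights(a, b)
  w[1] * a + w[2] * b
}

# Reference SSIM from scikit-image (Wang et al. formulation), run through
# the system python on CSV-serialized matrices.
skimageSSIM <- function(a, b) {
  td <- withr::local_tempdir()
  fa <- file.path(td, "a.csv"); fb <- file.path(td, "b.csv")
  write.table(a, fa, row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(b, fb, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- file.path(td, "ssim.py")
  writeLines(c(
    "import numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    sprintf("a = np.loadtxt(%s, delimiter=',') * 255", shQuote(fa)),
    sprintf("b = np.loadtxt(%s, delimiter=',') * 255", shQuote(fb)),
    paste0("print('%.12f' % ssim(a, b, win_size=11, gaussian_weights=True,",
           " sigma=1.5, use_sample_covariance=False, data_range=255))")),
    script)
  as.numeric(system2("python", script, stdout = TRUE))
}
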