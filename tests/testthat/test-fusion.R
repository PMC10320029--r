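test_that("intensity density is mean plus median", {
  expect_equal(intensityDensity(matrix(0.3, 5, 5)), 0.6)
  expect_equal(intensityDensity(matrix(seq(0.1, 0.9, by = 0.1), 3, 3)), 1.0)
  expect_equal(intensityDensity(matrix(c(0, 0, 0, 1), 2, 2)), 0.25)
  expect_error(intensityDensity(matrix(numeric(0), 0, 0)),
               class = "shearfuse_value_error")
})

test_that("structural information is the exponential deviation weight", {
  b <- matrix(c(0.2, 0.5), 2, 2)
  expect_equal(structuralInformation(b, 0.5, 0),
               matrix(1, 2, 2))
  expect_equal(structuralInformation(matrix(0.5), 1.0, 4)[1, 1], exp(2))
  expect_equal(structuralInformation(matrix(0.7), 0.7, 4)[1, 1], 1)
  expect_error(structuralInformation(b, 0.5, -1),
               class = "shearfuse_config_error")
})

test_that("low-frequency SI fusion reduces to known closed forms", {
  set.seed(31)
  a <- randImage(6)
  expect_lt(max(abs(fuseLowpassSI(a, a, 4) - a)), 1e-10)
  b <- randImage(6)
  expect_equal(fuseLowpassSI(a, b, 0), (a + b) / 2)
  expect_error(fuseLowpassSI(a, randImage(5)),
               class = "shearfuse_shape_error")
})

test_that("both fusion rules match independent brute-force oracles", {
  set.seed(32)
  for (rep in 1:50) {
    a <- randImage(8); b <- randImage(8)
    expect_lt(max(abs(fuseLowpassSI(a, b, 4) - oracleFuseSI(a, b, 4))),
              1e-9)
    expect_lt(max(abs(fuseHighpassPCA(a, b) - oracleFusePCA(a, b))), 1e-9)
  }
})

test_that("both rules are convex: fused pixels stay between the inputs", {
  set.seed(33)
  for (rep in 1:10) {
    a <- randImage(8); b <- randImage(8)
    lo <- pmin(a, b) - 1e-12; hi <- pmax(a, b) + 1e-12
    fsi <- fuseLowpassSI(a, b, 4)
    fpca <- fuseHighpassPCA(a, b)
    expect_true(all(fsi >= lo & fsi <= hi))
    expect_true(all(fpca >= lo & fpca <= hi))
  }
})

test_that("PCA weights follow the covariance structure", {
  set.seed(34)
  a <- randImage(8)
  expect_equal(pcaWeights(a, a)@weights, c(0.5, 0.5))

  # dominant-variance band takes almost all weight (diagonal covariance)
  big <- matrix(rnorm(64, sd = 1), 8)
  tiny <- matrix(rnorm(64, sd = 1e-6), 8)
  w <- pcaWeights(big, tiny)@weights
  expect_gt(w[1], 1 - 1e-6)
  expect_lt(max(abs(fuseHighpassPCA(big, tiny) - big)), 1e-5)

  # degenerate: two constant bands fall back to an even split
  expect_equal(pcaWeights(matrix(0.2, 4, 4), matrix(0.7, 4, 4))@weights,
               c(0.5, 0.5))

  w2 <- pcaWeights(a, randImage(8))
  expect_equal(sum(w2@weights), 1)
  expect_true(all(w2@weights >= 0 & w2@weights <= 1))
  expect_equal(w2@cov, t(w2@cov))
})

test_that("raising alpha shifts weight toward the deviating pixel", {
  # bands built so pixel (2,2) deviates far from band a's intensity
  # density (ID_a ~ 0.447, |a - ID_a| ~ 0.50) and only slightly from band
  # b's (ID_b ~ 1.025, |b - ID_b| ~ 0.13)
  a <- matrix(0.2, 4, 4); a[2, 2] <- 0.95
  b <- matrix(0.5, 4, 4); b[2, 2] <- 0.90
  gaps <- vapply(c(0, 1, 2, 4, 8),
                 function(al) abs(fuseLowpassSI(a, b, al)[2, 2] - a[2, 2]),
                 0)
  expect_true(all(diff(gaps) < 0))
})
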