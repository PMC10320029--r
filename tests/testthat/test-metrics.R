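test_that("standard deviation follows closed forms and scaling", {
  expect_equal(imageSD(matrix(0.4, 8, 8)), 0)
  expect_equal(imageSD(matrix(c(0, 1), 16, 16)), 127.5)
  set.seed(41)
  x <- randImage(16)
  expect_equal(imageSD(0.5 * x), 0.5 * imageSD(x))
})

test_that("entropy counts histogram information", {
  expect_equal(imageEntropy(matrix(0.77, 8, 8)), 0)
  expect_equal(imageEntropy(matrix((0:255) / 255, 16, 16)), 8)
  expect_equal(imageEntropy(matrix(c(0, 1), 8, 8)), 1)
  # histogram-only: permuting gray levels changes nothing
  set.seed(42)
  x <- matrix(sample(0:255, 256, replace = TRUE) / 255, 16)
  perm <- sample(0:255)
  y <- matrix(perm[round(x * 255) + 1] / 255, 16)
  expect_equal(imageEntropy(y), imageEntropy(x))
})

test_that("SSIM is reflexive, symmetric, bounded and matches scikit-image", {
  set.seed(43)
  x <- randImage(16); y <- randImage(16)
  expect_equal(imageSSIM(x, x), 1)
  expect_equal(imageSSIM(x, y), imageSSIM(y, x))
  expect_lte(imageSSIM(x, y), 1)
  for (rep in 1:3) {
    a <- randImage(16); b <- randImage(16)
    expect_lt(abs(imageSSIM(a, b) - skimageSSIM(a, b)), 1e-6)
  }
  # anticorrelated binary halves: similarity cannot be positive
  half <- rbind(matrix(0, 8, 16), matrix(1, 8, 16))
  expect_lte(imageSSIM(half, 1 - half), 0)
  expect_error(imageSSIM(x, randImage(15)), class = "shearfuse_shape_error")
})

test_that("structural content is the energy ratio", {
  set.seed(44)
  x <- randImage(8)
  expect_equal(structuralContent(x, x), 1)
  expect_equal(structuralContent(x, 2 * x), 0.25)
  y <- randImage(8)
  expect_equal(structuralContent(x, y), sum(x^2) / sum(y^2))
  expect_error(structuralContent(x, matrix(0, 8, 8)),
               class = "shearfuse_value_error")
})

test_that("all four metrics are invariant under transposition", {
  set.seed(45)
  x <- randImage(16); y <- randImage(16)
  expect_equal(imageSD(t(x)), imageSD(x))
  expect_equal(imageEntropy(t(x)), imageEntropy(x))
  expect_equal(imageSSIM(t(x), t(y)), imageSSIM(x, y))
  expect_equal(structuralContent(t(x), t(y)), structuralContent(x, y))
})

test_that("quality reports expose per-source and mean similarity", {
  set.seed(46)
  p <- phantomPair(size = 64, seed = 9)
  res <- fusePair(p$functional, p$structural,
                  fusionConfig(scales = 2, directions = c(4, 8)))
  q <- qualityReport(res, p$functional, p$structural)
  expect_gte(q$sd, 0)
  expect_true(q$entropy >= 0 && q$entropy <= 8)
  expect_equal(q$ssim$mean, (q$ssim$structural + q$ssim$functional) / 2)
  expect_equal(q$sc$mean, (q$sc$structural + q$sc$functional) / 2)
  expect_gt(q$sc$structural, 0)
})
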