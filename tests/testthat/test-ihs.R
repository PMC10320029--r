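test_that("achromatic pixels map to pure intensity and back", {
  v <- 0.37
  img <- array(v, dim = c(4, 4, 3))
  trip <- rgbToIHS(img)
  expect_equal(intensityPlane(trip), matrix(v, 4, 4))
  expect_equal(max(abs(chromaPlane(trip, 1))), 0)
  expect_equal(max(abs(chromaPlane(trip, 2))), 0)
  expect_equal(ihsToRGB(trip), img)

  zero <- rgbToIHS(array(0, dim = c(4, 4, 3)))
  expect_equal(max(abs(intensityPlane(zero))), 0)
  expect_equal(ihsToRGB(zero), array(0, dim = c(4, 4, 3)))
})

test_that("forward and inverse transforms are mutually inverse linear maps", {
  set.seed(11)
  M <- ihsMatrix()
  Minv <- solve(M)
  for (rep in 1:5) {
    img <- randColorImage(16, 13)
    trip <- rgbToIHS(img)
    # matrix oracle: apply the documented 3x3 forward matrix per pixel
    flat <- matrix(img, ncol = 3) %*% t(M)
    expect_lt(max(abs(as.vector(intensityPlane(trip)) - flat[, 1])), 1e-12)
    expect_lt(max(abs(as.vector(chromaPlane(trip, 1)) - flat[, 2])), 1e-12)
    back <- ihsToRGB(trip)
    expect_lt(max(abs(back - img)), 1e-9)
    expect_lt(max(abs(matrix(flat %*% t(Minv), ncol = 3) -
                      matrix(img, ncol = 3))), 1e-12)
  }
})

test_that("intensity is symmetric under channel permutation", {
  set.seed(12)
  img <- randColorImage(8)
  rot <- img[, , c(2, 3, 1)]
  expect_equal(intensityPlane(rgbToIHS(img)),
               intensityPlane(rgbToIHS(rot)))
})

test_that("intensity substitution leaves chroma untouched and round-trips", {
  set.seed(13)
  img <- randColorImage(12)
  trip <- rgbToIHS(img)

  same <- substituteIntensity(trip, intensityPlane(trip))
  expect_identical(chromaPlane(same, 1), chromaPlane(trip, 1))
  expect_equal(ihsToRGB(same), img)

  zeroed <- substituteIntensity(trip, matrix(0, 12, 12))
  expect_identical(chromaPlane(zeroed, 1), chromaPlane(trip, 1))
  expect_identical(chromaPlane(zeroed, 2), chromaPlane(trip, 2))

  newI <- randImage(12)
  rt <- rgbToIHS(ihsToRGB(substituteIntensity(trip, newI)))
  expect_lt(max(abs(intensityPlane(rt) - newI)), 1e-9)
})

test_that("grayscale input is treated as an achromatic color image", {
  g <- randImage(8)
  trip <- rgbToIHS(g)
  expect_equal(intensityPlane(trip), g)
  expect_equal(max(abs(chromaPlane(trip, 1))), 0)
})

test_that("invalid inputs raise typed errors", {
  expect_error(rgbToIHS(array(0, dim = c(4, 4, 2))),
               class = "shearfuse_shape_error")
  bad <- array(0, dim = c(4, 4, 3)); bad[1] <- NaN
  expect_error(rgbToIHS(bad), class = "shearfuse_value_error")
  trip <- rgbToIHS(randColorImage(6))
  expect_error(substituteIntensity(trip, matrix(0, 5, 6)),
               class = "shearfuse_shape_error")
})
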