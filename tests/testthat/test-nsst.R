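test_that("filter responses are real, partition unity, and behave at DC", {
  bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
  err <- partitionOfUnityError(bank)
  expect_lt(err["total"], 1e-10)
  expect_lt(err["shear"], 1e-10)
  # DC: low-pass responds fully, every band-pass composite not at all
  expect_equal(bank@lowpass[1, 1], 1)
  for (j in 1:2) for (w in bank@shear[[j]])
    expect_equal(bank@bandpass[[j]][1, 1] * w[1, 1], 0)
  expect_true(all(vapply(bank@bandpass, is.numeric, TRUE)))

  one <- shearletFilterBank(16, 16, scales = 1, directions = 2)
  expect_equal(one@scales, 1L)
  expect_length(one@shear[[1]], 2L)
})

test_that("constant images land entirely in the low-frequency band", {
  bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
  dec <- nsstDecompose(matrix(0.6, 32, 32), bank)
  expect_lt(max(abs(lowFreq(dec) - 0.6)), 1e-8)
  hfEnergy <- sum(unlist(lapply(dec@hfs,
    function(s) vapply(s, function(b) sum(b^2), 0))))
  expect_lt(hfEnergy, 1e-12 * sum(0.6^2 * 32 * 32))
})

test_that("decomposition is linear and sub-bands sum back to the input", {
  set.seed(21)
  bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
  x <- randImage(32)
  dx <- nsstDecompose(x, bank)
  d3x <- nsstDecompose(3 * x, bank)
  expect_lt(max(abs(lowFreq(d3x) - 3 * lowFreq(dx))), 1e-10)
  expect_lt(max(abs(highFreq(d3x, 2, 5) - 3 * highFreq(dx, 2, 5))), 1e-10)

  # impulse: direct summation of all bands restores it
  imp <- matrix(0, 32, 32); imp[16, 16] <- 1
  di <- nsstDecompose(imp, bank)
  total <- Reduce(`+`, c(list(lowFreq(di)), unlist(di@hfs, recursive = FALSE)))
  expect_lt(max(abs(total - imp)), 1e-8)

  # reconstruction is linear in the band sets
  y <- randImage(32)
  dy <- nsstDecompose(y, bank)
  dsum <- nsstDecompose(x + y, bank)
  expect_lt(max(abs(nsstReconstruct(dsum) -
                    (nsstReconstruct(dx) + nsstReconstruct(dy)))), 1e-10)
})

test_that("perfect reconstruction holds over random images", {
  set.seed(22)
  bank <- shearletFilterBank(64, 64)
  for (rep in 1:5) {
    x <- randImage(64)
    expect_lt(relL2(nsstReconstruct(nsstDecompose(x, bank)), x), 1e-8)
  }
  # non-square geometry
  bank2 <- shearletFilterBank(48, 64, scales = 2, directions = c(4, 8))
  x <- randImage(48, 64)
  expect_lt(relL2(nsstReconstruct(nsstDecompose(x, bank2)), x), 1e-8)
})

test_that("decomposition commutes with circular shifts", {
  set.seed(23)
  bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
  x <- randImage(32)
  sh <- function(m, dr, dc) {
    m[((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1]
  }
  dx <- nsstDecompose(x, bank)
  dsh <- nsstDecompose(sh(x, 5, 9), bank)
  expect_lt(max(abs(lowFreq(dsh) - sh(lowFreq(dx), 5, 9))), 1e-10)
  expect_lt(max(abs(highFreq(dsh, 2, 3) - sh(highFreq(dx, 2, 3), 5, 9))),
            1e-10)
})

test_that("filtered real images are real up to round-off", {
  set.seed(24)
  bank <- shearletFilterBank(32, 32, scales = 2, directions = c(4, 8))
  x <- randImage(32)
  F <- stats::fft(x)
  worst <- 0
  for (j in 1:2) for (w in bank@shear[[j]]) {
    band <- stats::fft(F * bank@bandpass[[j]] * w, inverse = TRUE) /
      length(x)
    worst <- max(worst, max(abs(Im(band))))
  }
  expect_lt(worst, 1e-12)
})

test_that("misconfigured banks and mismatched shapes are rejected", {
  expect_error(shearletFilterBank(32, 32, scales = 2, directions = c(3, 8)),
               class = "shearfuse_config_error")
  expect_error(shearletFilterBank(8, 8), class = "shearfuse_config_error")
  expect_error(shearletFilterBank(32, 32, scales = 2, directions = 4),
               class = "shearfuse_config_error")
  bank <- shearletFilterBank(32, 32, scales = 1, directions = 2)
  expect_error(nsstDecompose(randImage(16), bank),
               class = "shearfuse_shape_error")
})
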