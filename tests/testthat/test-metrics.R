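test_that("energy-normalized MSE is scale-free and matches hand-computed values", {
  a <- randRaster(c(5L, 5L), 51)
  delta <- centeredImpulse(c(5L, 5L))
  # same image at any positive scale: zero error
  expect_equal(imageMSE(a, delta, 7.3 * a), 0, tolerance = 1e-12)
  expect_equal(imageMSE(2 * a, delta, a), imageMSE(a, delta, a),
               tolerance = 1e-12)
  # orthogonal images: ||a - b||^2 = 2 for unit vectors with a.b = 0
  x <- matrix(0, 2, 2); x[1, 1] <- 3
  y <- matrix(0, 2, 2); y[2, 1] <- 4
  d2 <- centeredImpulse(c(2L, 2L))
  expect_equal(imageMSE(x, d2, y), 2, tolerance = 1e-12)
  # 2x2 worked instance: a = (1,1)/sqrt(2), b = (1,0)
  xx <- matrix(c(1, 0, 1, 0), 2, 2)
  yy <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(imageMSE(xx, d2, yy), (1 / sqrt(2) - 1)^2 + 1 / 2,
               tolerance = 1e-12)
  expect_error(imageMSE(a, delta, matrix(0, 5, 5)), "zero-energy")
})

test_that("SNR follows 20 log10(peak / background mean) and its closed forms", {
  img <- matrix(10, 60, 60)
  img[30, 30] <- 1000
  expect_equal(imageSNR(img, 15L), 40)
  # smax equal to the background mean: 0 dB
  flat <- matrix(5, 40, 40)
  expect_equal(imageSNR(flat, 10L), 0)
  # 2^16 peak over 2^8 background: 20 log10(256) dB
  img2 <- matrix(2^8, 64, 64)
  img2[32, 32] <- 2^16
  expect_equal(imageSNR(img2, 16L), 20 * log10(256), tolerance = 1e-12)
  expect_equal(20 * log10(256), 48.1647993, tolerance = 1e-7)
  # invariant to positive rescaling of the whole image
  expect_equal(imageSNR(0.037 * img, 15L), 40, tolerance = 1e-12)
  expect_error(imageSNR(img - 10, 15L), "positive")
})

test_that("axis-wise Gaussian fitting recovers PSF parameters", {
  # noiseless sampled Gaussian: sigma per axis within 1%
  h <- rasterizePsf(PsfModel(2.7, 1, 0, c(41L, 41L)))
  fit <- fitGaussianPsf(h)
  expect_equal(unname(psfSigma(fit)[1]), 2.7, tolerance = 0.01)
  expect_equal(unname(psfSigma(fit)[2]), 1, tolerance = 0.01)
  expect_equal(fit@center, c(21, 21), tolerance = 0.01)
  # a noisy bead image at the photon-budget noise level: within 10%
  bead <- simulateView(centeredImpulse(c(41L, 41L)),
                       PsfModel(2.7, 1, 0, c(41L, 41L)),
                       noiseMean = 2^8, seed = 12)
  fitn <- fitGaussianPsf(bead)
  expect_equal(unname(psfSigma(fitn)[1]), 2.7, tolerance = 0.1)
  expect_equal(unname(psfSigma(fitn)[2]), 1, tolerance = 0.1)
  # degenerate input
  expect_error(fitGaussianPsf(matrix(1, 9, 9)), "converge")
})

test_that("round trip: rasterized PSF parameters survive fit and rotation moments", {
  for (th in c(0, 35, 90)) {
    h <- rasterizePsf(PsfModel(3, 1.4, th, c(61L, 61L)))
    mom <- psfSecondMoments(h)
    expect_equal(sqrt(max(mom$eigenvalues)), 3, tolerance = 0.02)
    expect_equal(sqrt(min(mom$eigenvalues)), 1.4, tolerance = 0.02)
    # major-axis angle matches the model rotation (mod 180, toward rows)
    dAng <- min(abs(mom$angle - th), abs(mom$angle - th + 180),
                abs(mom$angle - th - 180))
    expect_lt(dAng, 1)
  }
})

test_that("cross orientation reads the arm axes of four-fold kernels", {
  d <- c(61L, 61L)
  mk <- function(th) rasterizePsf(PsfModel(3, 1, th, d))
  # a symmetric cross with arms on the axes: orientation 0
  cross <- (mk(0) + mk(90)) / 2
  expect_lt(abs(crossOrientation(cross)), 1)
  # rotating the whole cross rotates the measure (mod 90)
  cross30 <- (mk(30) + mk(120)) / 2
  expect_equal(crossOrientation(cross30), 30, tolerance = 0.05)
  cross45 <- (mk(45) + mk(135)) / 2
  expect_equal(abs(crossOrientation(cross45)), 45, tolerance = 0.05)
  # a single elongated Gaussian also orients correctly
  expect_lt(abs(crossOrientation(mk(0))), 1)
})

test_that("registered NCC removes the translation/reflection ambiguity", {
  a <- randRaster(c(21L, 21L), 52)
  b <- circShift(reverseRaster(a), c(4, -6))
  reg <- registeredNCC(a, b)
  expect_equal(reg$ncc, 1, tolerance = 1e-10)
  expect_true(reg$flipped)
  reg2 <- registeredNCC(a, circShift(a, c(-2, 5)))
  expect_equal(reg2$ncc, 1, tolerance = 1e-10)
  expect_identical(reg2$shift, c(-2L, 5L))
  # unrelated images score below
  expect_lt(registeredNCC(a, randRaster(c(21L, 21L), 53))$ncc, 0.95)
})
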