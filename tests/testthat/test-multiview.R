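test_that("background subtraction clamps at zero", {
  v <- matrix(c(5, 0, 1, 3), 2, 2, byrow = TRUE)
  dark <- matrix(2, 2, 2)
  expect_equal(subtractBackground(v, dark),
               matrix(c(3, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(subtractBackground(v, matrix(0, 2, 2)), v)
  expect_equal(subtractBackground(v, v), matrix(0, 2, 2))
  expect_error(subtractBackground(v, matrix(0, 3, 2)), "shape")
})

test_that("quarter-turn rotation is lossless and cyclic of order four", {
  m <- matrix(as.numeric(1:12), 3, 4)
  expect_identical(coarseRotate(m, 0), m)
  expect_identical(coarseRotate(m, 4), m)
  expect_identical(coarseRotate(m, 1), oracleRotate90(m))
  expect_identical(coarseRotate(coarseRotate(m, 1), 3), m)
  expect_identical(coarseRotate(m, -1), coarseRotate(m, 3))
  expect_identical(sort(as.vector(coarseRotate(m, 2))), sort(as.vector(m)))
})

test_that("cross-correlation registration recovers constructed shifts", {
  ref <- randRaster(c(33L, 33L), 21)
  expect_identical(registerTranslation(ref, ref), c(0L, 0L))
  mov <- circShift(ref, c(5, -3))
  s <- registerTranslation(ref, mov)
  expect_identical(s, c(5L, -3L))
  # compensating the opposite shift restores the reference exactly
  expect_equal(applyShift(mov, -s), ref)
  # impulse pair: shift read off directly
  d <- c(21L, 21L)
  refi <- centeredImpulse(d)
  movi <- matrix(0, d[1], d[2])
  movi[centerIndex(d)[1] + 1, centerIndex(d)[2] + 2] <- 1
  expect_identical(registerTranslation(refi, movi), c(1L, 2L))
  expect_error(registerTranslation(matrix(0, 5, 5), refi[1:5, 1:5]),
               "all-zero")
})

test_that("registration followed by compensation peaks the cross-correlation at zero shift", {
  ref <- randRaster(c(29L, 29L), 22)
  for (s in list(c(4, 9), c(-7, 2))) {
    mov <- circShift(ref, s)
    comp <- applyShift(mov, -registerTranslation(ref, mov))
    cc <- fftCorrelate(ref, comp)
    expect_identical(arrayInd(which.max(cc), dim(cc))[1, ],
                     centerIndex(dim(cc)))
  }
})

test_that("non-wrapping shifts zero the wrapped-in band", {
  x <- matrix(1, 4, 4)
  y <- applyShift(x, c(1, -2), wrap = FALSE)
  expect_equal(y[1, ], rep(0, 4))       # wrapped-in bottom row zeroed
  expect_equal(y[2, ], c(1, 1, 0, 0))   # wrapped-in right columns zeroed
  expect_equal(sum(y == 0), 4 + 8 - 2)
})

test_that("aligned fusion of cyclically shifted copies restores the original", {
  base <- randRaster(c(33L, 33L), 23)
  shifts <- list(c(0, 0), c(6, -2), c(-4, 8), c(3, 3))
  vs <- ViewSet(lapply(shifts, function(s) circShift(base, s)))
  al <- alignViews(vs)
  expect_equal(al$shifts[2, ], c(6L, -2L))
  fused <- fuseAligned(al$views)
  expect_equal(fused, base, tolerance = 1e-12)
  # fusion preserves mean intensity
  vs2 <- ViewSet(list(randRaster(c(9L, 9L), 1), randRaster(c(9L, 9L), 2)))
  expect_equal(mean(fuseAligned(vs2)),
               mean(vapply(viewRasters(vs2), mean, numeric(1))))
  expect_equal(fuseAligned(list(matrix(2, 1, 1), matrix(4, 1, 1))),
               matrix(3, 1, 1))
  expect_error(fuseAligned(list()), "empty")
})

test_that("averaged absolute autocorrelation fuses without any alignment", {
  base <- randRaster(c(25L, 25L), 24)
  blur <- rasterizePsf(PsfModel(2, 1, 0, c(25L, 25L)))
  v1 <- fftConvolve(base, blur)
  v2 <- fftConvolve(base, t(blur))
  chi <- averageAutocorrelation(list(v1, v2))
  # equals the mean of the brute-force per-view autocorrelations
  expect_equal(chi, (abs(oracleCorrelate(v1, v1)) +
                     abs(oracleCorrelate(v2, v2))) / 2, tolerance = 1e-8)
  # invariant under independent cyclic translation of each view
  chiShifted <- averageAutocorrelation(list(circShift(v1, c(7, -5)),
                                            circShift(v2, c(-2, 9))))
  expect_equal(chiShifted, chi, tolerance = 1e-9)
  # m identical views reduce to a single |autocorrelation|
  expect_equal(averageAutocorrelation(list(v1, v1)),
               abs(autocorrelate(v1)), tolerance = 1e-12)
  # point symmetry of the fusion target
  expect_equal(chi, reverseRaster(chi), tolerance = 1e-9)
  expect_error(averageAutocorrelation(list()), "empty")
})

test_that("zero-flooring replaces exact zeros by one hundredth of the mean", {
  x <- matrix(c(0, 4, 2, 0), 2, 2)
  y <- floorZeros(x)
  expect_equal(y[x == 0], rep(mean(x) / 100, 2))  # (6/4)/100 = 0.015
  expect_equal(y[1, 2], 2)
  expect_equal(sum(y == 0), 0)
  xp <- matrix(1:4, 2, 2) * 1.0
  expect_identical(floorZeros(xp), xp)
  expect_error(floorZeros(matrix(0, 3, 3)), "all-zero")
})
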