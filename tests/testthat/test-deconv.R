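test_that("single multiplicative steps match the direct-sum oracles on 1D instances", {
  # 8-pixel 1D instances represented as 8 x 1 rasters
  set.seed(31)
  o <- matrix(runif(8) + 0.2, 8, 1)
  h <- matrix(c(0.1, 0.2, 0.4, 0.2, 0.05, 0.03, 0.01, 0.01), 8, 1)
  h <- h / sum(h)
  f <- fftConvolve(o, h)
  expect_equal(rlStep(o, f, h), oracleRLStep(o, f, h), tolerance = 1e-8)
  chi <- abs(autocorrelate(f))
  H <- abs(autocorrelate(h))
  K <- auKernel(o, H)
  expect_equal(auStep(o, chi, K), oracleAUStep(o, chi, H), tolerance = 1e-8)
  # and on a 2D instance
  o2 <- randRaster(c(6L, 6L), 32) + 0.1
  h2 <- rasterizePsf(PsfModel(1.2, 0.7, 20, c(7L, 7L)))[1:6, 1:6]
  h2 <- h2 / sum(h2)
  f2 <- fftConvolve(o2, h2)
  expect_equal(rlStep(o2, f2, h2), oracleRLStep(o2, f2, h2),
               tolerance = 1e-8)
})

test_that("Richardson-Lucy fixed points and flux conservation hold", {
  f <- randRaster(c(9L, 9L), 33) + 0.1
  delta <- centeredImpulse(c(9L, 9L))
  # impulse kernel: the measurement is its own fixed point
  expect_equal(rlStep(f, f, delta), f, tolerance = 1e-12)
  # consistent data: ratio is one, flux is exactly conserved
  h <- rasterizePsf(PsfModel(1.5, 1, 0, c(9L, 9L)))
  o <- randRaster(c(9L, 9L), 34) + 0.1
  f2 <- fftConvolve(o, h)
  expect_equal(sum(rlStep(o, f2, h)), sum(o), tolerance = 1e-10)
})

test_that("RL deconvolution descends on a consistent problem and resolves two points", {
  d <- c(33L, 33L)
  o <- matrix(0, d[1], d[2])
  o[c(14, 20), 17] <- 1            # two points 6 px apart along rows
  h <- rasterizePsf(PsfModel(3, 3, 0, d))
  f <- fftConvolve(o, h)
  res <- rlDeconvolve(f, h, nIter = 500, recordMSE = TRUE)
  # monotone-improving fit: final MSE strictly below the initial one
  expect_lt(res$mseTrace[100], res$mseTrace[1])
  expect_lt(tail(res$mseTrace, 1), res$mseTrace[100])
  # initial guess is a single hump, the estimate separates the two peaks
  prof0 <- f[, 17]
  expect_equal(length(which(diff(sign(diff(prof0))) == -2)), 1)
  prof <- res$estimate[, 17]
  expect_gt(min(prof[14], prof[20]), prof[17] / 0.8)
  # impulse kernel: estimate equals the measurement at every iteration
  resi <- rlDeconvolve(f, centeredImpulse(d), nIter = 3, o0 = f)
  expect_equal(resi$estimate, f, tolerance = 1e-10)
  expect_error(rlDeconvolve(f, h, 10, o0 = -f), "nonnegative")
})

test_that("the effective AU kernel follows its defining convention", {
  cur <- randRaster(c(7L, 7L), 35) + 0.1
  delta <- centeredImpulse(c(7L, 7L))
  # correlation with a centered impulse is coordinate reversal
  expect_equal(auKernel(cur, delta), reverseRaster(cur) / sum(cur),
               tolerance = 1e-10)
  H <- abs(autocorrelate(rasterizePsf(PsfModel(1.5, 1, 0, c(7L, 7L)))))
  K <- auKernel(cur, H)
  expect_equal(sum(K), 1, tolerance = 1e-12)
  expect_equal(K * sum(fftCorrelate(cur, H)), fftCorrelate(cur, H),
               tolerance = 1e-10)
  expect_equal(K * sum(oracleCorrelate(cur, H)) , oracleCorrelate(cur, H),
               tolerance = 1e-8)
  expect_error(auKernel(matrix(0, 4, 4), matrix(0, 4, 4)), "all-zero")
})

test_that("AU updates preserve nonnegativity and fix consistent data", {
  o <- randRaster(c(8L, 8L), 36) + 0.1
  K <- rasterizePsf(PsfModel(1.3, 0.9, 45, c(9L, 9L)))[1:8, 1:8]
  K <- K / sum(K)
  chi <- fftConvolve(o, K)
  expect_equal(auStep(o, chi, K), o, tolerance = 1e-10)
  expect_gte(min(auStep(o, abs(randRaster(c(8L, 8L), 37)), K)), 0)
})

test_that("known-PSF AU inversion recovers a sparse object up to shift and reflection", {
  d <- c(63L, 63L)
  set.seed(38)
  o <- matrix(0, d[1], d[2])
  idx <- cbind(sample(15:49, 12), sample(15:49, 12))
  o[idx] <- runif(12, 0.5, 1)
  h <- rasterizePsf(PsfModel(2, 1.2, 30, d))
  meas <- fftConvolve(o, h)
  chi <- abs(autocorrelate(meas))
  # start from the measurement (a flat start is a stationary saddle: a
  # constant estimate yields a constant effective kernel, which maps every
  # update factor to its own mean)
  o0 <- floorZeros(pmax(meas, 0))
  # AU converges slowly by design; ~8e3 iterations for a clean recovery
  res <- auDeconvolve(chi, h, o0, nIter = 8000, recordResidual = TRUE)
  # residual falls and is non-increasing over the first 50 iterations
  expect_lt(tail(res$residualTrace, 1), res$residualTrace[1])
  expect_true(all(diff(res$residualTrace[1:50]) <= 1e-9 * res$residualTrace[1]))
  # recovery up to the trivial translation/reflection ambiguity
  reg <- registeredNCC(o, res$estimate)
  expect_gte(reg$ncc, 0.95)
  # consistent fixed point: impulse PSF and the exact object keep the
  # (energy-normalized) autocorrelation residual at numerical zero
  chid <- abs(autocorrelate(o))
  resd <- auDeconvolve(chid, centeredImpulse(d), o, nIter = 5,
                       recordResidual = TRUE)
  expect_lt(max(resd$residualTrace), 1e-10)
})

test_that("the C++ iteration cores reproduce the pure-R update path exactly", {
  set.seed(39)
  f <- matrix(runif(81) + 0.1, 9, 9)
  h <- rasterizePsf(PsfModel(1.5, 0.8, 30, c(9L, 9L)))
  oR <- f
  for (i in 1:25) oR <- rlStep(oR, f, h)
  oc <- rlDeconvolve(f, h, nIter = 25, o0 = f)
  expect_equal(oc$estimate, oR, tolerance = 1e-12)
  chi <- abs(autocorrelate(f))
  H <- abs(autocorrelate(h))
  aR <- f
  for (i in 1:25) aR <- auStep(aR, chi, auKernel(aR, H))
  ac <- auDeconvolve(chi, h, f, nIter = 25)
  expect_equal(ac$estimate, aR, tolerance = 1e-12)
})

test_that("Blind-AU alternation matches its R reference and is stationary at the truth", {
  set.seed(40)
  d <- c(21L, 21L)
  o <- matrix(runif(prod(d)) + 0.05, d[1], d[2])
  h <- rasterizePsf(PsfModel(1.8, 1, 0, d))
  chi <- abs(autocorrelate(fftConvolve(o, h)))
  # R reference: two cycles of (3 object, 2 PSF) iterations
  oB <- o; hB <- h
  for (k in 1:2) {
    Hk <- abs(autocorrelate(hB))
    for (i in 1:3) oB <- auStep(oB, chi, auKernel(oB, Hk))
    Ok <- abs(autocorrelate(oB))
    for (i in 1:2) hB <- auStep(hB, chi, auKernel(hB, Ok))
    hB <- hB / sum(hB)
  }
  st <- blindAU(chi, o, h, BlindSchedule(3, 2, 2, 2))
  expect_equal(objectEstimate(st), oB, tolerance = 1e-12)
  expect_equal(psfEstimate(st), hB, tolerance = 1e-12)
  # ground-truth initialization: stationary after the one-cycle scale burn-in
  st1 <- blindAU(chi, o, h, BlindSchedule(5, 5, 1, 1))
  st2 <- blindAU(chi, objectEstimate(st1), psfEstimate(st1),
                 BlindSchedule(5, 5, 1, 1))
  relO <- max(abs(objectEstimate(st2) - objectEstimate(st1))) /
    max(objectEstimate(st1))
  relH <- max(abs(psfEstimate(st2) - psfEstimate(st1))) /
    max(psfEstimate(st1))
  expect_lt(relO, 1e-6)
  expect_lt(relH, 1e-6)
  expect_error(blindAU(chi, o, h, BlindSchedule(5, 5, 0, 1)), ">= 1")
})

test_that("solver iterates stay nonnegative and conserve flux over long runs", {
  set.seed(41)
  d <- c(31L, 31L)
  o <- matrix(runif(prod(d)) + 0.02, d[1], d[2])
  h <- rasterizePsf(PsfModel(2, 1, 0, d))
  f <- fftConvolve(o, h)
  # RL: flux equals sum(f) from the first iteration on; drift < 1e-6/1e3 iters
  r1 <- rlDeconvolve(f, h, nIter = 1, o0 = f)
  r1000 <- rlDeconvolve(f, h, nIter = 1000, o0 = f)
  expect_gte(min(r1000$estimate), 0)
  expect_lt(abs(sum(r1000$estimate) - sum(r1$estimate)) / sum(r1$estimate),
            1e-6)
  # AU: same property against sum(chi)
  chi <- abs(autocorrelate(f))
  a1 <- auDeconvolve(chi, h, f, nIter = 1)
  a1000 <- auDeconvolve(chi, h, f, nIter = 1000)
  expect_gte(min(a1000$estimate), 0)
  expect_lt(abs(sum(a1000$estimate) - sum(a1$estimate)) / sum(a1$estimate),
            1e-6)
})

test_that("schedules expose their total iteration count", {
  expect_equal(totalIterations(BlindSchedule(50, 50, 2000)), 2e5)
  expect_error(BlindSchedule(0, 50, 10), ">= 1")
})
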