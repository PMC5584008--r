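test_that("arch matches its closed form, is symmetric and bounded", {
  expect_identical(arch(0), 0)
  expect_identical(arch(1), 0)
  expect_equal(arch(0.5), 1 / sqrt(2 * pi), tolerance = 1e-15)
  x <- seq(0.001, 0.999, length.out = 501)
  expect_equal(arch(x), arch(1 - x), tolerance = 1e-14)
  # printed formula via an independent inverse error function
  erfinv <- function(y) qnorm((y + 1) / 2) / sqrt(2)
  ref <- exp(-erfinv(2 * x - 1)^2) / sqrt(2 * pi)
  expect_lt(max(abs(arch(x) - ref)), 1e-12)
  expect_error(arch(-0.1), "\\[0, 1\\]")
  expect_error(arch(1.1), "\\[0, 1\\]")
})

test_that("projection is exact on the curve and at the endpoints", {
  m <- TransitionModel("TT", 0, 680, sigmaOmega = 1, theta = 1.2)
  xs <- c(0.1, 0.3, 0.5, 0.77, 0.95)
  I <- m@L + xs * (m@H - m@L)
  gI <- (m@H - m@L) * arch(xs)        # sigma = 1: gI = (H-L) arch(x)
  pr <- projectToArch(I, gI, m)
  expect_lt(max(abs(pr$x - xs)), 1e-9)
  expect_equal(pr$IPrime, I, tolerance = 1e-6)
  expect_equal(pr$tLow + pr$tHigh, rep(1, 5))

  ends <- projectToArch(c(m@L, m@H), c(0, 0), m)
  expect_lt(abs(ends$tLow[1] - 1), 1e-9)
  expect_lt(abs(ends$tHigh[2] - 1), 1e-9)
  expect_error(projectToArch(1, 1, TransitionModel("TT", 5, 5.1)), NA)
  expect_error(TransitionModel("TT", 5, 5), "L < H")
})

test_that("projection agrees with the exhaustive nearest-point search", {
  m <- TransitionModel("TA", -950, 710, sigmaOmega = 1, theta = 1.3)
  set.seed(4)
  n <- 2000
  I <- runif(n, m@L - 300, m@H + 300)
  gI <- runif(n, 0, 0.6 * (m@H - m@L))
  pr <- projectToArch(I, gI, m)
  xs <- pmin(pmax((I - m@L) / (m@H - m@L), 0), 1)
  ys <- abs(gI) / (m@H - m@L)
  brute <- ecleanse:::.arch_brute(xs, ys, m@theta, 100001L)
  expect_lt(max(abs(pr$x - brute)), 1e-3)
})

test_that("bases are estimated from interior masks and errors are named", {
  ph <- cachedPhantom("at_pool", shape = c(40L, 64L, 64L), seed = 5L)
  pre <- preprocessVolume(ph$volume)
  a <- voxelData(pre$volume)
  lum <- voxelData(pre$lumen) > 0
  masks <- list(air = a < -600 & lum, ftm = a > 200 & lum,
                st = a >= -100 & a <= 100 & lum)
  models <- estimateBases(pre$volume, masks)
  expect_equal(models$TA@L, -950, tolerance = 0.02)
  # the tagged base sits below the pure mean: the thresholded mask keeps
  # partial-volume voxels that one erosion cannot fully exclude
  expect_true(models$TA@H > 640 && models$TA@H < 720)
  # soft-tissue reference is pseudo-enhancement-biased upward of 20 HU
  expect_true(models$TT@L > 0 && models$TT@L < 80)
  expect_identical(models$SA@L, models$TA@L)
  expect_identical(models$SA@H, models$TT@L)

  expect_error(estimateBases(pre$volume,
                             list(air = masks$air, ftm = masks$ftm,
                                  st = array(FALSE, dim(a)))),
               "'st'")

  # constant regions: bases recovered exactly
  d2 <- c(6, 6, 9)
  blk <- array(0, d2)
  blk[, , 1:3] <- -950; blk[, , 7:9] <- 700
  mk <- function(sel) { m <- array(FALSE, d2); m[, , sel] <- TRUE; m }
  mods <- estimateBases(HUVolume(blk),
                        list(air = mk(1:3), st = mk(4:6), ftm = mk(7:9)),
                        erode = 0)
  expect_identical(mods$TA@H, 700)
  expect_identical(mods$TA@L, -950)
  expect_identical(mods$TT@L, 0)
})

test_that("theta calibration matches the apex of a noiseless edge", {
  # analytic erf edge with blur equal to the sampling scale
  m <- TransitionModel("TT", 0, 680, sigmaOmega = 1)
  x <- seq(-4, 4, by = 0.05)
  I <- m@L + (m@H - m@L) * pnorm(x / 1)
  gI <- (m@H - m@L) * dnorm(x / 1)
  th <- estimateTheta(I, gI, m)
  expect_equal(th, 1, tolerance = 0.05)
  # doubling the gradients halves theta
  expect_equal(estimateTheta(I, 2 * gI, m), th / 2, tolerance = 1e-12)
  expect_error(estimateTheta(I[1:10], gI[1:10], m), "at least 50")
  expect_error(estimateTheta(I, gI * 0, m), "zero")
})

test_that("three-material averaging is exact and always sums to one", {
  even <- list(tLow = 0.5, tHigh = 0.5)
  tf <- threeFractions(even, even, even)
  expect_equal(unlist(tf), c(tAir = 1, tST = 1, tTR = 1) / 3)

  # clamped pure-tagged voxel
  tf2 <- threeFractions(list(tLow = 0, tHigh = 1),   # TA
                        list(tLow = 0, tHigh = 1),   # TT
                        list(tLow = 0, tHigh = 1))   # SA
  expect_equal(unlist(tf2), c(tAir = 0, tST = 1 / 3, tTR = 2 / 3))

  set.seed(9)
  x1 <- runif(1e4); x2 <- runif(1e4); x3 <- runif(1e4)
  tf3 <- threeFractions(list(tLow = x1, tHigh = 1 - x1),
                        list(tLow = x2, tHigh = 1 - x2),
                        list(tLow = x3, tHigh = 1 - x3))
  expect_lt(max(abs(tf3$tAir + tf3$tST + tf3$tTR - 1)), 1e-12)

  expect_error(threeFractions(list(tLow = 0.5, tHigh = 0.6), even, even),
               "sum to 1")
})
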