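mTT0 <- TransitionModel("TT", 0, 710)
mTA0 <- TransitionModel("TA", -1000, 710)

test_that("replacement formulas reproduce their algebra", {
  # pure soft-tissue side: the tagged term vanishes
  expect_equal(sttReplacement(1, 0, 0.7, mTT0, mTA0), 0)
  # strong-edge blend moves the tagged contribution onto the air base
  expect_equal(sttReplacement(0.8, 0.2, 1, mTT0, mTA0), -200)
  # three-material rule
  expect_equal(tjunctionReplacement(0, 0, 1, mTA0, mTT0), -1000)
  expect_equal(tjunctionReplacement(1/3, 1/3, 1/3, mTA0, mTT0),
               -666.6667, tolerance = 1e-6)
  expect_equal(tjunctionReplacement(0, 1, 0, mTA0, mTT0), mTT0@L)
})

test_that("the tissue-side rule honors its gate", {
  d <- c(5, 7, 7)
  a <- array(0, d)
  a[3, 4, 4] <- 90     # below the 100 HU gate
  a[3, 4, 5] <- 150    # above the gate
  vol <- HUVolume(a)
  mask <- array(FALSE, d); mask[3, 4, 4:5] <- TRUE
  fww <- array(0.5, d)
  res <- replaceSTT(vol, mask, list(tLow = c(0.9, 0.9), tHigh = c(0.1, 0.1)),
                    fww, list(TA = mTA0, TT = mTT0), gate = 100,
                    blendApex = 0.5)
  out <- voxelData(res$volume)
  expect_identical(out[3, 4, 4], 90)                      # gated out
  expect_equal(out[3, 4, 5], 0.9 * 0 + 0.1 * (-1000))     # w = 1
  expect_identical(sum(res$replaced), 1L)

  # negative GDSD never qualifies
  fww2 <- array(-0.5, d)
  res2 <- replaceSTT(vol, mask, list(tLow = c(0.9, 0.9), tHigh = c(0.1, 0.1)),
                     fww2, list(TA = mTA0, TT = mTT0))
  expect_identical(voxelData(res2$volume), a)
})

test_that("the three-material rule validates fraction consistency", {
  d <- c(4, 4, 4)
  vol <- HUVolume(array(500, d))
  mask <- array(FALSE, d); mask[2, 2, 2] <- TRUE
  good <- list(tAir = 0.2, tST = 0.3, tTR = 0.5)
  res <- replaceTJunction(vol, mask, good, list(TA = mTA0, TT = mTT0))
  expect_equal(voxelData(res$volume)[2, 2, 2], 0.7 * -1000 + 0.3 * 0)
  bad <- list(tAir = 0.2, tST = 0.3, tTR = 0.6)
  expect_error(replaceTJunction(vol, mask, bad, list(TA = mTA0, TT = mTT0)),
               "sum to 1")
})

test_that("wall smoothing is local and matches a reference convolution", {
  d <- c(9, 9, 9)
  set.seed(3)
  a <- array(rnorm(prod(d), sd = 300), d)
  vol <- HUVolume(a)
  expect_identical(voxelData(enhanceWall(vol, array(FALSE, d))), a)

  band <- array(FALSE, d); band[4:6, 4:6, 4:6] <- TRUE
  sm <- enhanceWall(vol, band, sigma = 0.5)
  ref <- bruteGaussSmooth(a, 0.5)
  expect_equal(voxelData(sm)[band], ref[band], tolerance = 1e-10)
  expect_identical(voxelData(sm)[!band], a[!band])
})

test_that("a volume with an empty lumen passes through unchanged", {
  vol <- HUVolume(array(50, c(8, 8, 8)))
  expect_warning(res <- runEC(vol), "unchanged")
  expect_identical(voxelData(res$volume), voxelData(vol))
})

test_that("cleansing removes the pool, keeps thin tissue, and stays local", {
  ph <- cachedPhantom("combined", shape = c(64L, 64L, 64L), seed = 11L)
  res <- runEC(ph$volume)
  out <- voxelData(res$volume)
  f <- ph$truth@features
  # tagged material collapses far below the soft-tissue range
  expect_lt(median(out[f$pureFTM]), -600)
  # thin soft-tissue layer sandwiched between air and tagging survives
  expect_true(all(out[f$attCenterline] > -300))
  # locality: every changed voxel lies inside the detected lumen
  pre <- preprocessVolume(ph$volume)
  lum <- voxelData(pre$lumen) > 0
  changed <- out != voxelData(ph$volume)
  expect_identical(sum(changed & !lum), 0L)
  # QC bookkeeping is consistent
  qc <- res$qc
  expect_identical(as.integer(qc@counts[["rewritten_stt"]] >= 0), 1L)
  expect_lt(qc@counts[["ftm_after"]], qc@counts[["ftm_before"]])
  expect_identical(nrow(qc@bases), 3L)
})
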