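test_that("outside-air removal floods exactly the boundary-connected air", {
  # all-air volume: everything is connected to the boundary
  vol <- HUVolume(array(-1000, c(6, 6, 6)))
  res <- removeOutsideAir(vol)
  expect_true(all(voxelData(res$volume) == -100))

  # hollow soft-tissue box: air inside and outside; only outside flooded
  d <- c(10, 10, 10)
  a <- array(-1000, d)
  a[3:8, 3:8, 3:8] <- 0           # box walls
  a[5:6, 5:6, 5:6] <- -1000       # enclosed air
  vol <- HUVolume(a)
  res <- removeOutsideAir(vol)
  seeds <- array(FALSE, d)
  seeds[c(1, d[1]), , ] <- TRUE; seeds[, c(1, d[2]), ] <- TRUE
  seeds[, , c(1, d[3])] <- TRUE
  oracle <- bruteFlood(a < -100, seeds, conn = 6)
  expect_identical(voxelData(res$mask) > 0, oracle)
  out <- voxelData(res$volume)
  expect_true(all(out[oracle] == -100))
  expect_true(all(out[5:6, 5:6, 5:6] == -1000))   # interior untouched

  # no outside air at all
  vol <- HUVolume(array(50, c(5, 5, 5)))
  expect_warning(res <- removeOutsideAir(vol), "no outside air")
  expect_identical(voxelData(res$volume), voxelData(vol))
})

test_that("lung removal picks the end segment with more inside air", {
  d <- c(24, 16, 16)
  a <- array(0, d)
  a[2:6, 4:10, 4:10] <- -900      # lung blob in the first 10 slices
  vol <- HUVolume(a)
  outside <- LabelMap(array(0L, d))
  expect_warning(res <- removeLungs(vol, outside), NA)
  expect_true(all(voxelData(res$volume)[2:6, 4:10, 4:10] == -100))
  expect_identical(sort(unique(res$slices)), 2:6)

  # no inside air: nothing happens
  res2 <- removeLungs(HUVolume(array(0, d)), outside)
  expect_identical(sum(voxelData(res2$mask)), 0L)

  # tie: equal blobs at both ends; the first segment wins
  a3 <- array(0, d)
  a3[2:4, 4:6, 4:6] <- -900
  a3[21:23, 4:6, 4:6] <- -900
  res3 <- removeLungs(HUVolume(a3), outside)
  out3 <- voxelData(res3$volume)
  expect_true(all(out3[2:4, 4:6, 4:6] == -100))
  expect_true(all(out3[21:23, 4:6, 4:6] == -900))   # last-segment blob stays
})

test_that("bone removal grows from bright seeds in the lung slices only", {
  d <- c(24, 16, 16)
  a <- array(0, d)
  # rib ring spanning the lung slices, touching the volume edge
  a[2:8, 2:3, ] <- 1000
  # disconnected tagged pool in distal slices
  a[18:20, 8:10, 8:10] <- 700
  vol <- HUVolume(a)
  res <- removeBones(vol, lungSlices = 2:8)
  seeds <- array(FALSE, d); seeds[2:8, , ] <- a[2:8, , ] > 200
  oracle <- bruteFlood(a > 200, seeds, conn = 6)
  expect_identical(voxelData(res$mask) > 0, oracle)
  out <- voxelData(res$volume)
  expect_true(all(out[2:8, 2:3, ] == -100))
  expect_true(all(out[18:20, 8:10, 8:10] == 700))   # pool intact

  # all soft tissue: unchanged
  res2 <- removeBones(HUVolume(array(0, d)), lungSlices = 2:8)
  expect_identical(voxelData(res2$volume), array(0, d))
})

test_that("lumen is the r=3 spherical dilation of air and tagged voxels", {
  d <- c(11, 11, 11)
  a <- array(0, d)
  a[6, 6, 6] <- -1000
  lum <- detectColonicLumen(HUVolume(a))
  co <- expand.grid(z = 1:11, y = 1:11, x = 1:11)
  ball <- (co$z - 6)^2 + (co$y - 6)^2 + (co$x - 6)^2 <= 9
  expect_identical(voxelData(lum) > 0, array(ball, d))

  # air and tagged blocks with a 3-voxel partial-volume gap merge
  a2 <- array(0, c(9, 12, 9))
  a2[4:6, 2:4, 4:6] <- -1000
  a2[4:6, 8:10, 4:6] <- 700
  lum2 <- detectColonicLumen(HUVolume(a2))
  lab <- labelComponents(voxelData(lum2) > 0, 6)
  expect_identical(max(lab), 1L)   # one connected lumen over the gap

  expect_warning(empty <- detectColonicLumen(HUVolume(array(0, d))),
                 "empty lumen")
  expect_identical(sum(voxelData(empty)), 0L)
})

test_that("preprocessing is idempotent and clears sub-tissue HU outside the lumen", {
  ph <- cachedPhantom("torso", shape = c(40L, 64L, 64L), seed = 3L)
  p1 <- preprocessVolume(ph$volume)
  p2 <- preprocessVolume(p1$volume)
  expect_identical(voxelData(p2$volume), voxelData(p1$volume))
  lum <- voxelData(p1$lumen) > 0
  expect_identical(sum(voxelData(p1$volume) < -100 & !lum), 0L)
  # lumen covers air and tagged voxels and stays within 3 voxels of them
  a <- voxelData(p1$volume)
  core <- (a < -600) | (a > 200)
  expect_true(all(lum[core]))
  expect_true(all((dilateMask(core, 3) | !lum)))
})
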