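# Toy scene: air block over a tagged slab inside a soft-tissue casing,
# values chosen so threshold masks are unambiguous.
airOnFtmToy <- function() {
  d <- c(5, 12, 12)
  a <- array(0, d)
  a[2:4, 3:6, 3:10] <- -1000    # air
  a[2:4, 7:9, 3:10] <- 700      # tagged slab directly below
  HUVolume(a)
}

test_that("ambiguous layers are the air-hugging voxels with tagged neighbors", {
  vol <- airOnFtmToy()
  lum <- detectColonicLumen(vol)
  comps <- detectAmbiguousLayers(vol, lum)
  expect_length(comps, 1L)
  amb <- attr(comps, "mask")
  # oracle: 26-neighbor scan on the raw masks
  a <- voxelData(vol)
  air <- a < -600; ftm <- a > 200
  edge <- (voxelData(lum) > 0) & !air & bruteAdjacent26(air)
  oracle <- edge & bruteAdjacent26(ftm)
  expect_identical(amb, oracle)
  expect_true(all(amb[2:4, 7, 3:10]))   # the first tagged row

  # air surrounded by soft tissue only: no ambiguous layers
  d <- c(5, 10, 10)
  a2 <- array(0, d); a2[2:4, 4:6, 4:6] <- -1000
  vol2 <- HUVolume(a2)
  expect_length(detectAmbiguousLayers(vol2, detectColonicLumen(vol2)), 0L)
})

test_that("a flat top interface and a separate side sheet give two components", {
  d <- c(3, 18, 18)
  a <- array(0, d)
  a[, 4:9, 8:15] <- -1000       # air over the open pool
  a[, 10:13, 11:15] <- 700      # pool with a flat top interface
  a[, 10:13, 4:6] <- 700        # covered pool (soft tissue above)
  a[, 10:13, 7] <- -120         # thin sheet flanking the covered pool
  a[, 10:13, 8:9] <- -1000      # air on the other side of the sheet
  vol <- HUVolume(a)
  comps <- detectAmbiguousLayers(vol, detectColonicLumen(vol))
  expect_length(comps, 2L)
})

test_that("connectivity counting separates flat-atop from along-the-bend layers", {
  d <- c(3, 16, 16)
  pools <- array(0L, d)
  pools[2, 8:12, 4:12] <- 1L
  # horizontal 1-voxel layer lying on the pool
  layerH <- new("LayerComponent", id = 1L,
                voxels = cbind(2L, 7L, 4:12), cls = "ambiguous")
  clH <- classifyLayer(layerH, pools, leap = 5L)
  expect_identical(layerClass(clH), "AT")
  expect_identical(clH@connVertical, 9L)
  expect_identical(clH@connHorizontal, 0L)

  # vertical 1-voxel layer flanking the pool side
  layerV <- new("LayerComponent", id = 2L,
                voxels = cbind(2L, 8:12, 3L), cls = "ambiguous")
  clV <- classifyLayer(layerV, pools, leap = 5L)
  expect_identical(layerClass(clV), "ATT")
  expect_identical(clV@connHorizontal, 5L)
  expect_identical(clV@connVertical, 0L)

  # equal counts fall to AT (strict inequality removes only): an
  # L-shaped pool hit once rightward and once downward
  poolsT <- array(0L, d)
  poolsT[2, 8, 9] <- 1L; poolsT[2, 9, 8] <- 1L; poolsT[2, 9, 9] <- 1L
  layerT <- new("LayerComponent", id = 3L,
                voxels = cbind(2L, 8L, 8L), cls = "ambiguous")
  clT <- classifyLayer(layerT, poolsT, leap = 5L)
  expect_identical(clT@connHorizontal, 1L)
  expect_identical(clT@connVertical, 1L)
  expect_identical(layerClass(clT), "AT")

  # no adjacent pool anywhere: caller bug
  empty <- array(0L, d)
  expect_error(classifyLayer(layerH, empty), "no adjacent tagged pool")
})

test_that("rotating a scene in-slice swaps the decision", {
  d <- c(3, 16, 16)
  a <- array(0, d)
  a[, 8:12, 4:12] <- 700
  a[, 7, 4:12] <- -120
  a[, 5:6, 4:12] <- -1000
  vol <- HUVolume(a)
  lay <- identifyATLayers(vol, detectColonicLumen(vol))
  expect_true(sum(lay$atMask) > 0 && sum(lay$attMask) == 0)

  # 90-degree in-slice rotation: swap down and right axes
  volR <- HUVolume(aperm(voxelData(vol), c(1, 3, 2)))
  layR <- identifyATLayers(volR, detectColonicLumen(volR))
  expect_true(sum(layR$attMask) > 0 && sum(layR$atMask) == 0)
})

test_that("STT layers are the tagged vicinity minus air and AT voxels", {
  d <- c(5, 14, 14)
  a <- array(0, d)
  a[2:4, 6:9, 4:10] <- 700      # slab on a soft-tissue floor
  a[2:4, 3:5, 4:10] <- -1000    # air above
  vol <- HUVolume(a)
  lum <- detectColonicLumen(vol)
  lay <- identifyATLayers(vol, lum)
  stt <- detectSTTLayers(vol, lum, lay$atMask)
  mask <- attr(stt, "mask")
  # independent set computation with naive operators
  ftm <- voxelData(vol) > 200; air <- voxelData(vol) < -600
  expected <- (bruteDilate(ftm, 2) & !bruteErode(ftm, 1)) & !air & !lay$atMask
  expect_identical(mask, expected)
  # the shell below the slab (soft-tissue side) is present
  expect_true(all(mask[2:4, 10, 4:10]))
  # and nothing above the AT layer (air side) survives
  expect_false(any(mask & air))

  # no tagged material: empty
  vol2 <- HUVolume(array(0, d))
  lum2 <- suppressWarnings(detectColonicLumen(vol2))
  expect_length(detectSTTLayers(vol2, lum2, array(FALSE, d)), 0L)
})

test_that("every ambiguous voxel ends in exactly one of AT/ATT on phantoms", {
  ph <- cachedPhantom("att_bend", shape = c(40L, 64L, 64L), seed = 5L)
  pre <- preprocessVolume(ph$volume)
  lay <- identifyATLayers(pre$volume, pre$lumen)
  expect_identical(lay$atMask | lay$attMask, lay$ambMask)
  expect_false(any(lay$atMask & lay$attMask))
})

test_that("phantom layers of matching geometry classify correctly", {
  for (scene in c("at_pool", "att_bend")) {
    ph <- cachedPhantom(scene, shape = c(40L, 64L, 64L), seed = 5L)
    pre <- preprocessVolume(ph$volume)
    lay <- identifyATLayers(pre$volume, pre$lumen)
    acc <- layerAccuracy(lay, ph$truth, minVoxels = 10L)
    expect_gt(acc$total, 0L)
    expect_identical(acc$correct, acc$total)
  }
})
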