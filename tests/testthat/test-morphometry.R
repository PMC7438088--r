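test_that("segmentation finds planted disks with correct area/centroid", {
  rf <- renderFrameSequence(4.0, fieldSize = 128, seed = 5)  # r = 20 px
  mask <- segmentCells(rf$frames[[1]])
  sm <- shapeMetrics(mask)
  expect_equal(nrow(sm), 1)
  expect_lt(abs(sm$area_um2 / (pi * 4^2) - 1), 0.02)
  # blank frame -> zero objects
  blank <- matrix(0.1, 64, 64)
  expect_equal(nrow(shapeMetrics(segmentCells(blank))), 0)
  # two disks -> two objects at the planted centroids (+-1 px)
  rf2 <- renderFrameSequence(c(4.0, 5.0), fieldSize = 256, seed = 8)
  sm2 <- shapeMetrics(segmentCells(rf2$frames[[1]]))
  expect_equal(nrow(sm2), 2)
  got <- sm2[order(sm2$radius_um), c("x_um", "y_um")] / 0.2
  want <- rf2$truth[order(rf2$truth$radius_um), c("x_px", "y_px")]
  expect_lt(max(abs(as.matrix(got) - as.matrix(want))), 1)
})

test_that("segmentation radius bias is below half a pixel for r 10-60 px", {
  for (rpx in c(10, 20, 40, 60)) {
    rf <- renderFrameSequence(rpx * 0.2, fieldSize = 4 * rpx + 80,
                              seed = rpx)
    sm <- shapeMetrics(segmentCells(rf$frames[[1]]))
    expect_equal(nrow(sm), 1)
    expect_lt(abs(sm$radius_um / 0.2 - rpx), 0.5)
  }
})

test_that("equivalent radius and volume follow the sphere formula", {
  m <- labeledMask(rasterDisk(20), pixelSize = 0.2)
  rv <- radiusAndVolume(m)
  expect_lt(abs(rv$radius_um - 4.0), 0.05)
  expect_equal(rv$volume_m3, 4 / 3 * pi * (rv$radius_um * 1e-6)^3,
               tolerance = 1e-12)
})

test_that("circularity is near 1 for disks, near pi/4 for squares", {
  expect_gte(circularity(rasterDisk(45)), 0.98)
  sq <- circularity(rasterSquare(60))
  expect_lt(abs(sq / (pi / 4) - 1), 0.03)
  # lobed shape scores strictly below a disk
  star <- makeShapeMasks(1, amplitude = 0.3, k = 4, radius_px = 45)[[1]]
  expect_lt(circularity(maskLabels(star)), circularity(rasterDisk(45)))
  expect_error(circularity(matrix(0L, 5, 5)), "positive")
})

test_that("shape features are invariant to translation and rotation", {
  star <- maskLabels(makeShapeMasks(1, amplitude = 0.25, k = 5,
                                    radius_px = 40, seed = 2)[[1]])
  shifted <- matrix(0L, nrow(star) + 30, ncol(star) + 30)
  shifted[31:(30 + nrow(star)), 31:(30 + ncol(star))] <- star
  rotated <- t(star)[ncol(star):1, ]  # 90 degree rotation
  sm0 <- shapeMetrics(labeledMask(star))
  smS <- shapeMetrics(labeledMask(shifted))
  smR <- shapeMetrics(labeledMask(rotated))
  expect_equal(smS$area_um2, sm0$area_um2)
  expect_equal(smS$circularity, sm0$circularity, tolerance = 1e-6)
  expect_equal(smR$area_um2, sm0$area_um2)
  expect_equal(smR$circularity, sm0$circularity, tolerance = 0.01)
  # circularity is scale invariant (up to rasterization)
  big <- maskLabels(makeShapeMasks(1, amplitude = 0.25, k = 5,
                                   radius_px = 80, seed = 2)[[1]])
  expect_equal(shapeMetrics(labeledMask(big))$circularity,
               sm0$circularity, tolerance = 0.02)
})

test_that("tracking links static, shrinking and disappearing cells", {
  rf <- renderFrameSequence(c(5.0, 7.0), nFrames = 10, fieldSize = 256,
                            seed = 3)
  masks <- lapply(seq_along(rf$frames), function(i)
    segmentCells(rf$frames[[i]], frameIndex = i))
  tracks <- trackCells(masks)
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_true(all(table(tracks$track_id) == 10))
  # shrinking cell stays one continuous track
  radii <- matrix(seq(8, 6.5, length.out = 8), nrow = 1)
  rf2 <- renderFrameSequence(radii, fieldSize = 160, seed = 4)
  masks2 <- lapply(seq_along(rf2$frames), function(i)
    segmentCells(rf2$frames[[i]], frameIndex = i))
  tracks2 <- trackCells(masks2)
  expect_equal(length(unique(tracks2$track_id)), 1)
  expect_equal(nrow(tracks2), 8)
  expect_true(all(diff(tracks2$radius_um) < 0))
  # object vanishing mid-sequence terminates its track
  masks3 <- masks[1:5]
  blank <- segmentCells(matrix(0.1, 256, 256), frameIndex = 6)
  tracks3 <- trackCells(c(masks3, list(blank)))
  expect_true(all(tapply(tracks3$frame, tracks3$track_id, max) == 5))
})

test_that("gating keeps exactly the planted single cells", {
  set.seed(9)
  singles <- lapply(singleCellRadii(100) / 0.2, function(r)
    labeledMask(rasterDisk(max(10, round(r)))))
  fragments <- lapply(runif(20, 5, 12), function(r)
    labeledMask(rasterDisk(round(r))))
  doublets <- lapply(rep(45, 5), function(r)
    labeledMask(rasterDoublet(r)))
  metrics <- do.call(rbind, lapply(c(singles, fragments, doublets),
                                   shapeMetrics))
  expect_equal(nrow(metrics), 125)
  gated <- gateSingleCells(metrics, gateConfig())
  expect_equal(nrow(gated), 100)
  removed <- attr(gated, "removed")
  expect_equal(unname(removed["fragment"]), 20L)
  expect_equal(unname(removed["aspect"] + removed["cluster"]), 5L)
  # gating is idempotent
  again <- gateSingleCells(gated, gateConfig())
  expect_equal(nrow(again), nrow(gated))
})

test_that("intensity is size-normalized then control-normalized", {
  m <- labeledMask(rasterDisk(20))
  img <- matrix(0.5, nrow(maskLabels(m)), ncol(maskLabels(m)))
  res <- normalizedIntensity(img, m)
  # uniform image: per-area intensity equals the pixel value / px area
  expect_equal(res$intensity_per_um2, 0.5 / 0.2^2, tolerance = 1e-9)
  # a mask twice the size gives the same per-area intensity
  m2 <- labeledMask(rasterDisk(30))
  img2 <- matrix(0.5, nrow(maskLabels(m2)), ncol(maskLabels(m2)))
  expect_equal(normalizedIntensity(img2, m2)$intensity_per_um2,
               res$intensity_per_um2, tolerance = 1e-9)
  # control normalization: control population averages 1, a 20% dimmer
  # population averages 0.8
  ctrl <- res$intensity_per_um2
  expect_equal(normalizedIntensity(img, m, ctrl)$norm_intensity, 1)
  expect_equal(normalizedIntensity(img * 0.8, m, ctrl)$norm_intensity,
               0.8, tolerance = 1e-9)
  expect_error(normalizedIntensity(img, m, 0), "zero")
})

test_that("similarity score behaves like a log-transformed correlation", {
  cp <- makeChannelPair(0, size = 128, seed = 21)
  # identical channels: maximal (capped) positive score
  same <- nuclearSimilarity(cp$channelA, cp$channelA, cp$mask)
  expect_gt(same$similarity, 6)
  # independent channels: near zero at >= 1000 pixels
  indep <- nuclearSimilarity(cp$channelA, cp$channelB, cp$mask)
  expect_lt(abs(indep$similarity), 0.1)
  # inverted channel: negative
  inv <- nuclearSimilarity(cp$channelA, -cp$channelA, cp$mask)
  expect_lt(inv$similarity, -6)
  # symmetric in channel order
  cp2 <- makeChannelPair(0.5, size = 64, seed = 22)
  ab <- nuclearSimilarity(cp2$channelA, cp2$channelB, cp2$mask)
  ba <- nuclearSimilarity(cp2$channelB, cp2$channelA, cp2$mask)
  expect_equal(ab$similarity, ba$similarity, tolerance = 1e-12)
  # constant channel flagged
  const <- nuclearSimilarity(matrix(1, 128, 128), cp$channelB, cp$mask)
  expect_equal(const$flag, "constant_channel")
  expect_true(is.na(const$similarity))
})

test_that("focus score ranks sharp above blurred regions", {
  rf <- renderFrameSequence(4, fieldSize = 128, noiseSD = 0, seed = 6)
  sharp <- rf$frames[[1]]
  blurred <- EBImage::gblur(sharp, sigma = 4)
  expect_gt(focusScore(sharp), focusScore(blurred))
})
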