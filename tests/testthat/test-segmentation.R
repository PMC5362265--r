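test_that("preprocessing flattens constants and keeps isolated peaks", {
  p <- segmentationParams(gaussSigma = 1, tophatRadius = 5)
  expect_equal(preprocessChannel(matrix(7, 32, 32), p), matrix(0, 32, 32))
  ## single bright pixel: opening removes it entirely, top-hat ~ blurred spot
  img <- matrix(0, 33, 33); img[17, 17] <- 100
  pre <- preprocessChannel(img, p)
  blurred <- gaussBlur(img, 1)
  expect_lt(abs(max(pre) - max(blurred)) / max(blurred), 0.01)
  expect_true(all(pre <= blurred + 1e-9))
  expect_true(all(pre >= 0))
})

test_that("top-hat residual of a linear ramp is bounded by slope x diameter", {
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32, byrow = TRUE)
  res <- whiteTopHat(ramp, 4)
  expect_true(all(res < 1 * 4 * 2 + 1e-9))
  ## cross-check against brute-force opening on the same fixture
  expect_equal(res, pmax(ramp - bruteOpening(ramp, 4), 0))
})

test_that("tophat radius must fit the image", {
  p <- segmentationParams(tophatRadius = 20)
  expect_error(preprocessChannel(matrix(0, 32, 32), p), "tophatRadius")
})

test_that("local mean threshold matches the brute-force oracle exactly", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(runif(32 * 32, 0, 100), 32, 32)
    r <- sample(c(2, 3, 5), 1); off <- runif(1, 0, 5)
    expect_identical(localMeanThreshold(img, r, off),
                     bruteLocalMeanThreshold(img, r, off))
  }
})

test_that("threshold tie-break is strict (constant image stays empty)", {
  img <- matrix(3, 15, 15)
  expect_false(any(localMeanThreshold(img, 5, 1)))
  expect_false(any(localMeanThreshold(img, 5, 0)))
})

test_that("a plateau on zero background thresholds cleanly", {
  img <- matrix(0, 15, 15)
  img[7:9, 7:9] <- 10
  m <- localMeanThreshold(img, 5, 1)
  expect_true(all(m[7:9, 7:9]))
  expect_false(any(m[img == 0]))
  expect_identical(m, bruteLocalMeanThreshold(img, 5, 1))
})

test_that("mask cleanup removes specks, keeps disks, enforces area window", {
  p <- segmentationParams(medianRadius = 1, minArea = 10, maxArea = 400)
  ## a single isolated pixel is flipped by the majority median
  m1 <- matrix(FALSE, 20, 20); m1[10, 10] <- TRUE
  expect_equal(nSpots(cleanMask(m1, p)), 0L)
  ## a solid disk survives with area eroded at most by its perimeter
  m2 <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64)
    if ((i - 32)^2 + (j - 32)^2 <= 8^2) m2[i, j] <- TRUE
  sp <- cleanMask(m2, p)
  expect_equal(nSpots(sp), 1L)
  perim <- sum(m2) - sum((bruteErodeDilate(m2 * 1, 1, min)) > 0)
  expect_gte(spotTable(sp)$area, sum(m2) - perim)
  expect_lte(spotTable(sp)$area, sum(m2) + perim)
  ## area opening: of two disks only the large one survives
  m3 <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    if ((i - 12)^2 + (j - 12)^2 <= 5^2) m3[i, j] <- TRUE
    if ((i - 30)^2 + (j - 30)^2 <= 1.2^2) m3[i, j] <- TRUE
  }
  expect_equal(nSpots(cleanMask(m3, p)), 1L)
})

test_that("blank images segment to zero spots", {
  expect_equal(nSpots(segmentSpots(matrix(0, 64, 64))), 0L)
  expect_equal(nSpots(segmentSpots(matrix(55, 64, 64))), 0L)
})

test_that("masks are invariant to intensity shifts and scale-equivariant", {
  set.seed(42)
  sim <- simulateField(sceneParams(imageShape = c(96L, 96L), nCells = 2L,
                                   cellRadius = 12,
                                   backgroundSmoothness = 10), seed = 9)
  img <- redChannel(sim$field)
  p <- anchorSegParams()
  base <- spotLabels(segmentSpots(img, p = p))
  ## adding a constant: top-hat removes it, threshold offset from MAD
  shifted <- spotLabels(segmentSpots(img + 500, p = p))
  expect_identical(base, shifted)
  ## multiplying by k with offset scaled by k gives the identical mask
  pre <- preprocessChannel(img, p)
  off <- 5 * mad(pre)
  mk <- localMeanThreshold(pre, p@localRadius, off)
  pre2 <- preprocessChannel(img * 3, p)
  mk2 <- localMeanThreshold(pre2, p@localRadius, 3 * off)
  expect_identical(mk, mk2)
})

test_that("synthetic anchors are recovered with high recall and precision", {
  p <- sceneParams(imageShape = c(160L, 160L), nCells = 8L,
                   anchorsPerCell = 2L, anchorAmplitude = 750,
                   cellRadius = 14, backgroundSmoothness = 20)
  rec <- prec <- numeric(3)
  for (s in 1:3) {
    sim <- simulateField(p, seed = s)
    tb <- spotTable(segmentSpots(redChannel(sim$field)))
    an <- groundTruthAnchors(sim$truth)
    D <- sqrt(outer(tb$centroidRow, an$row, "-")^2 +
                outer(tb$centroidCol, an$col, "-")^2)
    rec[s] <- mean(apply(D, 2, min) <= 2)
    prec[s] <- mean(apply(D, 1, min) <= 2)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})
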