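## Study-condition generator: determinism, photon accounting, analytic
## score, and the Monte-Carlo oracle for expectedScore.

smallScene <- function(...) {
  args <- utils::modifyList(
    list(imageShape = c(96L, 96L), nCells = 2L, cellRadius = 12,
         backgroundSmoothness = 10), list(...))
  do.call(sceneParams, args)
}

test_that("identical (params, seed) give bit-identical fields", {
  p <- smallScene()
  a <- simulateField(p, seed = 11)
  b <- simulateField(p, seed = 11)
  expect_identical(a$field@red, b$field@red)
  expect_identical(a$field@green, b$field@green)
  expect_identical(groundTruthCells(a$truth), groundTruthCells(b$truth))
  c <- simulateField(p, seed = 12)
  expect_false(identical(a$field@green, c$field@green))
})

test_that("nothing emits when all green sources are off", {
  p <- smallScene(preyAmplitudeAtAnchor = 0, nucleolusAmplitude = 0,
                  backgroundMean = 0, cellFluor = 0, readNoiseSigma = 0)
  sim <- simulateField(p, seed = 1, noise = FALSE)
  expect_true(all(greenChannel(sim$field) == 0))
})

test_that("red channel has exactly 2 local maxima per cell with noise off", {
  p <- smallScene(anchorsPerCell = 2L, backgroundMean = 0)
  sim <- simulateField(p, seed = 3, noise = FALSE)
  r <- redChannel(sim$field)
  ## strict local maxima above half the peak
  nmax <- 0L
  for (i in 2:(nrow(r) - 1)) for (j in 2:(ncol(r) - 1)) {
    nb <- r[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (r[i, j] == max(nb) && sum(nb == max(nb)) == 1 &&
        r[i, j] > max(r) / 4) nmax <- nmax + 1L
  }
  expect_equal(nmax, 2L * 2L)
})

test_that("placement fails loudly when cells cannot fit", {
  p <- sceneParams(imageShape = c(48L, 48L), nCells = 20L, cellRadius = 12)
  expect_error(simulateField(p, seed = 1), "too small")
})

test_that("photon accounting: noise-free sums match the analytic integrals", {
  for (s in 1:3) {
    p <- smallScene(recruitedFraction = c(0, 0.5, 1)[s])
    sim <- simulateField(p, seed = s, noise = FALSE)
    pt <- sim$truth@photonTotals
    expect_lt(abs(sum(greenChannel(sim$field)) - pt[["green"]]) /
                pt[["green"]], 0.005)
    expect_lt(abs(sum(redChannel(sim$field)) - pt[["red"]]) / pt[["red"]],
              0.005)
  }
})

test_that("expectedScore is monotone in recruited fraction and prey level", {
  base <- smallScene(nCells = 4L)
  rf <- c(0, 0.25, 0.5, 0.75, 1)
  es <- vapply(rf, function(x) {
    p <- base; p@recruitedFraction <- x; expectedScore(p)
  }, numeric(1))
  expect_true(all(diff(es) >= 0))
  amps <- c(0, 500, 1000, 4000)
  es2 <- vapply(amps, function(a) {
    p <- base; p@preyAmplitudeAtAnchor <- a; expectedScore(p)
  }, numeric(1))
  expect_true(all(diff(es2) > 0))
})

test_that("expectedScore limiting cases follow the generative model", {
  ## only a flat background under the mask -> score = background mean
  p <- smallScene(preyAmplitudeAtAnchor = 0, nucleolusAmplitude = 0,
                  cellFluor = 0, backgroundMean = 80)
  expect_equal(expectedScore(p), 80)
  ## linearity in the prey amplitude with all other sources off
  p2 <- smallScene(nucleolusAmplitude = 0, cellFluor = 0, backgroundMean = 0,
                   recruitedFraction = 1, preyAmplitudeAtAnchor = 1000)
  p3 <- p2; p3@preyAmplitudeAtAnchor <- 2000
  expect_equal(expectedScore(p3), 2 * expectedScore(p2), tolerance = 1e-12)
})

test_that("simulateCondition yields distinct reproducible per-field seeds", {
  p <- smallScene()
  seeds <- outer(1:3, 1:6, Vectorize(function(r, f) fieldSeed(42, r, f)))
  expect_equal(length(unique(as.vector(seeds))), 18L)
  a <- simulateCondition(p, 2L, 2L, baseSeed = 42)
  b <- simulateCondition(p, 2L, 2L, baseSeed = 42)
  expect_identical(a[[2]][[1]]$field@green, b[[2]][[1]]$field@green)
})

test_that("recruitment flag changes green only at anchor neighborhoods", {
  p0 <- smallScene(recruitedFraction = 0)
  p1 <- smallScene(recruitedFraction = 1)
  a <- simulateField(p0, seed = 5, noise = FALSE)
  b <- simulateField(p1, seed = 5, noise = FALSE)
  diffImg <- abs(greenChannel(b$field) - greenChannel(a$field))
  idx <- which(diffImg > 1e-9, arr.ind = TRUE)
  an <- groundTruthAnchors(b$truth)
  ## every changed pixel lies within the spot window of some anchor
  h <- ceiling(4 * p1@psfSigma)
  near <- apply(idx, 1, function(px)
    any(abs(px[1] - an$row) <= h + 1 & abs(px[2] - an$col) <= h + 1))
  expect_true(all(near))
  expect_gt(nrow(idx), 0)
})

test_that("timecourse generator follows the model curves", {
  kp <- kineticParams(measurementNoiseSd = 0)
  tcs <- simulateTimecourse(kp)
  v <- levelValues(tcs$rrn3); t <- timePoints(tcs$rrn3)
  expect_equal(v[1], 0.4 + 0.6)                     # t = 0
  expect_equal(v[length(v)], 0.4 + 0.6 * exp(-120 / 10), tolerance = 1e-12)
  ## logistic midpoint at t50 (evaluate on a grid containing t50)
  kp2 <- kineticParams(measurementNoiseSd = 0,
                       timepoints = c(0, 10, 25, 40, 60))
  d <- simulateTimecourse(kp2)$dimer
  expect_equal(levelValues(d)[timePoints(d) == 25], 0.5)
  ## determinism with noise
  kp3 <- kineticParams()
  expect_identical(levelValues(simulateTimecourse(kp3, seed = 4)$rrn3),
                   levelValues(simulateTimecourse(kp3, seed = 4)$rrn3))
})
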