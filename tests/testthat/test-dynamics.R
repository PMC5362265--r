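test_that("normalization sets the peak to exactly 1 and is idempotent", {
  tc <- timeCourse("x", c(0, 10, 20), c(2, 4, 3))
  n1 <- normalizeLevels(tc)
  expect_equal(levelValues(n1), c(0.5, 1.0, 0.75))
  expect_identical(max(levelValues(n1)), 1)
  expect_equal(levelValues(normalizeLevels(n1)), levelValues(n1))
  expect_error(normalizeLevels(timeCourse("z", c(0, 5), c(0, 0))),
               "all-zero")
})

test_that("interval rates are forward differences and telescope exactly", {
  tc <- timeCourse("x", c(0, 15, 35), c(1.0, 0.7, 0.6))
  rs <- intervalRates(tc)
  expect_equal(rateValues(rs), c(-0.02, -0.005))
  expect_equal(timePoints(rs), c(7.5, 25))
  ## constant series
  expect_true(all(rateValues(intervalRates(
    timeCourse("c", c(0, 5, 9), c(2, 2, 2)))) == 0))
  ## telescoping identity on random series
  for (s in 1:5) {
    set.seed(s)
    t <- sort(sample(0:200, 8))
    v <- runif(8)
    r <- intervalRates(timeCourse("r", t, v))
    expect_equal(sum(rateValues(r) * r@dt), v[8] - v[1], tolerance = 1e-12)
  }
})

test_that("exponential decay recovery is exact on noiseless data", {
  t <- c(0, 5, 10, 20, 35, 60, 120)
  tc <- timeCourse("rrn3", t, 0.4 + 0.6 * exp(-t / 10))
  f <- fitExponentialDecay(tc)
  expect_true(f@converged)
  expect_lt(abs(fitParameters(f)[["tau"]] - 10) / 10, 0.01)
  expect_lt(abs(fitParameters(f)[["offset"]] - 0.4), 0.01)
  expect_lt(abs(fitParameters(f)[["amplitude"]] - 0.6), 0.01)
})

test_that("a constant series is flagged degenerate", {
  f <- fitExponentialDecay(timeCourse("c", c(0, 5, 10, 20), rep(3, 4)))
  expect_true(f@degenerate)
  expect_equal(fitParameters(f)[["amplitude"]], 0)
  f2 <- fitLogistic(timeCourse("c", c(0, 5, 10, 20), rep(3, 4)))
  expect_true(f2@degenerate)
})

test_that("tau is recovered within 20% (median) under 5% noise", {
  errs <- vapply(1:50, function(s) {
    tc <- simulateTimecourse(kineticParams(measurementNoiseSd = 0.05),
                             seed = s)$rrn3
    abs(fitParameters(fitExponentialDecay(tc))[["tau"]] - 10) / 10
  }, numeric(1))
  expect_lte(median(errs), 0.2)
})

test_that("logistic parameters are recovered within 1% on noiseless data", {
  t <- c(0, 5, 10, 15, 20, 25, 30, 40, 50, 70)
  v <- 0 + (1 - 0) / (1 + exp(-0.2 * (t - 25)))
  f <- fitLogistic(timeCourse("dimer", t, v))
  p <- fitParameters(f)
  expect_lt(abs(p[["t50"]] - 25) / 25, 0.01)
  expect_lt(abs(p[["steepness"]] - 0.2) / 0.2, 0.01)
  expect_lt(abs(p[["hi"]] - 1), 0.01)
  expect_lt(abs(p[["lo"]] - 0), 0.01)
})

test_that("mirroring a symmetric logistic flips steepness, keeps t50", {
  t <- seq(0, 50, by = 5)          # symmetric grid around t50 = 25
  v <- 1 / (1 + exp(-0.2 * (t - 25)))
  fwd <- fitParameters(fitLogistic(timeCourse("d", t, v)))
  rev_ <- fitParameters(fitLogistic(timeCourse("d", t, rev(v))))
  expect_equal(rev_[["t50"]], fwd[["t50"]], tolerance = 1e-3)
  expect_equal(rev_[["steepness"]], -fwd[["steepness"]], tolerance = 1e-3)
})

test_that("a monotone step localizes t50 between the bracketing points", {
  t <- c(0, 10, 20, 30, 40, 50)
  v <- c(0, 0, 0, 1, 1, 1)
  f <- fitLogistic(timeCourse("step", t, v))
  expect_gte(fitParameters(f)[["t50"]], 20)
  expect_lte(fitParameters(f)[["t50"]], 30)
})

test_that("stage labels follow the dominant-rate rule", {
  mkRates <- function(r) new("RateSeries", midpoints = c(7.5, 25, 42.5),
                             rates = r, dt = c(15, 20, 15))
  st <- classifyStages(mkRates(c(-0.02, -0.004, -0.002)),
                       mkRates(c(0, -0.012, -0.002)), slowThreshold = 0.2)
  expect_equal(st@intervals$stage,
               c("A_fast", "B_fast", "consolidation"))
  expect_equal(st@boundaries, c(15, 35))
  ## all-zero rates: one consolidation stage
  st0 <- classifyStages(mkRates(c(0, 0, 0)), mkRates(c(0, 0, 0)))
  expect_equal(st0@intervals$stage, "consolidation")
  ## random pairs match the per-interval rule applied directly
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(6, 0, 0.02); b <- rnorm(6, 0, 0.02)
    ra <- new("RateSeries", midpoints = seq(5, 55, 10), rates = a,
              dt = rep(10, 6))
    rb <- new("RateSeries", midpoints = seq(5, 55, 10), rates = b,
              dt = rep(10, 6))
    st2 <- classifyStages(ra, rb, slowThreshold = 0.3)
    mx <- max(abs(c(a, b)))
    expected <- ifelse(abs(a) < 0.3 * mx & abs(b) < 0.3 * mx,
                       "consolidation",
                       ifelse(abs(a) >= abs(b), "A_fast", "B_fast"))
    ## merged runs of the direct rule equal the classifier's intervals
    expect_equal(rle(expected)$values, st2@intervals$stage)
  }
  ## mismatched grids rejected
  rb2 <- new("RateSeries", midpoints = c(1, 2, 3), rates = c(0, 0, 0),
             dt = c(1, 1, 1))
  expect_error(classifyStages(mkRates(c(0, 0, 0)), rb2), "grid")
})

test_that("the default synthetic scenario reproduces the stage order", {
  tcs <- simulateTimecourse(kineticParams(measurementNoiseSd = 0))
  r1 <- intervalRates(normalizeLevels(tcs$rrn3))
  r2 <- intervalRates(normalizeLevels(tcs$dimer))
  st <- classifyStages(r1, r2, idA = "rrn3", idB = "dimer")
  expect_equal(st@intervals$stage,
               c("rrn3_fast", "dimer_fast", "consolidation"))
})
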