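mkSpots <- function(lab, raw = matrix(1, nrow(lab), ncol(lab)))
  new("LabeledSpots", labels = lab, table = PICTquant:::regionTable(lab, raw))

test_that("overlap regions equal exhaustive pixel enumeration", {
  ## disjoint masks
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 8, 8); b[6:7, 6:7] <- 1L
  expect_equal(yellowArea(overlapRegions(mkSpots(a), mkSpots(b))), 0)
  ## containment: prey strictly inside an anchor
  a2 <- matrix(0L, 8, 8); a2[3:4, 3:4] <- 1L
  b2 <- matrix(0L, 8, 8); b2[2:6, 2:6] <- 1L
  expect_equal(yellowArea(overlapRegions(mkSpots(a2), mkSpots(b2))), 4)
  ## random label pairs vs brute force
  for (s in 1:6) {
    pl <- randomLabels(16, 16, 3, seed = s)
    al <- randomLabels(16, 16, 3, seed = s + 100)
    ov <- overlapRegions(mkSpots(pl), mkSpots(al))
    br <- bruteOverlapArea(pl, al)
    expect_equal(yellowArea(ov), br$area)
    expect_equal(sort(paste(ov@pairs$preyLabel, ov@pairs$anchorLabel)),
                 br$pairs)
  }
  expect_error(overlapRegions(mkSpots(a), mkSpots(matrix(0L, 4, 4))),
               "shape")
})

test_that("recruitment score identities hold exactly", {
  ## a fully covered anchor with constant raw green I scores exactly I
  anchor <- matrix(0L, 10, 10); anchor[4:6, 4:6] <- 1L
  prey <- matrix(0L, 10, 10); prey[3:7, 3:7] <- 1L
  g <- matrix(17.5, 10, 10)
  res <- recruitmentScore(g, mkSpots(prey), mkSpots(anchor))
  expect_equal(recruitScore(res), 17.5, tolerance = 1e-15)
  ## zero overlap scores exactly 0
  prey2 <- matrix(0L, 10, 10); prey2[1:2, 1:2] <- 1L
  expect_identical(recruitScore(recruitmentScore(g, mkSpots(prey2),
                                                 mkSpots(anchor))), 0)
  ## random 8x8 integer fixtures vs brute force, plus the exact identity
  for (s in 1:10) {
    set.seed(s)
    g3 <- matrix(sample(0:20, 64, TRUE), 8, 8)
    pl <- randomLabels(8, 8, 2, seed = s + 7)
    al <- randomLabels(8, 8, 2, seed = s + 19)
    if (sum(al > 0) == 0) next
    res3 <- recruitmentScore(g3, mkSpots(pl), mkSpots(al))
    expect_equal(recruitScore(res3), bruteScore(g3, pl, al),
                 tolerance = 1e-12)
    expect_equal(recruitScore(res3) * redArea(res3), res3@sumGreen,
                 tolerance = 1e-12)
  }
})

test_that("a field without anchors is excluded with a warning", {
  g <- matrix(1, 6, 6)
  empty <- mkSpots(matrix(0L, 6, 6))
  prey <- matrix(0L, 6, 6); prey[2:3, 2:3] <- 1L
  expect_warning(res <- recruitmentScore(g, mkSpots(prey), empty),
                 "red area 0")
  expect_null(res)
})

test_that("prey spots away from anchors contribute nothing", {
  anchor <- matrix(0L, 12, 12); anchor[3:4, 3:4] <- 1L
  preyOn <- matrix(0L, 12, 12); preyOn[3:4, 3:4] <- 1L
  preyOff <- preyOn; preyOff[9:11, 9:11] <- 2L  # extra false positive
  set.seed(2); g <- matrix(runif(144, 0, 50), 12, 12)
  expect_identical(
    recruitScore(recruitmentScore(g, mkSpots(preyOn), mkSpots(anchor))),
    recruitScore(recruitmentScore(g, mkSpots(preyOff), mkSpots(anchor))))
})

test_that("scores are linear in the green channel with fixed masks", {
  pl <- randomLabels(10, 10, 2, seed = 1)
  al <- randomLabels(10, 10, 2, seed = 5)
  set.seed(3); g <- matrix(runif(100), 10, 10)
  s1 <- recruitScore(recruitmentScore(g, mkSpots(pl), mkSpots(al)))
  s2 <- recruitScore(recruitmentScore(3.7 * g, mkSpots(pl), mkSpots(al)))
  expect_equal(s2, 3.7 * s1, tolerance = 1e-12)
})

test_that("whole-spot area mode uses every pixel of overlapping prey spots", {
  anchor <- matrix(0L, 10, 10); anchor[4:5, 4:5] <- 1L
  prey <- matrix(0L, 10, 10); prey[4:7, 4:5] <- 1L  # extends past the anchor
  g <- matrix(0, 10, 10); g[4:7, 4:5] <- 2
  ov <- recruitmentScore(g, mkSpots(prey), mkSpots(anchor))
  ws <- recruitmentScore(g, mkSpots(prey), mkSpots(anchor),
                         areaMode = "whole_spot")
  expect_equal(yellowArea(ov), 4)
  expect_equal(yellowArea(ws), 8)
  expect_equal(recruitScore(ws), 2 * 8 / 4)
})

test_that("replicate pooling sums before dividing", {
  mkRes <- function(labP, labA, g)
    recruitmentScore(g, mkSpots(labP), mkSpots(labA))
  ## one field: pooled equals the field score
  pl <- randomLabels(10, 10, 2, seed = 2); al <- randomLabels(10, 10, 2, 9)
  set.seed(1); g <- matrix(runif(100, 0, 10), 10, 10)
  r1 <- mkRes(pl, al, g)
  expect_equal(recruitScore(poolReplicate(list(r1))), recruitScore(r1))
  ## equal red areas: pooled equals the arithmetic mean of the scores
  a1 <- matrix(0L, 10, 10); a1[2:3, 2:3] <- 1L
  p1 <- a1
  g1 <- matrix(4, 10, 10); g2 <- matrix(10, 10, 10)
  ra <- mkRes(p1, a1, g1); rb <- mkRes(p1, a1, g2)
  expect_equal(recruitScore(poolReplicate(list(ra, rb))), (4 + 10) / 2)
  ## three random fields vs global enumeration over concatenated pixels
  num <- 0; den <- 0
  frs <- list()
  for (s in 1:3) {
    plx <- randomLabels(12, 12, 2, seed = s + 40)
    alx <- randomLabels(12, 12, 2, seed = s + 80)
    set.seed(s); gx <- matrix(runif(144, 0, 30), 12, 12)
    frs[[s]] <- mkRes(plx, alx, gx)
    num <- num + sum(gx[plx > 0 & alx > 0]); den <- den + sum(alx > 0)
  }
  expect_equal(recruitScore(poolReplicate(frs)), num / den)
  expect_error(poolReplicate(list()), "no usable fields")
})

test_that("condition summaries normalize and test as specified", {
  cs <- summarizeCondition("wt", c(1.0, 1.2, 0.8))
  expect_equal(cs@mean, 1.0)
  expect_equal(cs@sd, 0.2)
  ## reference = itself: normalized mean is 1
  cs2 <- summarizeCondition("wt", c(1.0, 1.2, 0.8), reference = cs)
  expect_equal(cs2@normalizedMean, 1)
  ## identical degenerate samples: p = 1
  a <- summarizeCondition("a", c(2, 2, 2))
  b <- summarizeCondition("b", c(2, 2, 2), comparison = a)
  expect_equal(pValue(b), 1)
  ## Welch test agrees with stats::t.test on ordinary samples
  x <- c(1.1, 1.4, 0.9); y <- c(2.2, 2.6, 2.1)
  cmp <- summarizeCondition("x", x)
  cs3 <- summarizeCondition("y", y, comparison = cmp)
  expect_equal(pValue(cs3), t.test(y, x)$p.value)
  expect_error(summarizeCondition("z", 1.5, comparison = cmp), ">= 2")
})
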