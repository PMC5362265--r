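perfectDilution <- function(amplicon = "35S", eff = 1, intercept = 20) {
  slope <- -1 / log10(1 + eff)
  lq <- 0:-3
  data.frame(amplicon = amplicon, log10Quantity = rep(lq, each = 2),
             techRep = rep(1:2, 4), ct = intercept + slope * rep(lq, each = 2))
}

test_that("standard curves recover slope, efficiency and r2", {
  sc <- fitStandardCurve(perfectDilution())
  expect_lt(abs(efficiency(sc) - 1), 1e-6)
  expect_equal(sc@r2, 1)
  expect_equal(sc@slope, -log2(10), tolerance = 1e-9)  # 3.3219 Ct per decade
  ## slope -3.6 gives the closed-form efficiency
  sc2 <- fitStandardCurve(data.frame(log10Quantity = 0:-3,
                                     ct = 20 - 3.6 * (0:-3)))
  expect_equal(efficiency(sc2), 10^(1 / 3.6) - 1, tolerance = 1e-9)
  ## replicated Cts with zero variance across dilutions are rejected upstream
  expect_error(fitStandardCurve(data.frame(log10Quantity = c(0, -1),
                                           ct = c(20, 23.3))), ">= 3")
  expect_error(fitStandardCurve(data.frame(log10Quantity = 0:-3,
                                           ct = c(20, 21, 22, 23) * -1 + 10)),
               "slope")
})

test_that("quantification inverts the standard curve", {
  sc <- fitStandardCurve(perfectDilution())
  expect_equal(quantifyCt(sc@intercept, sc), 1)
  ## one log-unit step: Ct at intercept + slope corresponds to quantity 10
  expect_equal(quantifyCt(sc@intercept + sc@slope, sc), 10)
  ## direction: higher Ct, lower quantity
  expect_lt(quantifyCt(25, sc), quantifyCt(24, sc))
  ## algebraic round trip
  for (q in c(0.013, 0.7, 5, 42)) {
    ct <- sc@intercept + sc@slope * log10(q)
    expect_equal(quantifyCt(ct, sc), q, tolerance = 1e-9)
  }
})

mkCurves <- function(loci, eff = 1)
  setNames(lapply(loci, function(l)
    fitStandardCurve(perfectDilution(l, eff))), loci)

test_that("the occupancy chain reduces to 2^ddCt arithmetic exactly", {
  loci <- c("35S", "5S", "chrVII")
  curves <- mkCurves(loci)
  ## all Cts equal: occupancy 1, fold 1
  flat <- expand.grid(fraction = c("IP", "input"), amplicon = loci,
                      condition = c("rich", "starved"), replicate = 1:2,
                      stringsAsFactors = FALSE)
  flat$ct <- 22
  occ <- relativeOccupancy(flat, curves, target = "35S",
                           referenceCondition = "rich")
  expect_true(all(abs(occ@perReplicate$occupancy - 1) < 1e-12))
  expect_true(all(abs(occ@summary$fold - 1) < 1e-12))
  ## target IP one cycle lower than input: r = 2, occupancy 2
  oneLess <- flat
  oneLess$ct[oneLess$amplicon == "35S" & oneLess$fraction == "IP"] <- 21
  occ2 <- relativeOccupancy(oneLess, curves, target = "35S",
                            referenceCondition = "rich")
  expect_true(all(abs(occ2@perReplicate$occupancy - 2) < 1e-12))
  ## 20 random integer Ct tables match the spreadsheet-style oracle
  for (s in 1:20) {
    set.seed(s)
    tab <- expand.grid(fraction = c("IP", "input"), amplicon = loci,
                       condition = c("rich", "starved"), replicate = 1:3,
                       techRep = 1:2, stringsAsFactors = FALSE)
    tab$ct <- sample(15:30, nrow(tab), replace = TRUE)
    occ3 <- relativeOccupancy(tab, curves, target = "35S",
                              referenceCondition = "rich")
    for (k in seq_len(nrow(occ3@perReplicate))) {
      expect_equal(occ3@perReplicate$occupancy[k],
                   ddctOracle(tab, "35S", "chrVII", "5S",
                              occ3@perReplicate$condition[k],
                              occ3@perReplicate$replicate[k]),
                   tolerance = 1e-9)
    }
  }
})

test_that("occupancy is invariant to a global Ct shift", {
  loci <- c("35S", "5S", "chrVII")
  curves <- mkCurves(loci)
  set.seed(99)
  tab <- expand.grid(fraction = c("IP", "input"), amplicon = loci,
                     condition = c("rich", "starved"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  tab$ct <- runif(nrow(tab), 16, 30)
  occA <- relativeOccupancy(tab, curves, target = "35S",
                            referenceCondition = "rich")
  tabB <- tab; tabB$ct <- tab$ct + 2.7
  occB <- relativeOccupancy(tabB, curves, target = "35S",
                            referenceCondition = "rich")
  expect_equal(occA@perReplicate$occupancy, occB@perReplicate$occupancy,
               tolerance = 1e-9)
})

test_that("missing loci and conditions are reported by name", {
  curves <- mkCurves(c("35S", "5S", "chrVII"))
  tab <- expand.grid(fraction = c("IP", "input"),
                     amplicon = c("35S", "5S"),
                     condition = "rich", replicate = 1,
                     stringsAsFactors = FALSE)
  tab$ct <- 20
  expect_error(relativeOccupancy(tab, curves, target = "35S",
                                 referenceCondition = "rich"), "chrVII")
})

test_that("simulated Ct tables recover their true occupancies", {
  occTruth <- data.frame(
    condition = rep(c("rich", "starved"), each = 3),
    locus = rep(c("35S", "5S", "chrVII"), 2),
    occ = c(1, 1, 1, 0.05, 1, 1))
  cts <- simulateCtTable(occTruth, efficiency = 1, ctNoiseSd = 0.05,
                         bioCv = 0, seed = 5)
  curves <- mkCurves(c("35S", "5S", "chrVII"))
  occ <- relativeOccupancy(cts, curves, target = "35S",
                           referenceCondition = "rich")
  fold <- occ@summary$fold[occ@summary$condition == "starved"]
  expect_lt(abs(fold - 0.05) / 0.05, 0.5)
})
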