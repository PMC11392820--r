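test_that("binomial tail matches term-by-term enumeration", {
  # fixed reference cases
  expect_equal(binomialSiteTest(0, 10, 0.01), 1)
  expect_equal(binomialSiteTest(1, 10, 0), 0)
  expect_equal(binomialSiteTest(3, 20, 0.01), oracleBinomTail(3, 20, 0.01),
               tolerance = 1e-12)
  expect_equal(binomialSiteTest(3, 20, 0.01), 0.001003, tolerance = 1e-3)
  expect_true(is.na(binomialSiteTest(0, 0, 0.01)))

  # exhaustive agreement for all N <= 30 at several error rates
  for (eps in c(0, 0.001, 0.005, 0.01, 0.05)) {
    for (n in c(1L, 7L, 18L, 30L)) {
      for (c in 0:n) {
        expect_equal(binomialSiteTest(c, n, eps),
                     oracleBinomTail(c, n, eps), tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value is monotone in the count and in the error rate", {
  n <- 25L
  p <- binomialSiteTest(0:n, n, 0.01)
  expect_true(all(diff(p) <= 0))
  epsGrid <- c(0.001, 0.005, 0.01, 0.05, 0.2)
  p2 <- vapply(epsGrid, function(e) binomialSiteTest(4L, n, e), numeric(1))
  expect_true(all(diff(p2) >= 0))
})

test_that("callSites flags by strict alpha and respects min coverage", {
  cal <- CalibrationResult(epsMCpG = 0.005,
                           support = c(mCpG = 1000L, CH = 0L, hmC = 0L))
  x <- makeTable(pos = c(100, 200, 300, 400),
                 nUnc = c(0, 5, 1, 2), nConv = c(30, 25, 0, 28))
  calls <- callSites(x, cal, alpha = 0.025, minCov = 2L)
  expect_equal(length(calls), 4L)
  df <- as.data.frame(mcols(calls))
  expect_equal(df$pValue[1], 1)            # C = 0 cannot be significant
  expect_false(df$highConfidence[1])
  expect_true(df$highConfidence[2])
  expect_true(is.na(df$pValue[3]))          # below min coverage
  expect_false(df$highConfidence[3])
  # strictness of p < alpha at the boundary
  expect_identical(df$highConfidence, !is.na(df$pValue) & df$pValue < 0.025)
  # errors: wrong assay, missing calibration
  w <- makeTable(pos = 100, nUnc = 1, nConv = 1, assay = "WGBS")
  expect_error(callSites(w, cal), "ACE")
  expect_error(callSites(x, CalibrationResult()), "calibration")
})

test_that("high 5hmC sites are detected with near-nominal type-I error", {
  cal <- CalibrationResult(epsMCpG = 0.005,
                           support = c(mCpG = 1000L, CH = 0L, hmC = 0L))
  set.seed(42)
  # power at h = 0.2, depth 30: expected flag rate from exact enumeration
  n <- 4000L
  cH <- rbinom(n, 30L, 0.2)
  xH <- makeTable(pos = seq_len(n) * 10, nUnc = cH, nConv = 30L - cH)
  callsH <- callSites(xH, cal)
  powerExact <- sum(vapply(0:30, function(c) {
    if (binomialSiteTest(c, 30L, 0.005) < 0.025)
      exp(lchoose(30, c) + c * log(0.2) + (30 - c) * log(0.8)) else 0
  }, numeric(1)))
  expect_gt(powerExact, 0.95)
  expect_lt(abs(mean(mcols(callsH)$highConfidence) - powerExact),
            3 * sqrt(powerExact * (1 - powerExact) / n) + 1e-9)
  # type-I error under the null (h = 0, all reads are error)
  c0 <- rbinom(n, 30L, 0.005)
  x0 <- makeTable(pos = seq_len(n) * 10, nUnc = c0, nConv = 30L - c0)
  calls0 <- callSites(x0, cal)
  expect_lte(mean(mcols(calls0)$highConfidence),
             0.025 + 3 * sqrt(0.025 * 0.975 / n))
})

test_that("high-fraction tiles need >=3 significant sites and level > 5%", {
  mk <- function(levels, hc, tile = 0L) {
    gr <- GRanges("chr1", IRanges(tile * 1000L + seq_along(levels) * 10L,
                                  width = 1L))
    mcols(gr) <- S4Vectors::DataFrame(
      coverage = 30L, nUnconverted = as.integer(30 * levels),
      level = levels, pValue = ifelse(hc, 1e-4, 0.5),
      highConfidence = hc)
    gr
  }
  # 3 significant sites, mean level 0.06 -> high fraction
  t1 <- highFractionTiles(mk(c(0.06, 0.06, 0.06), c(TRUE, TRUE, TRUE)))
  expect_true(mcols(t1)$isHighFraction)
  # 2 significant sites, mean level 0.10 -> fails the site count
  t2 <- highFractionTiles(mk(c(0.1, 0.1, 0.1), c(TRUE, TRUE, FALSE)))
  expect_false(mcols(t2)$isHighFraction)
  # 4 significant sites at exactly 5% -> strict inequality fails
  t3 <- highFractionTiles(mk(rep(0.05, 4), rep(TRUE, 4)))
  expect_false(mcols(t3)$isHighFraction)
  # tiling is anchored at 0 and non-overlapping
  calls <- mk(c(0.06, 0.06, 0.06), rep(TRUE, 3), tile = 7L)
  t4 <- highFractionTiles(calls)
  expect_equal(start(t4), 7001L)
  expect_equal(width(t4), 1000L)
})

test_that("tiles recover planted high-h regions and stay quiet on null", {
  cfg <- hydroxymap:::.twoGroupConfig(c(chrSim1 = 2e6), 0.0, 0.1369, 10L,
                                      7600L, 30, errorModel(),
                                      depthDispersion = 0.2)
  cal <- CalibrationResult(epsMCpG = 0.005,
                           support = c(mCpG = 1000L, CH = 0L, hmC = 0L))
  hits <- 0L; total <- 0L; falseTiles <- 0L; nullTiles <- 0L
  for (seed in 1:3) {
    sim <- simulateDataset(cfg, seed = seed)
    calls <- callSites(sim$tables[["alt.ACE.rep1"]], cal)
    tiles <- highFractionTiles(calls)
    high <- tiles[mcols(tiles)$isHighFraction]
    planted <- plantedRegions(sim$truth)
    covered <- countOverlaps(planted, high) > 0L
    hits <- hits + sum(covered); total <- total + length(planted)
    # tiles on the h = 0 background flagged high-fraction are false calls
    bg <- tiles[countOverlaps(tiles, planted) == 0L]
    falseTiles <- falseTiles + sum(mcols(bg)$isHighFraction)
    nullTiles <- nullTiles + length(bg)
  }
  expect_gte(hits / total, 0.9)
  expect_lte(falseTiles / nullTiles, 0.01)
})
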