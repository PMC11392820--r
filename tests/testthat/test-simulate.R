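test_that("identical seeds give bit-identical datasets", {
  cfg <- tinyConfig()
  s1 <- simulateDataset(cfg, seed = 1L)
  s2 <- simulateDataset(cfg, seed = 1L)
  expect_identical(lapply(s1$tables, siteRanges),
                   lapply(s2$tables, siteRanges))
  expect_identical(s1$truth@h, s2$truth@h)
  expect_identical(siteRanges(s1$spikes$lambda),
                   siteRanges(s2$spikes$lambda))
  s3 <- simulateDataset(cfg, seed = 2L)
  expect_false(identical(mcols(siteRanges(s1$tables[[1]])),
                         mcols(siteRanges(s3$tables[[1]]))))
})

test_that("noiseless limit: h = 1 everywhere yields fully unconverted ACE", {
  cfg <- simConfig(chromLengths = c(chrT = 5e4), chDensity = 0,
                   stages = "s", replicates = 1L,
                   hProfile = list(maternal = c(s = 1), paternal = c(s = 1)),
                   mProfile = list(maternal = c(s = 0), paternal = c(s = 0)),
                   betaPrecision = 1e6,
                   depthMean = 10, depthDispersion = 0,
                   errorModel = errorModel(epsMCpG = 0, epsU = 0, rho = 1,
                                           epsBs = 0),
                   regions = NULL, assays = "ACE")
  sim <- simulateDataset(cfg, seed = 3L)
  gr <- siteRanges(sim$tables[[1]])
  expect_true(all(mcols(gr)$nUnconverted == 10L))
  expect_true(all(mcols(gr)$nConverted == 0L))
  # and h = 0 with zero error rates yields fully converted reads
  cfg0 <- simConfig(chromLengths = c(chrT = 5e4), chDensity = 0,
                    stages = "s", replicates = 1L,
                    hProfile = list(maternal = c(s = 0),
                                    paternal = c(s = 0)),
                    mProfile = list(maternal = c(s = 0.5),
                                    paternal = c(s = 0.5)),
                    depthMean = 10, depthDispersion = 0,
                    errorModel = errorModel(epsMCpG = 0, epsU = 0, rho = 1,
                                            epsBs = 0),
                    regions = NULL, assays = "ACE")
  sim0 <- simulateDataset(cfg0, seed = 3L)
  expect_true(all(mcols(siteRanges(sim0$tables[[1]]))$nUnconverted == 0L))
})

test_that("observed levels agree with the analytic success probability", {
  cfg <- tinyConfig(chromLengths = c(chrT = 1e6))
  sim <- simulateDataset(cfg, seed = 13L)
  em <- cfg$errorModel
  tf <- trueFractions(sim$truth, "oocyte", "maternal")
  pExp <- tf$h * em$rho + tf$m * em$epsMCpG + tf$u * em$epsU
  x <- sim$tables[["oocyte.ACE.rep1"]]
  gr <- siteRanges(x)
  cpg <- mcols(gr)$context == "CpG"
  nU <- mcols(gr)$nUnconverted[cpg]
  tot <- nU + mcols(gr)$nConverted[cpg]
  obs <- sum(nU) / sum(tot)
  expected <- mean(pExp)
  se <- sqrt(expected * (1 - expected) / sum(tot))
  expect_lt(abs(obs - expected), 3 * se + 0.001)
  # WGBS level tracks m + h the same way
  w <- siteRanges(sim$tables[["oocyte.WGBS.rep1"]])
  cpgW <- mcols(w)$context == "CpG"
  nUw <- mcols(w)$nUnconverted[cpgW]
  totW <- nUw + mcols(w)$nConverted[cpgW]
  pW <- tf$m + tf$h + tf$u * em$epsBs
  expect_lt(abs(sum(nUw) / sum(totW) - mean(pW)), 0.003)
})

test_that("truth composition and planted regions obey their invariants", {
  sim <- simulateDataset(tinyConfig(), seed = 17L)
  tr <- sim$truth
  expect_true(max(abs(tr@u + tr@m + tr@h - 1)) < 1e-9)
  expect_true(min(tr@u, tr@m, tr@h) >= 0)
  # inside planted regions h is exactly the planted level on the planted
  # stage
  siteIn <- countOverlaps(tr@sites, plantedRegions(tr)) > 0
  oi <- match("oocyte", tr@stages)
  expect_true(all(tr@h[siteIn, oi, 1] == 0.1369))
  expect_true(all(tr@h[!siteIn, oi, 1] == 0.0575))
  # planting an empty region list leaves the truth unchanged
  tr2 <- plantRegions(tr, GRanges())
  expect_identical(tr2@h, tr@h)
  # overlapping plants are rejected
  ov <- GRanges("chrT", IRanges(c(1, 500), width = 1000L))
  expect_error(plantRegions(tr, ov), "overlap")
})

test_that("planting at the reported median geometry hits every inside site", {
  cfg <- simConfig(chromLengths = c(chrT = 2e5), chDensity = 0,
                   stages = "s", replicates = 1L,
                   hProfile = list(maternal = c(s = 0.01),
                                   paternal = c(s = 0.01)),
                   mProfile = list(maternal = c(s = 0.5),
                                   paternal = c(s = 0.5)),
                   regions = NULL, assays = "ACE")
  set.seed(1)
  truth <- hydroxymap:::.makeTruth(cfg)
  region <- GRanges("chrT", IRanges(50001, 50000 + 7600))
  planted <- plantRegions(truth, region, type = "hyper_hmDMR",
                          level = 0.1369)
  inside <- countOverlaps(truth@sites, region) > 0
  expect_true(all(planted@h[inside, 1, ] == 0.1369))
  expect_true(max(abs(planted@u + planted@m + planted@h - 1)) < 1e-9)
})

test_that("CH sites stay in the configured low range and spike-ins have
          the designed composition", {
  cfg <- tinyConfig()
  sim <- simulateDataset(cfg, seed = 19L)
  hCh <- mcols(sim$truth@chSites)$h
  expect_true(all(hCh >= 0.0012 & hCh <= 0.0020))
  lam <- siteRanges(sim$spikes$lambda)
  expect_setequal(unique(mcols(lam)$context), c("CpG", "CH"))
  # lambda CpG sites are fully methylated: nearly all reads convert
  lamCpG <- mcols(lam)$context == "CpG"
  lev <- sum(mcols(lam)$nUnconverted[lamCpG]) /
    sum((mcols(lam)$nUnconverted + mcols(lam)$nConverted)[lamCpG])
  expect_lt(lev, 0.03)
  hmc <- siteRanges(sim$spikes$hmcControl)
  levH <- sum(mcols(hmc)$nUnconverted) /
    sum(mcols(hmc)$nUnconverted + mcols(hmc)$nConverted)
  expect_gt(levH, 0.9)
})

test_that("allele-tagged emission splits reads at the assignable fraction", {
  cfg <- tinyConfig(alleleTagged = TRUE, chromLengths = c(chrT = 2e5),
                    regions = NULL)
  sim <- simulateDataset(cfg, seed = 23L)
  gr <- siteRanges(sim$tables[["oocyte.ACE.rep1"]])
  cpg <- gr[mcols(gr)$context == "CpG"]
  alleles <- table(mcols(cpg)$allele)
  expect_setequal(names(alleles), c("maternal", "paternal", "unassigned"))
  tot <- tapply(mcols(cpg)$nUnconverted + mcols(cpg)$nConverted,
                mcols(cpg)$allele, sum)
  # oocyte is fully maternal: assignable reads are maternal only
  expect_equal(unname(tot[["paternal"]]), 0)
  fracAssigned <- tot[["maternal"]] / sum(tot)
  expect_lt(abs(fracAssigned - 0.3), 0.02)
})

test_that("out-of-range composed probabilities are a config error", {
  em <- list(epsMCpG = 0.5, epsU = 0.9, rho = 2, epsBs = 0)
  expect_error(errorModel(rho = 2), "rates")
  cfg <- tinyConfig()
  cfg$errorModel$rho <- 2  # bypass the constructor check
  expect_error(simulateDataset(cfg, seed = 1L), "probability")
})
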