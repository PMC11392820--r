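test_that("site levels are C/(C+T), undefined (not zero) at no coverage", {
  x <- makeTable(pos = c(100, 200, 300), nUnc = c(3, 0, 0),
                 nConv = c(7, 10, 0))
  expect_equal(siteLevels(x), c(0.3, 0, NA))
  # scale invariance: (kC, kT) has the same level as (C, T)
  for (k in c(2L, 5L, 11L)) {
    xk <- makeTable(pos = c(100, 200), nUnc = k * c(3, 1),
                    nConv = k * c(7, 4))
    expect_equal(siteLevels(xk), c(0.3, 0.2))
  }
})

test_that("reader parses MethylDackel-style rows with 0/1-based conversion", {
  f <- tempfile()
  writeLines(c("track type=\"bedGraph\" name=x",
               "chr1\t99\t100\t.\t3\t7\t+\tCpG",
               "chr1\t199\t200\t0.5\t5\t5\t+\tCpG"), f)
  x <- readSiteCounts(f, assay = "ACE")
  gr <- siteRanges(x)
  expect_equal(start(gr), c(100L, 200L))
  expect_equal(mcols(gr)$nUnconverted, c(3L, 5L))
  expect_equal(siteLevels(x), c(0.3, 0.5))  # level column recomputed

  # header-only file gives an empty table
  f2 <- tempfile()
  writeLines("track type=\"bedGraph\"", f2)
  expect_length(readSiteCounts(f2, assay = "WGBS"), 0L)
})

test_that("reader rejects malformed rows and negative counts by line", {
  f <- tempfile()
  writeLines(c("chr1\t99\t100\t.\t3\t7", "chr1\txx\t200\t.\t1\t2"), f)
  expect_error(readSiteCounts(f, assay = "ACE"), "line 2")
  writeLines(c("chr1\t99\t100\t.\t-3\t7"), f)
  expect_error(readSiteCounts(f, assay = "ACE"), "negative")
  writeLines(c("chr1\t99\t100\t.\t3"), f)
  expect_error(readSiteCounts(f, assay = "ACE"), "malformed")
  expect_error(readSiteCounts(tempfile(), assay = "ACE"), "no such file")
})

test_that("unsorted input is sorted with a warning", {
  f <- tempfile()
  writeLines(c("chr1\t199\t200\t.\t1\t9", "chr1\t99\t100\t.\t3\t7"), f)
  expect_warning(x <- readSiteCounts(f, assay = "ACE"), "sorted")
  expect_equal(start(siteRanges(x)), c(100L, 200L))
})

test_that("write/read round-trips counts bit-exactly on generated data", {
  sim <- simulateDataset(tinyConfig(), seed = 11L)
  for (nm in c("oocyte.ACE.rep1", "sperm.WGBS.rep2")) {
    x <- sim$tables[[nm]]
    f <- tempfile()
    writeSiteCounts(x, f)
    y <- readSiteCounts(f, assay = assayType(x), stage = stageLabel(x))
    expect_identical(mcols(siteRanges(y))$nUnconverted,
                     mcols(siteRanges(x))$nUnconverted)
    expect_identical(mcols(siteRanges(y))$nConverted,
                     mcols(siteRanges(x))$nConverted)
    expect_identical(start(siteRanges(y)), start(siteRanges(x)))
    expect_identical(mcols(siteRanges(y))$context,
                     mcols(siteRanges(x))$context)
  }
})

test_that("bedGraph output converts coordinates, omits zero coverage,

          and round-trips levels to 1e-6", {
  x <- makeTable(pos = c(100, 250, 300), nUnc = c(3, 0, 2),
                 nConv = c(7, 0, 4))
  f <- tempfile()
  writeBedGraph(x, f)
  lines <- readLines(f)
  expect_equal(lines[1], "chr1\t99\t100\t0.300000")
  expect_length(lines, 2L)  # zero-coverage site omitted
  back <- readBedGraph(f)
  expect_equal(mcols(back)$level, c(0.3, 2 / 6), tolerance = 1e-6)
  # empty level set writes an empty file
  f2 <- tempfile()
  writeBedGraph(makeTable(pos = 5, nUnc = 0, nConv = 0), f2)
  expect_length(readLines(f2), 0L)
})

test_that("dyad collapse sums the minus strand onto pos - 1", {
  x <- SiteCountTable(chrom = c("chr1", "chr1"), pos = c(100L, 101L),
                      nUnconverted = c(3L, 2L), nConverted = c(7L, 8L),
                      strand = c("+", "-"), assay = "ACE")
  y <- collapseStrands(x)
  expect_length(y, 1L)
  expect_equal(start(siteRanges(y)), 100L)
  expect_equal(mcols(siteRanges(y))$nUnconverted, 5L)
  expect_equal(mcols(siteRanges(y))$nConverted, 15L)
})

test_that("replicate aggregation sums counts; commutative and associative", {
  a <- makeTable(pos = c(100, 200), nUnc = c(2, 1), nConv = c(3, 4))
  b <- makeTable(pos = c(100, 300), nUnc = c(1, 5), nConv = c(4, 5))
  ab <- aggregateReplicates(list(a, b))
  gr <- siteRanges(ab)
  expect_equal(start(gr), c(100L, 200L, 300L))
  expect_equal(mcols(gr)$nUnconverted, c(3L, 1L, 5L))
  expect_equal(mcols(gr)$nConverted, c(7L, 4L, 5L))
  # identity, commutativity, associativity
  expect_equal(siteRanges(aggregateReplicates(list(a))), siteRanges(a))
  ba <- aggregateReplicates(list(b, a))
  expect_equal(mcols(siteRanges(ba)), mcols(gr))
  c3 <- makeTable(pos = 100, nUnc = 10, nConv = 0)
  left <- aggregateReplicates(list(aggregateReplicates(list(a, b)), c3))
  right <- aggregateReplicates(list(a, aggregateReplicates(list(b, c3))))
  expect_equal(mcols(siteRanges(left)), mcols(siteRanges(right)))
  # mixed assay or stage is an error
  w <- makeTable(pos = 100, nUnc = 1, nConv = 1, assay = "WGBS")
  expect_error(aggregateReplicates(list(a, w)), "assay")
  s2 <- makeTable(pos = 100, nUnc = 1, nConv = 1, stage = "other")
  expect_error(aggregateReplicates(list(a, s2)), "stage")
})

test_that("aggregating generated replicates equals the generator's sums", {
  sim <- simulateDataset(tinyConfig(), seed = 21L)
  reps <- list(sim$tables[["oocyte.ACE.rep1"]],
               sim$tables[["oocyte.ACE.rep2"]])
  agg <- aggregateReplicates(reps)
  manual <- mcols(siteRanges(reps[[1]]))$nUnconverted +
    mcols(siteRanges(reps[[2]]))$nUnconverted
  expect_identical(mcols(siteRanges(agg))$nUnconverted, manual)
})

test_that("table validity rejects bad counts, duplicates and assays", {
  expect_error(makeTable(pos = 1, nUnc = -1, nConv = 2), "non-negative")
  expect_error(SiteCountTable(chrom = c("c", "c"), pos = c(5L, 5L),
                              nUnconverted = c(1L, 1L),
                              nConverted = c(1L, 1L), assay = "ACE"),
               "duplicate")
  expect_error(makeTable(pos = 1, nUnc = 1, nConv = 1, context = "CHH"),
               "context")
})
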