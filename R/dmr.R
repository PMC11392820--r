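# Sliding-window DMR/hmDMR calling between two conditions.
#
# Procedure: 100-bp window units (>=2 CpGs covered in both conditions),
# paired t-test on 1-kb sliding tiles stepped by 300 bp, merge of
# overlapping candidate tiles (p < 0.1) by label, a second merge of
# same-label regions within 10 kb, then a region-level paired t-test with
# Benjamini-Hochberg adjustment. Effect cutoffs: |diff| > 0.25 for 5mC,
# > 0.1 for 5hmC; adjusted p < 0.01 (5mC) / < 0.025 (5hmC); >= 3 CpGs
# covered in both conditions inside the region.

.markCutoffs <- function(mark) {
  switch(mark,
    "5mC" = list(diff = 0.25, alpha = 0.01),
    "5hmC" = list(diff = 0.1, alpha = 0.025),
    stop("mark must be \"5mC\" or \"5hmC\"")
  )
}

.pairedSiteDT <- function(a, b) {
  one <- function(x) {
    gr <- siteRanges(x)
    keep <- mcols(gr)$context == "CpG"
    gr <- gr[keep]
    nU <- mcols(gr)$nUnconverted
    tot <- nU + mcols(gr)$nConverted
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               level = ifelse(tot > 0L, nU / tot, NA_real_))[tot > 0L]
  }
  dtA <- one(a); dtB <- one(b)
  merge(dtA, dtB, by = c("chrom", "pos"), suffixes = c("A", "B"))
}

#' Build 100-bp window units from two conditions
#'
#' Fixed windows anchored at coordinate 0. A window's level in each
#' condition is the unweighted mean of the levels of CpG sites covered in
#' both conditions; windows with fewer than `minCpG` such sites are
#' dropped.
#'
#' @param a,b [SiteCountTable-class] objects (replicates already merged),
#'   same assay.
#' @param windowSize window width in bp (default 100).
#' @param minCpG minimum CpGs covered in both conditions (default 2).
#' @return GRanges of retained windows with metadata columns `nCpG`,
#'   `levelA`, `levelB`.
#' @export
makeWindowUnits <- function(a, b, windowSize = 100L, minCpG = 2L) {
  merged <- .pairedSiteDT(a, b)
  if (!nrow(merged)) {
    out <- GRanges()
    mcols(out) <- DataFrame(nCpG = integer(), levelA = numeric(),
                            levelB = numeric())
    return(out)
  }
  merged[, win := (pos - 1L) %/% as.integer(windowSize)]
  agg <- merged[, .(nCpG = .N, levelA = mean(levelA), levelB = mean(levelB)),
                by = .(chrom, win)]
  agg <- agg[nCpG >= minCpG]
  setorder(agg, chrom, win)
  out <- GRanges(agg$chrom,
                 IRanges(agg$win * as.integer(windowSize) + 1L,
                         width = as.integer(windowSize)))
  mcols(out) <- DataFrame(nCpG = agg$nCpG, levelA = agg$levelA,
                          levelB = agg$levelB)
  out
}

# closed-form one-sample t-test on paired differences; conventions for
# degenerate tiles: all diffs equal and nonzero -> p = 0 (infinitely
# strong signal, zero variance), all diffs zero -> p = 1
.pairedT <- function(n, meanDiff, sdDiff) {
  p <- rep(NA_real_, length(n))
  ok <- n >= 2L & !is.na(sdDiff)
  zeroVar <- ok & sdDiff == 0
  p[zeroVar & meanDiff == 0] <- 1
  p[zeroVar & meanDiff != 0] <- 0
  reg <- ok & sdDiff > 0
  tstat <- meanDiff[reg] / (sdDiff[reg] / sqrt(n[reg]))
  p[reg] <- 2 * pt(-abs(tstat), n[reg] - 1L)
  p
}

#' Paired t-tests on sliding tiles
#'
#' Slides tiles of `tileSize` bp stepped by `step` bp (anchored at 0)
#' over the window units and runs a paired two-sided Student's t-test on
#' the per-window level differences (condition A minus B) of the units
#' fully contained in each tile. Tiles with fewer than `minUnits` member
#' units are skipped.
#'
#' @param units GRanges from [makeWindowUnits()].
#' @param tileSize tile length in bp (default 1000).
#' @param step step size in bp (default 300).
#' @param minUnits minimum member units for testing (default 3).
#' @return GRanges of tested tiles with metadata columns `nUnits`,
#'   `meanDiff` (mean of unit differences), `pValue`.
#' @export
slidingTest <- function(units, tileSize = 1000L, step = 300L,
                        minUnits = 3L) {
  empty <- function() {
    out <- GRanges()
    mcols(out) <- DataFrame(nUnits = integer(), meanDiff = numeric(),
                            pValue = numeric())
    out
  }
  if (!length(units)) return(empty())
  winSize <- width(units)[1L]
  nOff <- (as.integer(tileSize) - winSize) %/% as.integer(step) + 1L
  dt <- data.table(chrom = as.character(seqnames(units)),
                   ws = start(units) - 1L,
                   diffAB = mcols(units)$levelA - mcols(units)$levelB)
  ex <- dt[rep(seq_len(.N), each = nOff)]
  ex[, tile := ws %/% as.integer(step) - rep(seq_len(nOff) - 1L,
                                             times = nrow(dt))]
  # keep tiles that start at/before the window and end at/after it
  ex <- ex[tile >= 0L & ws + winSize <= tile * as.integer(step) +
             as.integer(tileSize) & ws >= tile * as.integer(step)]
  agg <- ex[, .(nUnits = .N, meanDiff = mean(diffAB),
                sdDiff = sd(diffAB)), by = .(chrom, tile)]
  agg <- agg[nUnits >= minUnits]
  if (!nrow(agg)) return(empty())
  setorder(agg, chrom, tile)
  p <- .pairedT(agg$nUnits, agg$meanDiff, agg$sdDiff)
  out <- GRanges(agg$chrom,
                 IRanges(agg$tile * as.integer(step) + 1L,
                         width = as.integer(tileSize)))
  mcols(out) <- DataFrame(nUnits = agg$nUnits, meanDiff = agg$meanDiff,
                          pValue = p)
  out
}

#' Merge candidate tiles into labelled candidate regions
#'
#' Tiles with `pValue < pMerge` are labelled `hyper` when their mean
#' difference exceeds `diffCutoff` and `hypo` when below `-diffCutoff`
#' (others are discarded). Overlapping same-label tiles are merged, and
#' same-label merged regions separated by at most `maxGap` bp are merged
#' again.
#'
#' @param tiles GRanges from [slidingTest()].
#' @param diffCutoff effect-size cutoff (0.25 for 5mC, 0.1 for 5hmC).
#' @param pMerge tile p-value threshold for candidacy (default 0.1).
#' @param maxGap second-pass merge distance in bp (default 10000).
#' @return GRanges of candidate regions with metadata column `label`.
#' @export
mergeCandidates <- function(tiles, diffCutoff, pMerge = 0.1,
                            maxGap = 10000L) {
  lab <- rep(NA_character_, length(tiles))
  sel <- !is.na(mcols(tiles)$pValue) & mcols(tiles)$pValue < pMerge
  lab[sel & mcols(tiles)$meanDiff > diffCutoff] <- "hyper"
  lab[sel & mcols(tiles)$meanDiff < -diffCutoff] <- "hypo"
  pieces <- lapply(c("hyper", "hypo"), function(l) {
    g <- granges(tiles[!is.na(lab) & lab == l])
    if (length(g))
      g <- reduce(reduce(g), min.gapwidth = as.integer(maxGap) + 1L)
    mcols(g)$label <- rep(l, length(g))
    g
  })
  sort(do.call(c, pieces), ignore.strand = TRUE)
}

#' Finalise DMRs: region-level test, FDR, and threshold filters
#'
#' Recomputes the paired t-test over the window units contained in each
#' candidate region, adjusts across candidates with Benjamini-Hochberg,
#' counts the CpG sites covered in both conditions inside the region, and
#' retains regions that pass the mark's thresholds: at least `minCpG`
#' aggregate CpGs, adjusted p below the mark's cutoff, absolute mean
#' difference above the mark's effect cutoff, and a sign consistent with
#' the label.
#'
#' @param candidates GRanges from [mergeCandidates()].
#' @param units GRanges from [makeWindowUnits()].
#' @param a,b the condition [SiteCountTable-class] objects (for aggregate
#'   CpG support).
#' @param mark `"5mC"` or `"5hmC"`; sets the effect cutoff (0.25 / 0.1)
#'   and adjusted-p cutoff (0.01 / 0.025).
#' @param minCpG minimum CpGs covered in both conditions (default 3).
#' @return GRanges of DMRs with metadata columns `label`, `mark`, `nCpG`,
#'   `nUnits`, `meanDiff`, `pValue`, `pAdj`.
#' @export
finalizeDmrs <- function(candidates, units, a, b, mark = c("5hmC", "5mC"),
                         minCpG = 3L) {
  mark <- match.arg(mark)
  cut <- .markCutoffs(mark)
  emptyDmr <- function() {
    out <- GRanges()
    mcols(out) <- DataFrame(label = character(), mark = character(),
                            nCpG = integer(), nUnits = integer(),
                            meanDiff = numeric(), pValue = numeric(),
                            pAdj = numeric())
    out
  }
  if (!length(candidates)) return(emptyDmr())
  hits <- findOverlaps(units, candidates, type = "within")
  dt <- data.table(region = subjectHits(hits),
                   diffAB = (mcols(units)$levelA -
                               mcols(units)$levelB)[queryHits(hits)])
  agg <- dt[, .(nUnits = .N, meanDiff = mean(diffAB), sdDiff = sd(diffAB)),
            by = region]
  stats <- data.table(region = seq_along(candidates))
  agg <- agg[stats, on = "region"]
  agg[is.na(nUnits), nUnits := 0L]
  setorder(agg, region)
  p <- .pairedT(agg$nUnits, agg$meanDiff, agg$sdDiff)
  pAdj <- p.adjust(p, method = "BH")
  # aggregate CpG support: sites covered in both conditions in the region
  paired <- .pairedSiteDT(a, b)
  siteGr <- GRanges(paired$chrom, IRanges(paired$pos, width = 1L))
  nCpG <- countOverlaps(candidates, siteGr)
  keep <- !is.na(p) & nCpG >= minCpG & pAdj < cut$alpha &
    abs(agg$meanDiff) > cut$diff &
    ifelse(mcols(candidates)$label == "hyper",
           agg$meanDiff > 0, agg$meanDiff < 0)
  out <- granges(candidates[keep])
  mcols(out) <- DataFrame(label = mcols(candidates)$label[keep],
                          mark = mark, nCpG = nCpG[keep],
                          nUnits = agg$nUnits[keep],
                          meanDiff = agg$meanDiff[keep],
                          pValue = p[keep], pAdj = pAdj[keep])
  out
}

#' Call DMRs or hmDMRs between two conditions
#'
#' End-to-end sliding-window procedure (see the individual steps
#' [makeWindowUnits()], [slidingTest()], [mergeCandidates()],
#' [finalizeDmrs()]). For hmDMRs pass ACE-seq tables and `mark = "5hmC"`;
#' for 5mC DMRs pass WGBS tables and `mark = "5mC"`. `hyper` means the
#' level in `a` exceeds that in `b`. Swapping `a` and `b` swaps
#' hyper/hypo labels and leaves boundaries and p-values unchanged.
#'
#' @param a,b [SiteCountTable-class] objects, replicates already merged
#'   (see [aggregateReplicates()]).
#' @param mark `"5hmC"` (effect cutoff 0.1, adjusted p < 0.025) or
#'   `"5mC"` (0.25, adjusted p < 0.01).
#' @param windowSize,minCpGWindow 100-bp units with >= 2 covered CpGs.
#' @param tileSize,step,minUnits 1-kb tiles stepped by 300 bp, tested at
#'   >= 3 member units.
#' @param pMerge,maxGap candidate threshold p < 0.1; same-label merge
#'   within 10 kb.
#' @param minCpG region-level CpG support (>= 3).
#' @return GRanges of DMRs (see [finalizeDmrs()]).
#' @export
callDMRs <- function(a, b, mark = c("5hmC", "5mC"), windowSize = 100L,
                     minCpGWindow = 2L, tileSize = 1000L, step = 300L,
                     minUnits = 3L, pMerge = 0.1, maxGap = 10000L,
                     minCpG = 3L) {
  mark <- match.arg(mark)
  cut <- .markCutoffs(mark)
  units <- makeWindowUnits(a, b, windowSize = windowSize,
                           minCpG = minCpGWindow)
  tiles <- slidingTest(units, tileSize = tileSize, step = step,
                       minUnits = minUnits)
  cand <- mergeCandidates(tiles, diffCutoff = cut$diff, pMerge = pMerge,
                          maxGap = maxGap)
  finalizeDmrs(cand, units, a, b, mark = mark, minCpG = minCpG)
}
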