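# Enrichment of high-confidence 5hmCpG sites and of DMRs at genomic
# elements, and target-gene assignment for motif hits / regions.

#' Enrichment of high-confidence 5hmCpG sites in genomic elements
#'
#' For each element class, the density of high-confidence sites among
#' detected sites per megabase of element is compared with the same
#' quantity genome-wide:
#' `enrichment = [(hcIn / detectedIn) / elementMb] /
#'               [(hcTotal / detectedTotal) / genomeMb]`.
#' "Detected" sites are CpGs covered at least `minDetectCov` times
#' (default 2x). An element covering the whole genome has enrichment 1 by
#' construction; the statistic depends only on the union geometry of each
#' class, not on how its intervals are split. Raw per-Mb densities are
#' also reported.
#'
#' @param calls GRanges from [callSites()] (carries `coverage` and
#'   `highConfidence`).
#' @param elements GRanges of elements with a metadata column `group`
#'   naming the class, or a named [GenomicRanges::GRangesList].
#' @param genomeLength total genome length in bp; defaults to the sum of
#'   `seqlengths(calls)` when set.
#' @param minDetectCov coverage defining a detected site (default 2).
#' @return data.frame with one row per class: counts, lengths (Mb),
#'   densities and `enrichment` (NA when the class holds no detected
#'   site).
#' @export
siteEnrichment <- function(calls, elements, genomeLength = NULL,
                           minDetectCov = 2L) {
  if (is.null(genomeLength)) {
    sl <- seqlengths(calls)
    if (any(is.na(sl)))
      stop("genomeLength not given and seqlengths(calls) incomplete")
    genomeLength <- sum(as.numeric(sl))
  }
  if (is(elements, "GRangesList")) {
    classes <- names(elements)
    getClass <- function(cl) elements[[cl]]
  } else {
    if (!"group" %in% colnames(mcols(elements)))
      stop("elements need a 'group' metadata column (or pass a GRangesList)")
    classes <- unique(mcols(elements)$group)
    getClass <- function(cl) elements[mcols(elements)$group == cl]
  }
  detected <- calls[mcols(calls)$coverage >= minDetectCov]
  hc <- detected[mcols(detected)$highConfidence]
  nDetTot <- length(detected)
  nHcTot <- length(hc)
  genomeMb <- genomeLength / 1e6
  densGenome <- (nHcTot / nDetTot) / genomeMb
  rows <- lapply(classes, function(cl) {
    red <- reduce(getClass(cl), ignore.strand = TRUE)
    elemMb <- sum(as.numeric(width(red))) / 1e6
    nDetIn <- sum(countOverlaps(detected, red, ignore.strand = TRUE) > 0L)
    nHcIn <- sum(countOverlaps(hc, red, ignore.strand = TRUE) > 0L)
    densIn <- if (nDetIn > 0L && elemMb > 0) (nHcIn / nDetIn) / elemMb
              else NA_real_
    data.frame(class = cl, nHcIn = nHcIn, nDetectedIn = nDetIn,
               elementLenMb = elemMb, densityIn = densIn,
               densityGenome = densGenome,
               enrichment = densIn / densGenome)
  })
  do.call(rbind, rows)
}

#' Fisher's exact enrichment of DMR bases in an element class
#'
#' Discretises the genome into blocks of `unit` bp and tests whether DMR
#' blocks preferentially fall inside the element with a one-sided
#' hypergeometric tail: `P(X >= overlap)` with `X` the overlap of a
#' random placement of the DMR blocks among the genome blocks. The
#' enrichment score is `-log10(p)`, capped at 300; the tail is evaluated
#' in log space so extreme scores stay accurate.
#'
#' @param dmrs,elements GRanges; each set is reduced (internally merged)
#'   before measuring lengths.
#' @param genomeLength total genome length in bp.
#' @param unit block size in bp (default 1000).
#' @return data.frame with the 2x2 lengths in blocks (`overlap`, `dmr`,
#'   `element`, `genome`), `pValue` and `score`.
#' @export
dmrEnrichment <- function(dmrs, elements, genomeLength, unit = 1000L) {
  d <- reduce(granges(dmrs), ignore.strand = TRUE)
  e <- reduce(granges(elements), ignore.strand = TRUE)
  ov <- sum(as.numeric(width(GenomicRanges::intersect(d, e,
                                                      ignore.strand = TRUE))))
  dLen <- sum(as.numeric(width(d)))
  eLen <- sum(as.numeric(width(e)))
  if (genomeLength < dLen + eLen - ov)
    stop("genomeLength smaller than the union of DMRs and elements")
  toUnits <- function(x) as.integer(round(x / unit))
  q <- toUnits(ov); m <- toUnits(dLen); k <- toUnits(eLen)
  n <- toUnits(genomeLength)
  res <- hyperTailLog10(q, m, k, n)
  data.frame(overlap = q, dmr = m, element = k, genome = n,
             pValue = res$p, score = res$score)
}

# one-sided hypergeometric tail P(X >= q) for overlap q of m draws from a
# genome of n units containing k element units; log-space for accuracy
hyperTailLog10 <- function(q, m, k, n) {
  lp <- phyper(q - 1, k, n - k, m, lower.tail = FALSE, log.p = TRUE)
  score <- pmin(300, -lp / log(10))
  list(p = exp(lp), score = score)
}

#' Assign target genes to hits within the TSS-upstream window
#'
#' A gene is a target of a hit (motif match, region, peak) when the hit
#' overlaps the 15-kb window upstream of the gene's transcription start
#' site: `[tss - upstream, tss]` on the + strand, `[tss, tss + upstream]`
#' on the - strand (1-based, inclusive; downstream hits never qualify).
#'
#' @param hits GRanges of hit intervals.
#' @param tss data.frame with columns `geneId`, `chrom`, `tssPos`
#'   (1-based), `strand`, or a GRanges of width-1 TSS positions with a
#'   `geneId` metadata column.
#' @param upstream window size in bp (default 15000).
#' @return A [IRanges::CharacterList] of target gene ids, one element per
#'   hit.
#' @export
assignTargetGenes <- function(hits, tss, upstream = 15000L) {
  if (is(tss, "GRanges")) {
    tss <- data.frame(geneId = mcols(tss)$geneId,
                      chrom = as.character(seqnames(tss)),
                      tssPos = start(tss),
                      strand = as.character(strand(tss)))
  }
  stopifnot(all(c("geneId", "chrom", "tssPos", "strand") %in% names(tss)))
  plus <- tss$strand == "+"
  winStart <- ifelse(plus, pmax(1L, tss$tssPos - as.integer(upstream)),
                     tss$tssPos)
  winEnd <- ifelse(plus, tss$tssPos, tss$tssPos + as.integer(upstream))
  windows <- GRanges(tss$chrom, IRanges(winStart, winEnd))
  ov <- findOverlaps(hits, windows, ignore.strand = TRUE)
  genes <- S4Vectors::splitAsList(tss$geneId[subjectHits(ov)],
                                  factor(queryHits(ov),
                                         levels = seq_along(hits)))
  unname(IRanges::CharacterList(genes))
}

#' Partition genes by overlap with a region set
#'
#' At least one base of overlap (strand-agnostic) places a gene body in
#' the overlapping group.
#'
#' @param genes GRanges of gene bodies.
#' @param regions GRanges (e.g. hyper hmDMRs).
#' @return list with GRanges elements `overlapping` and `nonOverlapping`.
#' @export
overlapGroups <- function(genes, regions) {
  hit <- countOverlaps(genes, regions, ignore.strand = TRUE) > 0L
  list(overlapping = genes[hit], nonOverlapping = genes[!hit])
}
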