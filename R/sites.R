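#' One-sided binomial tail test for 5hmC at a site
#'
#' Probability of observing at least the given number of unconverted reads
#' under the null that every C read is assay error:
#' `P(X >= nUnconverted)` for `X ~ Binomial(nTotal, eps)`, where `eps` is
#' the spike-in calibrated non-conversion rate. Vectorised over sites.
#'
#' @param nUnconverted integer count(s) of reads observed as C.
#' @param nTotal integer total read count(s).
#' @param eps error rate(s) in \[0, 1\].
#' @return p-value(s); NA where `nTotal` is 0 (site not testable).
#' @examples
#' binomialSiteTest(0, 10, 0.01)   # 1
#' binomialSiteTest(3, 20, 0.01)   # ~1.03e-3
#' @export
binomialSiteTest <- function(nUnconverted, nTotal, eps) {
  stopifnot(all(nUnconverted >= 0), all(nUnconverted <= nTotal),
            all(eps >= 0 & eps <= 1))
  p <- pbinom(nUnconverted - 1L, nTotal, eps, lower.tail = FALSE)
  p[nTotal == 0L] <- NA_real_
  p
}

#' Call high-confidence 5hmCpG sites from an ACE-seq table
#'
#' Every covered CpG site with coverage at least `minCov` receives a
#' one-sided binomial p-value against the calibrated 5mC non-conversion
#' rate; sites with `p < alpha` (strict) are flagged high-confidence. No
#' multiple-testing adjustment is applied: the fixed per-site alpha is the
#' operating point of the caller. Sites covered below `minCov` are kept in
#' the output (they still contribute levels and "detected" denominators)
#' but receive no p-value.
#'
#' @param x [SiteCountTable-class] from the ACE assay.
#' @param calib [CalibrationResult-class]; `epsMCpG` is the null error
#'   rate (5mC escaping deamination is the dominant confusable signal at
#'   CpG sites).
#' @param alpha per-site significance threshold (default 0.025).
#' @param minCov minimum coverage for testing (default 2, the coverage
#'   notion used when counting detected sites).
#' @return GRanges of covered CpG sites with metadata columns `coverage`,
#'   `nUnconverted`, `level`, `pValue`, `highConfidence`; `alpha`, `eps`
#'   and `minCov` are recorded in `metadata()`.
#' @export
callSites <- function(x, calib, alpha = 0.025, minCov = 2L) {
  if (assayType(x) != "ACE")
    stop("site calling expects an ACE-seq table")
  if (!alpha > 0 || !alpha < 1) stop("alpha must be in (0, 1)")
  eps <- epsMCpG(calib)
  if (is.na(eps))
    stop("calibration does not provide the 5mCpG non-conversion rate")
  gr <- siteRanges(x)
  keep <- mcols(gr)$context == "CpG"
  gr <- gr[keep]
  nU <- mcols(gr)$nUnconverted
  cov <- nU + mcols(gr)$nConverted
  gr <- gr[cov > 0L]
  nU <- nU[cov > 0L]
  cov <- cov[cov > 0L]
  p <- rep(NA_real_, length(gr))
  testable <- cov >= minCov
  p[testable] <- binomialSiteTest(nU[testable], cov[testable], eps)
  out <- granges(gr)
  mcols(out) <- DataFrame(
    coverage = cov, nUnconverted = nU, level = nU / cov, pValue = p,
    highConfidence = !is.na(p) & p < alpha
  )
  metadata(out) <- list(alpha = alpha, eps = eps, minCov = as.integer(minCov),
                        sampleId = sampleId(x), stage = stageLabel(x))
  out
}

#' Define high-5hmC-fraction tiles
#'
#' Divides each chromosome into non-overlapping tiles (1 kb by default,
#' anchored at coordinate 0), computes the unweighted mean of per-site
#' 5hmC levels over covered CpGs in each tile and counts the significant
#' (high-confidence) sites it contains. A tile is high-fraction when it
#' holds at least `minSignificant` significant sites and its mean level is
#' strictly greater than `minLevel`.
#'
#' @param calls GRanges from [callSites()].
#' @param tileSize tile width in bp (default 1000).
#' @param minSignificant minimum high-confidence sites (default 3).
#' @param minLevel mean-level threshold, strict inequality (default 0.05).
#' @return GRanges of tiles containing at least one covered CpG, with
#'   metadata columns `nSites`, `nSignificant`, `meanLevel`,
#'   `isHighFraction`.
#' @export
highFractionTiles <- function(calls, tileSize = 1000L, minSignificant = 3L,
                              minLevel = 0.05) {
  dt <- data.table(
    chrom = as.character(seqnames(calls)),
    tile = (start(calls) - 1L) %/% as.integer(tileSize),
    level = mcols(calls)$level,
    hc = mcols(calls)$highConfidence
  )
  agg <- dt[, .(nSites = .N, nSignificant = sum(hc),
                meanLevel = mean(level)), by = .(chrom, tile)]
  setorder(agg, chrom, tile)
  out <- GRanges(agg$chrom,
                 IRanges(agg$tile * as.integer(tileSize) + 1L,
                         width = as.integer(tileSize)))
  mcols(out) <- DataFrame(
    nSites = agg$nSites, nSignificant = agg$nSignificant,
    meanLevel = agg$meanLevel,
    isHighFraction = agg$nSignificant >= minSignificant &
      agg$meanLevel > minLevel
  )
  metadata(out) <- list(tileSize = as.integer(tileSize),
                        minSignificant = as.integer(minSignificant),
                        minLevel = minLevel)
  out
}
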