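#' Jointly estimate (unmodified, 5mC, 5hmC) fractions from paired counts
#'
#' Model: the WGBS unconverted fraction estimates `m + h`, the ACE-seq
#' unconverted fraction estimates `h`. With exactly these two assays the
#' constrained maximum-likelihood estimate has a closed form. When the
#' naive estimates are consistent (`pAce <= pBs`) the MLE is the naive
#' subtraction `h = pAce`, `m = pBs - pAce`, `u = 1 - pBs`. When they
#' conflict (`pAce > pBs`, i.e. the naive 5mC component is negative) the
#' constrained maximum lies on the boundary `m = 0`, where both assays
#' measure the same parameter and the MLE pools the counts:
#' `h = (cBs + cAce) / (nBs + nAce)`. Conflicted sites are flagged and,
#' following the exclusion rule for negative or conflicting levels,
#' excluded by default; `ciConflict = TRUE` instead excludes only sites
#' whose Wilson score intervals are disjoint (see [conflictTest()]).
#'
#' @param cBs,nBs WGBS unconverted and total read counts (vectorised).
#' @param cAce,nAce ACE-seq unconverted and total read counts.
#' @param ciConflict use the interval-based conflict criterion for
#'   exclusion instead of the raw negative-component rule.
#' @param gamma confidence level of the Wilson intervals when
#'   `ciConflict = TRUE`.
#' @return data.frame with columns `u`, `m`, `h`, `conflict`, `excluded`.
#'   Rows with zero coverage in either assay are uncallable: all NA with
#'   `excluded = TRUE`.
#' @examples
#' tripleFromCounts(8, 10, 3, 10)  # u 0.2, m 0.5, h 0.3
#' tripleFromCounts(3, 10, 5, 10)  # conflict: h pooled to 0.4, m 0
#' @export
tripleFromCounts <- function(cBs, nBs, cAce, nAce, ciConflict = FALSE,
                             gamma = 0.95) {
  n <- max(length(cBs), length(cAce))
  cBs <- rep_len(as.numeric(cBs), n); nBs <- rep_len(as.numeric(nBs), n)
  cAce <- rep_len(as.numeric(cAce), n); nAce <- rep_len(as.numeric(nAce), n)
  callable <- nBs > 0 & nAce > 0
  pBs <- ifelse(callable, cBs / nBs, NA_real_)
  pAce <- ifelse(callable, cAce / nAce, NA_real_)
  conflict <- !is.na(pAce) & pAce > pBs
  h <- ifelse(conflict, (cBs + cAce) / (nBs + nAce), pAce)
  m <- ifelse(conflict, 0, pBs - pAce)
  u <- 1 - ifelse(conflict, h, pBs)
  if (ciConflict) {
    excl <- conflictTest(cBs, nBs, cAce, nAce, gamma = gamma)
  } else {
    excl <- conflict
  }
  out <- data.frame(u = u, m = m, h = h, conflict = conflict,
                    excluded = excl | !callable)
  out[!callable, c("u", "m", "h")] <- NA_real_
  out$conflict[!callable] <- NA
  out
}

#' Interval-based conflict test between the two assays
#'
#' A conservative alternative to the raw sign of the naive 5mC component:
#' the site is declared conflicted only when the `gamma`-level Wilson
#' score interval of the ACE fraction lies entirely above that of the
#' WGBS fraction, i.e. the disagreement is larger than sampling noise can
#' plausibly explain.
#'
#' @inheritParams tripleFromCounts
#' @param gamma confidence level in (0, 1).
#' @return logical vector.
#' @export
conflictTest <- function(cBs, nBs, cAce, nAce, gamma = 0.95) {
  if (!(gamma > 0 && gamma < 1)) stop("gamma must be in (0, 1)")
  stopifnot(all(nBs > 0), all(nAce > 0))
  bs <- wilsonInterval(cBs, nBs, gamma)
  ace <- wilsonInterval(cAce, nAce, gamma)
  ace[, "lower"] > bs[, "upper"]
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes, `n` trials, `gamma` confidence level.
#' @param n,gamma see above.
#' @return two-column matrix (`lower`, `upper`).
#' @export
wilsonInterval <- function(x, n, gamma = 0.95) {
  z <- qnorm(1 - (1 - gamma) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Triple estimation over paired SiteCountTables
#'
#' Matches CpG sites present in both the WGBS and ACE tables (by
#' chromosome, position, strand and allele) and runs [tripleFromCounts()]
#' on the paired counts.
#'
#' @param bs [SiteCountTable-class], WGBS assay.
#' @param ace [SiteCountTable-class], ACE assay.
#' @param ... passed to [tripleFromCounts()] (`ciConflict`, `gamma`).
#' @return GRanges of jointly covered CpG sites with metadata columns
#'   `u`, `m`, `h`, `conflict`, `excluded`, `nBs`, `nAce`.
#' @export
estimateTriple <- function(bs, ace, ...) {
  if (assayType(bs) != "WGBS" || assayType(ace) != "ACE")
    stop("estimateTriple(bs, ace) expects a WGBS table then an ACE table")
  key <- function(t) {
    gr <- siteRanges(t)
    keep <- mcols(gr)$context == "CpG" &
      mcols(gr)$nUnconverted + mcols(gr)$nConverted > 0L
    gr <- gr[keep]
    list(gr = gr,
         k = paste(as.character(seqnames(gr)), start(gr),
                   as.character(strand(gr)), mcols(gr)$allele))
  }
  b <- key(bs); a <- key(ace)
  idx <- match(b$k, a$k)
  hit <- !is.na(idx)
  grB <- b$gr[hit]
  grA <- a$gr[idx[hit]]
  nB <- mcols(grB)$nUnconverted + mcols(grB)$nConverted
  nA <- mcols(grA)$nUnconverted + mcols(grA)$nConverted
  est <- tripleFromCounts(mcols(grB)$nUnconverted, nB,
                          mcols(grA)$nUnconverted, nA, ...)
  out <- granges(grB)
  mcols(out) <- DataFrame(est, nBs = nB, nAce = nA)
  out
}
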