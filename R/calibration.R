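#' Estimate deamination error rates from the lambda DNA spike-in
#'
#' The in vitro CpG-methylated lambda spike-in carries fully methylated
#' CpG sites and unmodified CH sites. In ACE-seq every C read at a lambda
#' CpG is a 5mC that escaped deamination, so the pooled CpG level is the
#' 5mC non-conversion (deamination error) rate; CH sites give the
#' unmodified-C non-conversion rate the same way. Rates are pooled
#' (read-weighted) across sites by default, which is stable under
#' heterogeneous coverage; `perSite = TRUE` averages per-site levels
#' instead.
#'
#' @param spike [SiteCountTable-class] of the lambda spike-in (ACE assay),
#'   with `context` distinguishing CpG from CH sites.
#' @param perSite average per-site levels instead of pooling reads.
#' @return A [CalibrationResult-class] with `epsMCpG` and `epsCH` filled
#'   in (`rho` NA).
#' @export
calibrateLambda <- function(spike, perSite = FALSE) {
  gr <- siteRanges(spike)
  rate <- function(ctx) {
    keep <- mcols(gr)$context == ctx
    nU <- mcols(gr)$nUnconverted[keep]
    tot <- nU + mcols(gr)$nConverted[keep]
    n <- sum(tot)
    if (n == 0L) return(list(est = NA_real_, n = 0L))
    est <- if (perSite) {
      mean((nU / tot)[tot > 0L])
    } else {
      sum(nU) / n
    }
    list(est = est, n = as.integer(n))
  }
  cpg <- rate("CpG")
  ch <- rate("CH")
  CalibrationResult(epsMCpG = cpg$est, epsCH = ch$est,
                    support = c(mCpG = cpg$n, CH = ch$n, hmC = 0L))
}

#' Estimate the glucosylation protection rate from the 5hmC control
#'
#' On a fully hydroxymethylated control every cytosine is 5hmC, so the
#' pooled fraction of unconverted reads is the probability that a true
#' 5hmC is protected by glucosylation and survives deamination.
#'
#' @param spike [SiteCountTable-class] of the fully hydroxymethylated
#'   control (ACE assay).
#' @param perSite average per-site levels instead of pooling reads.
#' @return A [CalibrationResult-class] with `rho` filled in.
#' @export
calibrateProtection <- function(spike, perSite = FALSE) {
  gr <- siteRanges(spike)
  nU <- mcols(gr)$nUnconverted
  tot <- nU + mcols(gr)$nConverted
  n <- sum(tot)
  if (n == 0L)
    return(CalibrationResult(support = c(mCpG = 0L, CH = 0L, hmC = 0L)))
  est <- if (perSite) mean((nU / tot)[tot > 0L]) else sum(nU) / n
  CalibrationResult(rho = est,
                    support = c(mCpG = 0L, CH = 0L, hmC = as.integer(n)))
}

#' Combine lambda and protection calibrations into one result
#'
#' @param lambda [SiteCountTable-class] of the CpG-methylated lambda
#'   spike-in.
#' @param hmcControl [SiteCountTable-class] of the fully hydroxymethylated
#'   control, or NULL.
#' @param perSite see [calibrateLambda()].
#' @return A [CalibrationResult-class].
#' @export
calibrate <- function(lambda, hmcControl = NULL, perSite = FALSE) {
  lam <- calibrateLambda(lambda, perSite = perSite)
  if (is.null(hmcControl)) return(lam)
  pro <- calibrateProtection(hmcControl, perSite = perSite)
  sup <- calibSupport(lam)
  sup[["hmC"]] <- calibSupport(pro)[["hmC"]]
  CalibrationResult(epsMCpG = epsMCpG(lam), epsCH = epsCH(lam),
                    rho = protectionRate(pro), support = sup)
}
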