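#' Accessors for SiteCountTable and friends
#'
#' @param x a [SiteCountTable-class] (or, for `trueFractions` and
#'   `plantedRegions`, a [TrueMethylome-class]).
#' @return `siteRanges` the GRanges of sites; `sampleId`, `assayType`,
#'   `stageLabel` the respective labels; `siteCoverage` integer total reads
#'   per site; `siteLevels` the per-site methylation level
#'   `C / (C + T)`, NA (undefined, distinct from 0) at zero coverage.
#' @examples
#' x <- SiteCountTable(chrom = "chr1", pos = c(100L, 200L),
#'                     nUnconverted = c(3L, 0L), nConverted = c(7L, 0L),
#'                     sampleId = "s", assay = "ACE", stage = "oocyte")
#' siteLevels(x)   # 0.3 and NA (zero coverage)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("assayType", function(x) standardGeneric("assayType"))
#' @rdname accessors
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))
#' @rdname accessors
#' @export
setGeneric("siteCoverage", function(x) standardGeneric("siteCoverage"))
#' @rdname accessors
#' @export
setGeneric("siteLevels", function(x) standardGeneric("siteLevels"))

#' @rdname accessors
setMethod("siteRanges", "SiteCountTable", function(x) x@sites)
#' @rdname accessors
setMethod("sampleId", "SiteCountTable", function(x) x@sampleId)
#' @rdname accessors
setMethod("assayType", "SiteCountTable", function(x) x@assay)
#' @rdname accessors
setMethod("stageLabel", "SiteCountTable", function(x) x@stage)
#' @rdname accessors
setMethod("siteCoverage", "SiteCountTable", function(x) {
  mcols(x@sites)$nUnconverted + mcols(x@sites)$nConverted
})
#' @rdname accessors
setMethod("siteLevels", "SiteCountTable", function(x) {
  nU <- mcols(x@sites)$nUnconverted
  tot <- nU + mcols(x@sites)$nConverted
  ifelse(tot > 0L, nU / tot, NA_real_)
})

setMethod("length", "SiteCountTable", function(x) length(x@sites))

#' Calibration accessors
#'
#' @param x a [CalibrationResult-class].
#' @return The stored rate (`epsMCpG`, `epsCH`, `protectionRate`) or the
#'   named integer read support (`calibSupport`).
#' @name calibration-accessors
NULL

#' @rdname calibration-accessors
#' @export
setGeneric("epsMCpG", function(x) standardGeneric("epsMCpG"))
#' @rdname calibration-accessors
#' @export
setGeneric("epsCH", function(x) standardGeneric("epsCH"))
#' @rdname calibration-accessors
#' @export
setGeneric("protectionRate", function(x) standardGeneric("protectionRate"))
#' @rdname calibration-accessors
#' @export
setGeneric("calibSupport", function(x) standardGeneric("calibSupport"))

#' @rdname calibration-accessors
setMethod("epsMCpG", "CalibrationResult", function(x) x@epsMCpG)
#' @rdname calibration-accessors
setMethod("epsCH", "CalibrationResult", function(x) x@epsCH)
#' @rdname calibration-accessors
setMethod("protectionRate", "CalibrationResult", function(x) x@rho)
#' @rdname calibration-accessors
setMethod("calibSupport", "CalibrationResult", function(x) x@support)

#' Ground-truth accessors
#'
#' @param x a [TrueMethylome-class].
#' @param stage stage label.
#' @param allele `"maternal"`, `"paternal"` or `"merged"` (weighted by the
#'   stage's allele weights).
#' @return `trueFractions`: data.frame with columns `u`, `m`, `h` aligned
#'   with the CpG sites; `plantedRegions`: GRanges of planted regions.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("trueFractions", function(x, stage, allele = "merged")
  standardGeneric("trueFractions"))
#' @rdname truth-accessors
#' @export
setGeneric("plantedRegions", function(x) standardGeneric("plantedRegions"))

#' @rdname truth-accessors
setMethod("trueFractions", "TrueMethylome",
  function(x, stage, allele = "merged") {
    si <- match(stage, x@stages)
    if (is.na(si)) stop("unknown stage: ", stage)
    pick <- function(arr) {
      if (allele == "merged") {
        w <- x@alleleWeights[si, ]
        arr[, si, 1L] * w[1L] + arr[, si, 2L] * w[2L]
      } else {
        ai <- match(allele, c("maternal", "paternal"))
        if (is.na(ai)) stop("allele must be maternal/paternal/merged")
        arr[, si, ai]
      }
    }
    data.frame(u = pick(x@u), m = pick(x@m), h = pick(x@h))
  })
#' @rdname truth-accessors
setMethod("plantedRegions", "TrueMethylome", function(x) x@regions)
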