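#' SiteCountTable: per-cytosine converted/unconverted read counts
#'
#' The central container of the package: one sequencing library (or a merge
#' of biological replicates) of one assay, holding per-site counts of reads
#' observed as C (`nUnconverted`) and as T (`nConverted`). Sites live on a
#' [GenomicRanges::GRanges] of width-1 positions (1-based cytosine
#' coordinates) with metadata columns `nUnconverted`, `nConverted`,
#' `context` (`"CpG"` or `"CH"`) and `allele` (`"maternal"`, `"paternal"`
#' or `"unassigned"`).
#'
#' In ACE-seq an unconverted read reports 5hmC; in WGBS it reports
#' 5mC + 5hmC. The methylation level of a site is
#' `nUnconverted / (nUnconverted + nConverted)` and is undefined (NA), not
#' zero, at zero coverage.
#'
#' @slot sites GRanges of width-1 cytosine positions with the metadata
#'   columns described above, sorted by (chromosome, position, strand,
#'   allele).
#' @slot sampleId character(1) sample label.
#' @slot assay character(1), `"ACE"` or `"WGBS"`.
#' @slot stage character(1) developmental stage label (free-form, e.g.
#'   `"oocyte"`, `"zygote"`, `"two_cell"`).
#'
#' @seealso [SiteCountTable()] for construction, [readSiteCounts()],
#'   [siteLevels()], [aggregateReplicates()]
#' @exportClass SiteCountTable
setClass("SiteCountTable",
  slots = c(
    sites = "GRanges",
    sampleId = "character",
    assay = "character",
    stage = "character"
  )
)

.validSiteCountTable <- function(object) {
  msg <- character()
  gr <- object@sites
  need <- c("nUnconverted", "nConverted", "context", "allele")
  missing <- setdiff(need, colnames(mcols(gr)))
  if (length(missing)) {
    return(paste("missing site metadata columns:",
                 paste(missing, collapse = ", ")))
  }
  if (!object@assay %in% c("ACE", "WGBS"))
    msg <- c(msg, "assay must be \"ACE\" or \"WGBS\"")
  if (length(object@sampleId) != 1L || length(object@stage) != 1L ||
      length(object@assay) != 1L)
    msg <- c(msg, "sampleId, assay and stage must each be length 1")
  if (length(gr)) {
    if (any(mcols(gr)$nUnconverted < 0L) || any(mcols(gr)$nConverted < 0L))
      msg <- c(msg, "read counts must be non-negative")
    if (!all(mcols(gr)$context %in% c("CpG", "CH")))
      msg <- c(msg, "context must be \"CpG\" or \"CH\"")
    if (!all(mcols(gr)$allele %in% c("maternal", "paternal", "unassigned")))
      msg <- c(msg, "allele must be maternal/paternal/unassigned")
    if (any(width(gr) != 1L))
      msg <- c(msg, "sites must be width-1 positions")
    if (any(start(gr) < 1L))
      msg <- c(msg, "positions must be >= 1")
    key <- paste(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)), mcols(gr)$allele)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, strand, allele) sites")
    if (is.unsorted(order(.siteOrder(gr))))
      msg <- c(msg, "sites must be sorted by (chrom, pos, strand, allele)")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SiteCountTable", .validSiteCountTable)

# canonical sort order used everywhere: chrom (seqlevel order), pos,
# strand (+,-,*), allele
.siteOrder <- function(gr) {
  order(as.integer(seqnames(gr)), start(gr), as.integer(strand(gr)),
        mcols(gr)$allele, method = "radix")
}

#' Construct a SiteCountTable
#'
#' Builds the container from parallel vectors or a ready-made GRanges.
#' Sites are sorted into the canonical (chromosome, position, strand,
#' allele) order.
#'
#' @param chrom character vector of chromosome names (ignored when `sites`
#'   is given).
#' @param pos integer vector of 1-based cytosine positions.
#' @param nUnconverted,nConverted integer read counts observed as C / as T.
#' @param strand `"+"`, `"-"` or `"*"`; strand-collapsed dyad counts are
#'   conventionally reported on `"+"`.
#' @param context `"CpG"` or `"CH"` per site.
#' @param allele `"maternal"`, `"paternal"` or `"unassigned"` per site.
#' @param sampleId,assay,stage library metadata; `assay` is `"ACE"` or
#'   `"WGBS"`.
#' @param sites optional GRanges with the required metadata columns,
#'   overriding the vector arguments.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A [SiteCountTable-class] object.
#' @examples
#' x <- SiteCountTable(chrom = "chr1", pos = c(100L, 300L),
#'                     nUnconverted = c(3L, 0L), nConverted = c(7L, 10L),
#'                     sampleId = "oo1", assay = "ACE", stage = "oocyte")
#' siteLevels(x)
#' @export
SiteCountTable <- function(chrom = character(), pos = integer(),
                           nUnconverted = integer(), nConverted = integer(),
                           strand = "+", context = "CpG",
                           allele = "unassigned",
                           sampleId = "sample", assay = c("ACE", "WGBS"),
                           stage = "unknown", sites = NULL,
                           seqlengths = NULL) {
  assay <- match.arg(assay)
  if (is.null(sites)) {
    n <- length(pos)
    sites <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                     strand = rep_len(strand, n))
    mcols(sites)$nUnconverted <- as.integer(rep_len(nUnconverted, n))
    mcols(sites)$nConverted <- as.integer(rep_len(nConverted, n))
    mcols(sites)$context <- rep_len(as.character(context), n)
    mcols(sites)$allele <- rep_len(as.character(allele), n)
  }
  if (!is.null(seqlengths))
    seqlengths(sites) <- seqlengths[seqlevels(sites)]
  sites <- sites[.siteOrder(sites)]
  new("SiteCountTable", sites = sites, sampleId = as.character(sampleId),
      assay = assay, stage = as.character(stage))
}

setMethod("show", "SiteCountTable", function(object) {
  gr <- object@sites
  ncpg <- sum(mcols(gr)$context == "CpG")
  cat("SiteCountTable \"", object@sampleId, "\" (", object@assay,
      ", stage ", object@stage, ")\n", sep = "")
  cat("  ", length(gr), " sites (", ncpg, " CpG, ", length(gr) - ncpg,
      " CH) on ", length(seqlevelsInUse(gr)), " chromosome(s)\n", sep = "")
  cov <- mcols(gr)$nUnconverted + mcols(gr)$nConverted
  if (length(cov))
    cat("  mean coverage ", round(mean(cov), 2), "; zero-coverage sites ",
        sum(cov == 0L), "\n", sep = "")
})

#' CalibrationResult: spike-in derived assay error rates
#'
#' Error rates estimated from the two ACE-seq spike-in controls: in
#' vitro CpG-methylated lambda DNA (CpG sites fully 5mC, CH sites
#' unmodified) gives the deamination-escape (non-conversion) rates, and a
#' fully hydroxymethylated control gives the glucosylation protection rate
#' of true 5hmC.
#'
#' @slot epsMCpG numeric(1) non-conversion rate of 5mC in the CpG context
#'   (the deamination error rate used by the binomial site caller); NA when
#'   not estimated.
#' @slot epsCH numeric(1) non-conversion rate of unmodified cytosines in
#'   the CH context; NA when not estimated.
#' @slot rho numeric(1) protection rate of true 5hmC; NA when not
#'   estimated.
#' @slot support named integer of read totals behind each estimate.
#' @seealso [calibrateLambda()], [calibrateProtection()]
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  slots = c(epsMCpG = "numeric", epsCH = "numeric", rho = "numeric",
            support = "integer")
)

setValidity("CalibrationResult", function(object) {
  rates <- c(object@epsMCpG, object@epsCH, object@rho)
  ok <- is.na(rates) | (rates >= 0 & rates <= 1)
  if (!all(ok)) return("rates must be in [0, 1] or NA")
  if (any(!is.na(rates) & object@support[seq_along(rates)] <= 0L,
          na.rm = TRUE))
    return("a reported rate requires positive read support")
  TRUE
})

#' @rdname CalibrationResult-class
#' @param epsMCpG,epsCH,rho rates in \[0, 1\] (or NA).
#' @param support named integer read totals (`mCpG`, `CH`, `hmC`).
#' @return A `CalibrationResult`.
#' @export
CalibrationResult <- function(epsMCpG = NA_real_, epsCH = NA_real_,
                              rho = NA_real_,
                              support = c(mCpG = 0L, CH = 0L, hmC = 0L)) {
  new("CalibrationResult", epsMCpG = as.numeric(epsMCpG),
      epsCH = as.numeric(epsCH), rho = as.numeric(rho),
      support = setNames(as.integer(support), names(support)))
}

setMethod("show", "CalibrationResult", function(object) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.5f", x))
  cat("CalibrationResult\n")
  cat("  eps(5mCpG non-conversion):", fmt(object@epsMCpG),
      "(", object@support[["mCpG"]], "reads )\n")
  cat("  eps(CH non-conversion):   ", fmt(object@epsCH),
      "(", object@support[["CH"]], "reads )\n")
  cat("  rho(5hmC protection):     ", fmt(object@rho),
      "(", object@support[["hmC"]], "reads )\n")
})

#' TrueMethylome: ground truth of a simulated dataset
#'
#' Per-site true fractions of unmodified (u), methylated (m) and
#' hydroxymethylated (h) cytosines for every CpG site, stage and parental
#' allele of a simulated dataset, together with the planted regions and the
#' true CH 5hmC levels. `u + m + h = 1` at every site.
#'
#' @slot sites GRanges of CpG dyad positions (width 1, + strand).
#' @slot chSites GRanges of CH positions with metadata column `h`.
#' @slot stages character vector, the declared stage ordering.
#' @slot alleleWeights numeric matrix (stage x 2) of maternal/paternal
#'   genome weights used when emitting merged counts.
#' @slot u,m,h numeric arrays of dim (site, stage, allele) with
#'   allele in (maternal, paternal).
#' @slot regions GRanges of planted regions with metadata columns `type`
#'   and `level`.
#' @seealso [simulateDataset()], [plantRegions()], [trueFractions()]
#' @exportClass TrueMethylome
setClass("TrueMethylome",
  slots = c(sites = "GRanges", chSites = "GRanges", stages = "character",
            alleleWeights = "matrix", u = "array", m = "array", h = "array",
            regions = "GRanges")
)

setValidity("TrueMethylome", function(object) {
  d <- c(length(object@sites), length(object@stages), 2L)
  for (nm in c("u", "m", "h"))
    if (!identical(dim(slot(object, nm)), d))
      return(sprintf("array %s must have dim (site, stage, allele)", nm))
  tot <- object@u + object@m + object@h
  if (length(tot) && max(abs(tot - 1)) > 1e-8)
    return("u + m + h must equal 1 at every site")
  if (length(object@u) && (min(object@u, object@m, object@h) < -1e-12))
    return("fractions must be non-negative")
  TRUE
})

setMethod("show", "TrueMethylome", function(object) {
  cat("TrueMethylome: ", length(object@sites), " CpG sites, ",
      length(object@chSites), " CH sites, ", length(object@stages),
      " stages, ", length(object@regions), " planted region(s)\n", sep = "")
})
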