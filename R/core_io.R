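#' Read a per-cytosine count table
#'
#' Parses MethylDackel-style tab-separated extraction output. The dialect
#' is auto-detected from the column count:
#' \itemize{
#'   \item 6 columns: chrom, start (0-based), end, level, nUnconverted,
#'     nConverted (the MethylDackel bedGraph layout);
#'   \item 7 columns: + strand;
#'   \item 8 columns: + context (`CpG`/`CH`);
#'   \item 9 columns: + allele (`maternal`/`paternal`/`unassigned`).
#' }
#' The level column is ignored and recomputed from the counts; `.` or an
#' empty field is accepted there. Leading `track` or `#` lines and a
#' `chrom`-led header line are skipped. Rows with zero total coverage are
#' retained (their level is undefined). Unsorted input is sorted with a
#' warning; malformed rows and negative counts are errors naming the line.
#'
#' @param path file to read.
#' @param assay `"ACE"` or `"WGBS"`.
#' @param sampleId,stage labels stored on the returned table.
#' @param collapse collapse CpG dyads onto the + strand position (see
#'   [collapseStrands()]); the default follows the convention of counting
#'   CpG dyads rather than strands.
#' @return A [SiteCountTable-class].
#' @seealso [writeSiteCounts()], [writeBedGraph()]
#' @export
readSiteCounts <- function(path, assay = c("ACE", "WGBS"),
                           sampleId = sub("\\.[^.]*$", "", basename(path)),
                           stage = "unknown", collapse = TRUE) {
  assay <- match.arg(assay)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  # a header line naming the columns
  keep[grepl("^chrom\\b", lines, ignore.case = TRUE)] <- FALSE
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (!length(lines)) {
    return(SiteCountTable(sampleId = sampleId, assay = assay, stage = stage))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% 6:9) || length(unique(nf)) != 1L) {
    bad <- lineNo[which(!nf %in% 6:9 | nf != nf[1L])[1L]]
    stop("malformed row at line ", bad, ": expected 6-9 tab-separated ",
         "columns, consistently")
  }
  ncol <- nf[1L]
  col <- function(i) vapply(fields, `[[`, character(1), i)
  suppress <- function(x) suppressWarnings(as.integer(x))
  chrom <- col(1L)
  start0 <- suppress(col(2L))
  nU <- suppress(col(5L))
  nC <- suppress(col(6L))
  bad <- which(is.na(start0) | is.na(nU) | is.na(nC))
  if (length(bad))
    stop("malformed row at line ", lineNo[bad[1L]],
         ": non-integer coordinate or count")
  if (any(nU < 0L | nC < 0L)) {
    bad <- which(nU < 0L | nC < 0L)[1L]
    stop("negative read count at line ", lineNo[bad])
  }
  strand <- if (ncol >= 7L) col(7L) else "+"
  context <- if (ncol >= 8L) col(8L) else "CpG"
  allele <- if (ncol >= 9L) col(9L) else "unassigned"
  x <- SiteCountTable(chrom = chrom, pos = start0 + 1L, nUnconverted = nU,
                      nConverted = nC, strand = strand, context = context,
                      allele = allele, sampleId = sampleId, assay = assay,
                      stage = stage)
  # SiteCountTable() always sorts; warn if the file itself was not
  ord <- order(match(chrom, unique(chrom)), start0)
  if (is.unsorted(ord)) warning("input not sorted by (chrom, pos); sorted")
  if (collapse) x <- collapseStrands(x)
  x
}

#' Write a per-cytosine count table
#'
#' Writes the 9-column dialect read back by [readSiteCounts()]: chrom,
#' 0-based start, end, level (6 decimals, `.` at zero coverage),
#' nUnconverted, nConverted, strand, context, allele. `readSiteCounts()`
#' then `writeSiteCounts()` round-trips counts bit-exactly.
#'
#' @param x a [SiteCountTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSiteCounts <- function(x, path) {
  gr <- siteRanges(x)
  lv <- siteLevels(x)
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = start(gr),
    level = fifelse(is.na(lv), ".", sprintf("%.6f", lv)),
    nUnconverted = mcols(gr)$nUnconverted,
    nConverted = mcols(gr)$nConverted,
    strand = as.character(strand(gr)),
    context = mcols(gr)$context,
    allele = mcols(gr)$allele
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write methylation levels as 4-column bedGraph
#'
#' chrom, 0-based start, end, level to 6 decimal places. Zero-coverage
#' sites (undefined level) are omitted rather than written as 0.
#'
#' @param x a [SiteCountTable-class].
#' @param path output file.
#' @param context restrict to `"CpG"` (default), `"CH"`, or `NULL` for all.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(x, path, context = "CpG") {
  gr <- siteRanges(x)
  lv <- siteLevels(x)
  keep <- !is.na(lv)
  if (!is.null(context)) keep <- keep & mcols(gr)$context %in% context
  gr <- gr[keep]
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = start(gr),
    level = sprintf("%.6f", lv[keep])
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph of levels
#'
#' @param path bedGraph file (chrom, 0-based start, end, value).
#' @return GRanges of width-1 positions (1-based) with metadata column
#'   `level`.
#' @export
readBedGraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(GRanges(level = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L))
    stop("expected 4 tab-separated columns in bedGraph")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- as.integer(vapply(fields, `[[`, character(1), 2L))
  level <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  gr <- GRanges(chrom, IRanges(start0 + 1L, width = 1L), level = level)
  sort(gr)
}

#' Collapse CpG dyads onto the plus-strand position
#'
#' The two strands of a genomic CpG form a palindromic dyad; the minus
#' strand cytosine sits one base downstream of the plus strand one. This
#' sums minus-strand CpG counts onto the corresponding + position
#' (pos - 1) so each dyad is a single record, the unit in which CpG sites
#' are counted. CH sites are left untouched.
#'
#' @param x a [SiteCountTable-class].
#' @return A [SiteCountTable-class] with merged dyad counts.
#' @export
collapseStrands <- function(x) {
  gr <- siteRanges(x)
  isMinusCpG <- as.character(strand(gr)) == "-" & mcols(gr)$context == "CpG"
  if (!any(isMinusCpG)) return(x)
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    pos = ifelse(isMinusCpG, start(gr) - 1L, start(gr)),
    strand1 = ifelse(mcols(gr)$context == "CpG", "+",
                     as.character(strand(gr))),
    context = mcols(gr)$context,
    allele = mcols(gr)$allele,
    nUnc = mcols(gr)$nUnconverted,
    nConv = mcols(gr)$nConverted
  )
  agg <- dt[, .(nUnc = sum(nUnc), nConv = sum(nConv)),
            by = .(chrom, pos, strand1, context, allele)]
  SiteCountTable(chrom = agg$chrom, pos = agg$pos,
                 nUnconverted = agg$nUnc, nConverted = agg$nConv,
                 strand = agg$strand1, context = agg$context,
                 allele = agg$allele, sampleId = sampleId(x),
                 assay = assayType(x), stage = stageLabel(x))
}

#' Merge biological replicates by summing per-site counts
#'
#' A site is present in the merge when present in any input; counts are
#' summed over the tables carrying it. All tables must share assay and
#' stage. The operation is commutative and associative.
#'
#' @param tables list of [SiteCountTable-class] objects.
#' @param sampleId label of the merged table.
#' @return A [SiteCountTable-class].
#' @export
aggregateReplicates <- function(tables,
                                sampleId = paste0(tables[[1L]]@stage,
                                                  ".merged")) {
  stopifnot(length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1L]])
  assays <- vapply(tables, assayType, character(1))
  stages <- vapply(tables, stageLabel, character(1))
  if (length(unique(assays)) != 1L)
    stop("cannot merge tables from different assays")
  if (length(unique(stages)) != 1L)
    stop("cannot merge tables from different stages")
  dts <- lapply(tables, function(t) {
    gr <- siteRanges(t)
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               strand1 = as.character(strand(gr)),
               context = mcols(gr)$context, allele = mcols(gr)$allele,
               nUnc = mcols(gr)$nUnconverted, nConv = mcols(gr)$nConverted)
  })
  agg <- rbindlist(dts)[, .(nUnc = sum(nUnc), nConv = sum(nConv)),
                        by = .(chrom, pos, strand1, context, allele)]
  SiteCountTable(chrom = agg$chrom, pos = agg$pos,
                 nUnconverted = agg$nUnc, nConverted = agg$nConv,
                 strand = agg$strand1, context = agg$context,
                 allele = agg$allele, sampleId = sampleId,
                 assay = assays[1L], stage = stages[1L])
}

#' Pooled (read-weighted) global methylation level
#'
#' Total unconverted reads over total reads, the global level statistic
#' used for stage-wide 5hmCpG/5hmCH summaries.
#'
#' @param x a [SiteCountTable-class].
#' @param context `"CpG"` or `"CH"`.
#' @param allele optional restriction to one allele label.
#' @return numeric(1); NA when no reads.
#' @export
globalLevel <- function(x, context = "CpG", allele = NULL) {
  gr <- siteRanges(x)
  keep <- mcols(gr)$context %in% context
  if (!is.null(allele)) keep <- keep & mcols(gr)$allele %in% allele
  nU <- sum(mcols(gr)$nUnconverted[keep])
  tot <- nU + sum(mcols(gr)$nConverted[keep])
  if (tot == 0L) NA_real_ else nU / tot
}
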