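# Planted-region recovery experiments: simulate two conditions on a
# synthetic genome, call hmDMRs between them, and score the calls against
# the planted truth.

#' Reciprocal-overlap matching between two interval sets
#'
#' Two intervals match when their overlap covers at least `fraction` of
#' each of them.
#'
#' @param query,subject GRanges.
#' @param fraction minimum reciprocal overlap (default 0.5).
#' @return list with logical vectors `queryMatched` and `subjectMatched`.
#' @export
reciprocalOverlap <- function(query, subject, fraction = 0.5) {
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (!length(hits)) {
    return(list(queryMatched = logical(length(query)),
                subjectMatched = logical(length(subject))))
  }
  q <- query[queryHits(hits)]
  s <- subject[subjectHits(hits)]
  ovWidth <- width(pintersect(granges(q), granges(s)))
  ok <- ovWidth >= fraction * width(q) & ovWidth >= fraction * width(s)
  list(
    queryMatched = seq_along(query) %in% queryHits(hits)[ok],
    subjectMatched = seq_along(subject) %in% subjectHits(hits)[ok]
  )
}

# two-condition config for hmDMR benchmarking: a flat 5hmC background
# ("ref") versus the same background with planted hyper regions ("alt"),
# single replicate, ACE only
.twoGroupConfig <- function(chromLengths, backgroundH, level, nRegions,
                            regionLength, depthMean, em,
                            depthDispersion = 0) {
  simConfig(
    chromLengths = chromLengths, cpgDensity = 0.01, chDensity = 0,
    stages = c("ref", "alt"), replicates = c(1L, 1L),
    hProfile = list(maternal = c(ref = backgroundH, alt = backgroundH),
                    paternal = c(ref = backgroundH, alt = backgroundH)),
    mProfile = list(maternal = c(ref = 0.5, alt = 0.5),
                    paternal = c(ref = 0.5, alt = 0.5)),
    depthMean = depthMean, depthDispersion = depthDispersion,
    errorModel = em,
    regions = if (nRegions > 0L)
      list(n = nRegions, length = regionLength, level = level,
           type = "hyper_hmDMR", stages = "alt", alleles = NULL,
           minGap = 20000L)
    else NULL,
    assays = "ACE"
  )
}

#' Benchmark hmDMR recovery on planted regions
#'
#' For each seed, simulates a two-condition ACE-seq experiment (a flat
#' 5hmC background versus the same background with planted hyper
#' regions), calls hmDMRs, and scores recall and precision at 50%
#' reciprocal overlap against the planted truth. With `nRegions = 0` the
#' run is a null experiment and the score is the fraction of genome bases
#' inside called regions.
#'
#' @param seeds integer vector of simulation seeds.
#' @param chromLengths genome (default one 10-Mb chromosome).
#' @param nRegions planted hyper regions per genome (default 50; 0 for a
#'   null run).
#' @param regionLength region length in bp (default 7600, the reported
#'   median hmDMR length).
#' @param deltaH planted 5hmC effect size; regions carry
#'   `backgroundH + deltaH` (default 0.137, the reported median hmDMR
#'   level).
#' @param backgroundH background 5hmC level (default 0.01).
#' @param depthMean sequencing depth (default 30).
#' @param depthDispersion coverage dispersion; 0 (default) draws constant
#'   depth, matching the stated benchmark condition.
#' @param errorModel see [errorModel()].
#' @return data.frame with one row per seed: `recall`, `precision`,
#'   `nCalled`, `nPlanted`, `calledBaseFraction`.
#' @export
benchmarkHmDmrRecovery <- function(seeds,
                                   chromLengths = c(chrSim1 = 1e7),
                                   nRegions = 50L, regionLength = 7600L,
                                   deltaH = 0.137, backgroundH = 0.01,
                                   depthMean = 30, depthDispersion = 0,
                                   errorModel = hydroxymap::errorModel()) {
  genomeLen <- sum(as.numeric(chromLengths))
  cfg <- .twoGroupConfig(chromLengths, backgroundH, backgroundH + deltaH,
                         nRegions, regionLength, depthMean, errorModel,
                         depthDispersion = depthDispersion)
  rows <- lapply(seeds, function(seed) {
    sim <- simulateDataset(cfg, seed = seed)
    dmrs <- callDMRs(sim$tables[["alt.ACE.rep1"]],
                     sim$tables[["ref.ACE.rep1"]], mark = "5hmC")
    hyper <- dmrs[mcols(dmrs)$label == "hyper"]
    planted <- plantedRegions(sim$truth)
    calledBases <- sum(as.numeric(width(reduce(granges(dmrs)))))
    if (length(planted)) {
      m <- reciprocalOverlap(hyper, planted, fraction = 0.5)
      recall <- mean(m$subjectMatched)
      precision <- if (length(hyper)) mean(m$queryMatched) else NA_real_
    } else {
      recall <- NA_real_
      precision <- NA_real_
    }
    data.frame(seed = seed, recall = recall, precision = precision,
               nCalled = length(hyper), nPlanted = length(planted),
               calledBaseFraction = calledBases / genomeLen)
  })
  do.call(rbind, rows)
}
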