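# Synthetic paired ACE/WGBS count data with known ground truth.
#
# Per CpG site, stage and parental allele the truth is a composition
# (u, m, h) of unmodified, 5mC and 5hmC fractions. Observed counts are
# binomial draws at negative-binomial coverage with success probability
#   ACE:  h * rho + m * epsMCpG + u * epsU   (glucosylation protects 5hmC,
#                                             errors read 5mC/C as C)
#   WGBS: m + h + u * epsBs                  (both modifications resist
#                                             bisulfite conversion)
# Spike-ins: CpG-methylated lambda DNA (m = 1 at CpG, u = 1 at CH) and a
# fully hydroxymethylated control (h = 1).

#' Assay error model of the generator
#'
#' @param epsMCpG probability a 5mC escapes deamination in ACE-seq and
#'   reads as C (the dominant false-5hmC error; default 0.005).
#' @param epsU probability an unmodified C reads as C in ACE-seq
#'   (default 0.002).
#' @param rho glucosylation protection rate of true 5hmC (default 0.95).
#' @param epsBs bisulfite non-conversion of unmodified C in WGBS
#'   (default 0.005).
#' @return named list of rates.
#' @export
errorModel <- function(epsMCpG = 0.005, epsU = 0.002, rho = 0.95,
                       epsBs = 0.005) {
  rates <- c(epsMCpG = epsMCpG, epsU = epsU, rho = rho, epsBs = epsBs)
  if (any(rates < 0 | rates > 1)) stop("error rates must be in [0, 1]")
  as.list(rates)
}

.defaultStages <- c("sperm", "oocyte", "zygote", "two_cell", "four_cell",
                    "eight_cell", "blastocyst")

# Global 5hmCpG targets per stage and allele. Maternal oocyte/zygote and
# paternal zygote/two-cell values are the printed globals (5.75/5.17 and
# 5.71/6.09 per cent); the decline to blastocyst interpolates the
# reported trend. Gamete values on the absent allele are placeholders
# (weighted 0 at those stages).
.defaultHProfile <- list(
  maternal = c(sperm = 0.005, oocyte = 0.0575, zygote = 0.0517,
               two_cell = 0.052, four_cell = 0.040, eight_cell = 0.025,
               blastocyst = 0.008),
  paternal = c(sperm = 0.005, oocyte = 0.0575, zygote = 0.0571,
               two_cell = 0.0609, four_cell = 0.045, eight_cell = 0.028,
               blastocyst = 0.008)
)

# Global 5mC targets: highly methylated sperm, intermediate oocyte,
# paternal demethylation after fertilisation, gradual maternal decline.
.defaultMProfile <- list(
  maternal = c(sperm = 0.75, oocyte = 0.52, zygote = 0.50,
               two_cell = 0.45, four_cell = 0.40, eight_cell = 0.35,
               blastocyst = 0.30),
  paternal = c(sperm = 0.75, oocyte = 0.52, zygote = 0.35,
               two_cell = 0.33, four_cell = 0.32, eight_cell = 0.31,
               blastocyst = 0.30)
)

#' Generator configuration
#'
#' Defaults emulate the study design at desk scale: a 10-Mb two-chromosome
#' genome at human-like CpG density, the full gamete-to-blastocyst stage
#' series with the study's replicate counts, stage 5hmC profiles anchored
#' to the printed global levels, CH 5hmC in the printed 0.12-0.20% range,
#' negative-binomial depth (mean 30, dispersion 0.2), and 50 planted
#' hyper-hmDMRs of 7,600 bp at a 13.69% 5hmC level (the reported median
#' hmDMR geometry).
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param cpgDensity expected CpG dyads per bp (default 0.01).
#' @param chDensity expected simulated CH sites per bp (default 0.002; CH
#'   sites are only summarised globally downstream).
#' @param stages ordered stage labels.
#' @param replicates integer biological replicates per stage (recycled).
#' @param hProfile,mProfile lists with `maternal`/`paternal` named
#'   vectors of global 5hmC / 5mC targets per stage.
#' @param alleleWeights optional stage x 2 matrix of maternal/paternal
#'   genome weights; by default sperm is fully paternal, oocyte fully
#'   maternal, all other stages 50/50.
#' @param chLevelRange range of true CH 5hmC levels (default
#'   0.0012-0.0020).
#' @param depthMean,depthDispersion negative-binomial coverage model per
#'   site (mean 30, dispersion 0.2; use mean 5 for low-input embryos).
#' @param errorModel see [errorModel()].
#' @param regions planted-region settings: list with `n`, `length`, `level`,
#'   `type`, `stages` (stages carrying the region; default all
#'   post-gamete maternal-carrying stages plus oocyte), `alleles`,
#'   `minGap`; or NULL for none.
#' @param alleleFraction fraction of reads assignable to a parental
#'   allele when `alleleTagged` (default 0.3).
#' @param alleleTagged emit maternal/paternal/unassigned rows instead of
#'   merged counts (default FALSE).
#' @param assays which assays to emit.
#' @param spike spike-in sizes: `lambdaCpG`, `lambdaCH`, `hmcSites` site
#'   counts and `depth`.
#' @param betaPrecision concentration of the per-site Beta variation
#'   around the stage 5mC target (default 10).
#' @return config list for [simulateDataset()].
#' @export
simConfig <- function(chromLengths = c(chrSim1 = 6e6, chrSim2 = 4e6),
                      cpgDensity = 0.01, chDensity = 0.002,
                      stages = .defaultStages,
                      replicates = c(2L, 4L, 3L, 3L, 4L, 5L, 3L),
                      hProfile = .defaultHProfile,
                      mProfile = .defaultMProfile,
                      alleleWeights = NULL,
                      chLevelRange = c(0.0012, 0.0020),
                      depthMean = 30, depthDispersion = 0.2,
                      errorModel = hydroxymap::errorModel(),
                      regions = list(n = 50L, length = 7600L,
                                     level = 0.1369, type = "hyper_hmDMR",
                                     stages = NULL, alleles = NULL,
                                     minGap = 20000L),
                      alleleFraction = 0.3, alleleTagged = FALSE,
                      assays = c("ACE", "WGBS"), spike = list(),
                      betaPrecision = 10) {
  nStage <- length(stages)
  replicates <- rep_len(as.integer(replicates), nStage)
  names(replicates) <- stages
  fillProfile <- function(p) {
    lapply(p[c("maternal", "paternal")], function(v) {
      if (is.null(names(v))) v <- setNames(rep_len(v, nStage), stages)
      miss <- setdiff(stages, names(v))
      if (length(miss)) stop("profile missing stages: ",
                             paste(miss, collapse = ", "))
      v[stages]
    })
  }
  if (is.null(alleleWeights)) {
    alleleWeights <- matrix(0.5, nStage, 2,
                            dimnames = list(stages,
                                            c("maternal", "paternal")))
    alleleWeights[stages == "sperm", ] <- c(0, 1)
    alleleWeights[stages == "oocyte", ] <- c(1, 0)
  }
  spikeDef <- list(lambdaCpG = 500L, lambdaCH = 2000L, hmcSites = 500L,
                   depth = 50)
  spikeDef[names(spike)] <- spike
  list(chromLengths = chromLengths, cpgDensity = cpgDensity,
       chDensity = chDensity, stages = stages, replicates = replicates,
       hProfile = fillProfile(hProfile), mProfile = fillProfile(mProfile),
       alleleWeights = alleleWeights, chLevelRange = chLevelRange,
       depthMean = depthMean, depthDispersion = depthDispersion,
       errorModel = errorModel, regions = regions,
       alleleFraction = alleleFraction, alleleTagged = alleleTagged,
       assays = match.arg(assays, c("ACE", "WGBS"), several.ok = TRUE),
       spike = spikeDef, betaPrecision = betaPrecision)
}

# scatter n sites uniformly over the genome; returns sorted GRanges
.placeSites <- function(chromLengths, density) {
  si <- Seqinfo(names(chromLengths), seqlengths = unname(chromLengths))
  grl <- lapply(names(chromLengths), function(ch) {
    n <- round(chromLengths[[ch]] * density)
    if (n == 0L) return(GRanges(seqinfo = si))
    pos <- sort(sample.int(chromLengths[[ch]] - 1L, n))
    GRanges(rep(ch, n), IRanges(pos, width = 1L), strand = "+",
            seqinfo = si)
  })
  do.call(c, grl)
}

# per-site 5mC heterogeneity: Beta around the stage target
.siteM <- function(n, target, precision) {
  target <- min(max(target, 1e-3), 0.98)
  rbeta(n, target * precision, (1 - target) * precision)
}

.makeTruth <- function(config) {
  sites <- .placeSites(config$chromLengths, config$cpgDensity)
  chSites <- .placeSites(config$chromLengths, config$chDensity)
  # avoid colliding with a CpG position
  clash <- countOverlaps(chSites, sites) > 0L
  chSites <- chSites[!clash]
  mcols(chSites)$h <- runif(length(chSites), config$chLevelRange[1L],
                            config$chLevelRange[2L])
  nS <- length(sites)
  nStage <- length(config$stages)
  dims <- c(nS, nStage, 2L)
  dn <- list(NULL, config$stages, c("maternal", "paternal"))
  u <- m <- h <- array(0, dims, dimnames = dn)
  for (ai in 1:2) {
    allele <- c("maternal", "paternal")[ai]
    for (si in seq_len(nStage)) {
      st <- config$stages[si]
      mSite <- .siteM(nS, config$mProfile[[allele]][[st]],
                      config$betaPrecision)
      hSite <- rep(config$hProfile[[allele]][[st]], nS)
      mSite <- pmin(mSite, 1 - hSite)
      m[, si, ai] <- mSite
      h[, si, ai] <- hSite
      u[, si, ai] <- 1 - mSite - hSite
    }
  }
  new("TrueMethylome", sites = sites, chSites = chSites,
      stages = config$stages, alleleWeights = config$alleleWeights,
      u = u, m = m, h = h,
      regions = GRanges(type = character(), level = numeric()))
}

# deterministic region placement: slots of (length + 2*minGap) tile each
# chromosome; sampled slots get a region at a random offset within the
# first minGap bases, guaranteeing pairwise gaps >= minGap
.placeRegions <- function(chromLengths, n, len, minGap) {
  slot <- len + 2L * minGap
  slots <- lapply(names(chromLengths), function(ch) {
    k <- chromLengths[[ch]] %/% slot
    if (k < 1L) return(NULL)
    data.frame(chrom = ch, slotStart = (seq_len(k) - 1L) * slot)
  })
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n)
    stop("genome too small for ", n, " regions of length ", len)
  pick <- slots[sort(sample.int(nrow(slots), n)), ]
  off <- sample.int(minGap, n, replace = TRUE)
  GRanges(pick$chrom, IRanges(pick$slotStart + off, width = len))
}

#' Plant regions of altered modification into a TrueMethylome
#'
#' Inside each planted region the targeted fraction is set to `level` on
#' the given stages and alleles, with the unmodified fraction absorbing
#' the change (the 5mC fraction is reduced only if needed to keep the
#' composition valid). Supported types: `hyper_hmDMR` (h raised),
#' `hyper_DMR` (m raised), `hypo_DMR` (m lowered to `level`). Regions
#' must not overlap each other or previously planted regions.
#'
#' @param truth a [TrueMethylome-class].
#' @param regions GRanges of regions to plant; optional metadata columns
#'   `type` and `level` override the arguments per region.
#' @param type,level defaults for regions without metadata
#'   (`"hyper_hmDMR"` at the reported median hmDMR level 0.1369).
#' @param stages stages to modify (default: all).
#' @param alleles alleles to modify (default: both).
#' @return The modified [TrueMethylome-class]; planted regions are
#'   appended to `plantedRegions(truth)`.
#' @export
plantRegions <- function(truth, regions, type = "hyper_hmDMR",
                         level = 0.1369, stages = NULL, alleles = NULL) {
  if (!length(regions)) return(truth)
  if (is.null(stages)) stages <- truth@stages
  if (is.null(alleles)) alleles <- c("maternal", "paternal")
  all <- c(granges(truth@regions), granges(regions))
  if (sum(width(reduce(all))) != sum(width(all)))
    stop("planted regions must not overlap")
  typeVec <- mcols(regions)$type
  if (is.null(typeVec)) typeVec <- rep(type, length(regions))
  levelVec <- mcols(regions)$level
  if (is.null(levelVec)) levelVec <- rep(level, length(regions))
  si <- match(stages, truth@stages)
  if (anyNA(si)) stop("unknown stage in 'stages'")
  ai <- match(alleles, c("maternal", "paternal"))
  ov <- findOverlaps(truth@sites, regions, ignore.strand = TRUE)
  for (r in unique(subjectHits(ov))) {
    idx <- queryHits(ov)[subjectHits(ov) == r]
    lv <- levelVec[r]
    for (s in si) for (a in ai) {
      m0 <- truth@m[idx, s, a]
      h0 <- truth@h[idx, s, a]
      switch(typeVec[r],
        hyper_hmDMR = {
          h1 <- lv
          m1 <- pmin(m0, 1 - h1)
        },
        hyper_DMR = {
          m1 <- lv
          h1 <- pmin(h0, 1 - m1)
        },
        hypo_DMR = {
          m1 <- lv
          h1 <- h0
        },
        stop("unsupported region type: ", typeVec[r])
      )
      truth@m[idx, s, a] <- m1
      truth@h[idx, s, a] <- h1
      truth@u[idx, s, a] <- 1 - m1 - h1
    }
  }
  newRegions <- granges(regions)
  mcols(newRegions)$type <- typeVec
  mcols(newRegions)$level <- levelVec
  truth@regions <- c(truth@regions, newRegions)
  validObject(truth)
  truth
}

# per-site binomial success probability of reading C, by assay
.successProb <- function(u, m, h, assay, em) {
  if (assay == "ACE") h * em$rho + m * em$epsMCpG + u * em$epsU
  else m + h + u * em$epsBs
}

# coverage draw: negative binomial, or constant at dispersion 0
.drawDepth <- function(n, mean, dispersion) {
  if (dispersion == 0) rep(as.integer(round(mean)), n)
  else rnbinom(n, mu = mean, size = 1 / dispersion)
}

# one emitted table: NB coverage then binomial unconverted counts
.emitTable <- function(truth, config, stage, assay, rep) {
  em <- config$errorModel
  si <- match(stage, truth@stages)
  w <- truth@alleleWeights[si, ]
  pAll <- vapply(1:2, function(ai) {
    .successProb(truth@u[, si, ai], truth@m[, si, ai], truth@h[, si, ai],
                 assay, em)
  }, numeric(length(truth@sites)))
  if (any(pAll < 0 | pAll > 1))
    stop("composed success probability outside [0, 1]; check error model")
  pMerged <- drop(pAll %*% w)
  hCH <- mcols(truth@chSites)$h
  pCH <- .successProb(1 - hCH, 0, hCH, assay, em)
  drawFor <- function(gr, p, context) {
    n <- length(gr)
    N <- .drawDepth(n, config$depthMean, config$depthDispersion)
    C <- rbinom(n, N, p)
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               nUnc = C, nConv = N - C, context = context,
               allele = "unassigned")
  }
  if (config$alleleTagged) {
    gr <- truth@sites
    n <- length(gr)
    N <- .drawDepth(n, config$depthMean, config$depthDispersion)
    fracM <- w[1L] * config$alleleFraction
    fracP <- w[2L] * config$alleleFraction
    nM <- rbinom(n, N, fracM)
    nP <- rbinom(n, N - nM, ifelse(fracM < 1, fracP / (1 - fracM), 0))
    nUn <- N - nM - nP
    cM <- rbinom(n, nM, pAll[, 1L])
    cP <- rbinom(n, nP, pAll[, 2L])
    cU <- rbinom(n, nUn, pMerged)
    cpg <- rbindlist(list(
      data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
                 nUnc = cM, nConv = nM - cM, context = "CpG",
                 allele = "maternal"),
      data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
                 nUnc = cP, nConv = nP - cP, context = "CpG",
                 allele = "paternal"),
      data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
                 nUnc = cU, nConv = nUn - cU, context = "CpG",
                 allele = "unassigned")
    ))
  } else {
    cpg <- drawFor(truth@sites, pMerged, "CpG")
  }
  dt <- rbindlist(list(cpg, drawFor(truth@chSites, pCH, "CH")))
  SiteCountTable(chrom = dt$chrom, pos = dt$pos, nUnconverted = dt$nUnc,
                 nConverted = dt$nConv, strand = "+", context = dt$context,
                 allele = dt$allele,
                 sampleId = paste(stage, assay, paste0("rep", rep),
                                  sep = "."),
                 assay = assay, stage = stage,
                 seqlengths = config$chromLengths)
}

.emitSpikes <- function(config) {
  em <- config$errorModel
  sp <- config$spike
  draw <- function(n, p, context, chrom, offset = 0L) {
    N <- .drawDepth(n, sp$depth, config$depthDispersion)
    C <- rbinom(n, N, p)
    SiteCountTable(chrom = chrom, pos = offset + seq_len(n) * 10L,
                   nUnconverted = C, nConverted = N - C, strand = "+",
                   context = context, sampleId = chrom, assay = "ACE",
                   stage = "spike")
  }
  lambdaCpG <- draw(sp$lambdaCpG, em$epsMCpG, "CpG", "lambda")
  lambdaCH <- draw(sp$lambdaCH, em$epsU, "CH", "lambda",
                   offset = sp$lambdaCpG * 10L)
  # disjoint positions, so merging the two context tables is a plain union
  lambda <- aggregateReplicates(list(lambdaCpG, lambdaCH),
                                sampleId = "lambda")
  hmc <- draw(sp$hmcSites, em$rho, "CpG", "hmC_control")
  list(lambda = lambda, hmcControl = hmc)
}

#' Simulate a paired ACE/WGBS dataset with known ground truth
#'
#' Builds a [TrueMethylome-class] from the stage profiles, plants the
#' configured regions, then draws per-site read counts for every stage,
#' assay and replicate plus the two spike-in controls. Identical seeds
#' give bit-identical output.
#'
#' @param config from [simConfig()].
#' @param seed integer RNG seed.
#' @return list with elements `tables` (named
#'   `stage.assay.repN` [SiteCountTable-class] objects), `truth`
#'   ([TrueMethylome-class]), `spikes` (`lambda`, `hmcControl`), `config`
#'   and `seed`.
#' @export
simulateDataset <- function(config = simConfig(), seed = 1L) {
  rates <- unlist(config$errorModel)
  if (any(rates < 0 | rates > 1))
    stop("composed success probability outside [0, 1]; check error model")
  set.seed(seed)
  truth <- .makeTruth(config)
  reg <- config$regions
  if (!is.null(reg) && !is.null(reg$n) && reg$n > 0L) {
    gr <- .placeRegions(config$chromLengths, reg$n, reg$length,
                        if (is.null(reg$minGap)) 20000L else reg$minGap)
    stages <- reg$stages
    if (is.null(stages)) stages <- setdiff(config$stages, "sperm")
    truth <- plantRegions(truth, gr, type = reg$type, level = reg$level,
                          stages = intersect(stages, config$stages),
                          alleles = reg$alleles)
  }
  tables <- list()
  for (stage in config$stages) {
    for (assay in config$assays) {
      for (r in seq_len(config$replicates[[stage]])) {
        tab <- .emitTable(truth, config, stage, assay, r)
        tables[[sampleId(tab)]] <- tab
      }
    }
  }
  spikes <- .emitSpikes(config)
  list(tables = tables, truth = truth, spikes = spikes, config = config,
       seed = seed)
}
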