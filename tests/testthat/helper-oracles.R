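library(GenomicRanges)

# Independent oracles, kept deliberately naive: term-by-term enumeration
# rather than distribution functions.

# P(X >= c) for X ~ Binomial(n, p), summed term by term on the log scale
oracleBinomTail <- function(c, n, p) {
  if (c <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- c:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)))
}

# P(X >= q) for hypergeometric overlap: m dmr units drawn from n genome
# units of which k are element units
oracleHyperTail <- function(q, m, k, n) {
  lo <- max(0L, m + k - n)
  if (q <= lo) return(1)
  x <- q:min(m, k)
  if (!length(x)) return(0)
  sum(exp(lchoose(k, x) + lchoose(n - k, m - x) - lchoose(n, m)))
}

# log10 of the hypergeometric tail via logsumexp, for extreme tails
oracleHyperTailLog10 <- function(q, m, k, n) {
  lo <- max(0L, m + k - n)
  if (q <= lo) return(0)
  x <- q:min(m, k)
  lt <- lchoose(k, x) + lchoose(n - k, m - x) - lchoose(n, m)
  mx <- max(lt)
  (mx + log(sum(exp(lt - mx)))) / log(10)
}

# grid-search maximiser of the product binomial likelihood over the
# constrained region 0 <= h <= mh <= 1 (WGBS measures mh = m + h, ACE
# measures h); returns the h at the maximum
oracleGridMLE <- function(cBs, nBs, cAce, nAce, step = 2.5e-4) {
  loglik <- function(h, mh) {
    l1 <- cBs * log(mh) + (nBs - cBs) * log1p(-mh)
    l2 <- cAce * log(h) + (nAce - cAce) * log1p(-h)
    l1 + l2
  }
  # coarse 2-d scan to locate the optimum
  g <- seq(0.001, 0.999, by = 0.002)
  grid <- expand.grid(h = g, mh = g)
  grid <- grid[grid$mh >= grid$h, ]
  ll <- loglik(grid$h, grid$mh)
  best <- grid[which.max(ll), ]
  # fine 1-d scan along the boundary mh = h around the coarse optimum
  hs <- seq(max(step, best$h - 0.01), min(1 - step, best$h + 0.01),
            by = step)
  llb <- loglik(hs, hs)
  list(h = hs[which.max(llb)], coarse = best)
}

# small paired-table fixture builder
makeTable <- function(pos, nUnc, nConv, assay = "ACE", stage = "s",
                      chrom = "chr1", context = "CpG",
                      sampleId = "t", strand = "+",
                      allele = "unassigned", seqlengths = NULL) {
  SiteCountTable(chrom = chrom, pos = as.integer(pos),
                 nUnconverted = as.integer(nUnc),
                 nConverted = as.integer(nConv), strand = strand,
                 context = context, allele = allele, sampleId = sampleId,
                 assay = assay, stage = stage, seqlengths = seqlengths)
}

# tiny two-stage config for fast end-to-end runs; named arguments
# override the defaults
tinyConfig <- function(...) {
  defaults <- list(
    chromLengths = c(chrT = 4e5),
    stages = c("oocyte", "sperm"), replicates = c(2L, 2L),
    hProfile = list(maternal = c(oocyte = 0.0575, sperm = 0.005),
                    paternal = c(oocyte = 0.0575, sperm = 0.005)),
    mProfile = list(maternal = c(oocyte = 0.52, sperm = 0.75),
                    paternal = c(oocyte = 0.52, sperm = 0.75)),
    alleleWeights = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                           dimnames = list(c("oocyte", "sperm"),
                                           c("maternal", "paternal"))),
    regions = list(n = 5L, length = 7600L, level = 0.1369,
                   type = "hyper_hmDMR", stages = "oocyte",
                   alleles = NULL, minGap = 20000L),
    spike = list(lambdaCpG = 200L, lambdaCH = 500L,
                 hmcSites = 200L, depth = 50)
  )
  args <- list(...)
  defaults[names(args)] <- args
  do.call(simConfig, defaults)
}
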