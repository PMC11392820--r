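---
title: "Statistical methods for count-level 5hmC mapping"
author: "hydroxymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for count-level 5hmC mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxymap)
library(GenomicRanges)
```

# The measurement model

ACE-seq and WGBS report cytosine modification states through conversion
chemistry. At a CpG dyad with true fractions $u$ (unmodified), $m$
(5mC) and $h$ (5hmC), $u + m + h = 1$, the probability that a read
shows `C` is

$$
p_{\mathrm{ACE}} = h\rho + m\,\varepsilon_{\mathrm{mCpG}}
                  + u\,\varepsilon_u, \qquad
p_{\mathrm{WGBS}} = m + h + u\,\varepsilon_{\mathrm{bs}},
$$

where $\rho$ is the glucosylation protection rate of true 5hmC and the
$\varepsilon$ terms are non-conversion (error) rates. Observed counts
are binomial draws at the site's sequencing depth. Everything in the
package follows from this model: the level of a site is
$C/(C+T)$, undefined — not zero — at zero coverage, so that empty sites
never deflate regional means.

Two spike-in controls identify the nuisance parameters. In vitro
CpG-methylated lambda DNA is fully 5mC at CpG sites and unmodified at CH
sites, so its pooled CpG level estimates
$\varepsilon_{\mathrm{mCpG}}$ (the deamination-escape rate of 5mC) and
its pooled CH level estimates $\varepsilon_u$. A fully
hydroxymethylated control estimates $\rho$. Pooled (read-weighted)
estimation is the default because per-site averaging is unstable under
heterogeneous spike-in coverage; `perSite = TRUE` gives the site-mean
alternative. Following the upstream protocol, $\rho$ is reported for QC
but not used to rescale 5hmC levels.

# High-confidence 5hmCpG sites

A site with $N$ reads and $C$ unconverted is tested against the null
that all `C` reads are error:
$p = P(X \ge C),\ X \sim \mathrm{Binomial}(N,
\varepsilon_{\mathrm{mCpG}})$. Sites with $p < 0.025$ (strict) are
high-confidence. We use $\varepsilon_{\mathrm{mCpG}}$, not the smaller
CH error, because 5mC that escapes deamination is the dominant
confusable signal at CpG sites; this is the conservative choice. There
is deliberately no genome-wide multiple-testing correction here — the
fixed per-site alpha is the caller's operating point, and its realised
type-I error is checked on simulated null genomes. The default minimum
testable coverage is 2, matching the "detected at 2x" notion used as
the enrichment denominator.

1-kb tiles (anchored at coordinate 0) with at least three significant
sites and an unweighted mean site level strictly above 5% are
high-5hmC-fraction tiles. The unweighted site mean follows the
convention of averaging site levels within genomic bins; a pooled-count
mean would weight high-coverage sites and is not what binned level
summaries report.

# Joint (u, m, h) estimation

With exactly two assays the constrained maximum-likelihood estimate has
a closed form, which replaces an external iterative tool. Writing
$\hat p_{\mathrm{bs}} = C_{\mathrm{bs}}/N_{\mathrm{bs}}$ and
$\hat p_{\mathrm{ace}} = C_{\mathrm{ace}}/N_{\mathrm{ace}}$:

- if $\hat p_{\mathrm{ace}} \le \hat p_{\mathrm{bs}}$ the naive
  subtraction is the MLE:
  $\hat h = \hat p_{\mathrm{ace}},\ \hat m = \hat p_{\mathrm{bs}} -
  \hat p_{\mathrm{ace}},\ \hat u = 1 - \hat p_{\mathrm{bs}}$;
- otherwise the maximum lies on the boundary $m = 0$, where both assays
  measure the same parameter and the MLE pools the counts:
  $\hat h = (C_{\mathrm{bs}} + C_{\mathrm{ace}}) /
  (N_{\mathrm{bs}} + N_{\mathrm{ace}})$.

The boundary form is verified against a two-dimensional grid search of
the product binomial likelihood in the test suite. Sites whose naive
5mC component is negative are flagged as conflicted and excluded — the
literal reading of excluding "a negative level or any conflict". A
softer criterion (`ciConflict = TRUE`) excludes only sites whose 95%
Wilson score intervals for the two assays are disjoint, since the raw
sign rule discards sites whose disagreement is within sampling noise;
both are exposed because the original exclusion rule's definition of
"conflict" is not recoverable. Error-rate deconvolution of the levels
before estimation is deliberately off by default: the upstream
procedure describes assessment of the error rates, not correction.

# DMR and hmDMR calling

The sliding-window procedure between two conditions (replicates merged
first with `aggregateReplicates`):

1. **Window units.** Fixed 100-bp windows anchored at 0. A window is
   retained when at least two CpG sites are covered in both conditions;
   its level per condition is the unweighted mean of the jointly
   covered site levels. Windows, not single CpGs, are the sampling unit
   of the t-test — they are the object the procedure constructs first,
   and averaging within 100 bp damps single-site binomial noise.
2. **Sliding tiles.** 1,000-bp tiles stepped by 300 bp (both anchored
   at 0, so 100-bp windows are never split across a tile boundary). A
   paired two-sided Student's t-test is run on the per-window level
   differences of the windows inside the tile; tiles with fewer than
   three member windows are skipped. Whether the original test paired
   the conditions or treated them as independent samples is not
   recoverable; pairing is the default because the windows are matched
   by construction, and the unpaired variant would only lower power.
   Degenerate tiles have a documented convention: all differences zero
   gives $p = 1$, identical nonzero differences give $p = 0$.
3. **Candidates.** Tiles with $p < 0.1$ are labelled *hyper* when their
   mean difference (condition A minus B) exceeds the mark's cutoff —
   0.25 for 5mC, 0.1 for 5hmC — and *hypo* below the negative cutoff;
   unlabelled tiles are discarded. Overlapping same-label tiles merge,
   and same-label regions within 10 kb merge again. We also implemented
   the alternative reading in which overlapping $p<0.1$ tiles merge
   before labelling and the merged region is labelled as a whole; on
   planted-region benchmarks it recovers regions less accurately
   (flanking windows dilute the region-level effect below the cutoff),
   so per-tile labelling is used.
4. **Finalisation.** The paired t-test is recomputed over each merged
   region's member windows, Benjamini–Hochberg adjustment is applied
   across the candidate regions (after all merging — the stage at which
   the tested hypotheses are final), and a region is reported when it
   has at least three CpGs covered in both conditions, adjusted
   $p$ below the mark's cutoff (0.01 for 5mC, 0.025 for 5hmC), and an
   absolute mean difference above the effect cutoff with a sign
   matching its label. Every emitted region satisfies this triple by
   construction, and the caller is symmetric: swapping the conditions
   swaps hyper and hypo with identical boundaries and p-values.

Grid anchoring at coordinate 0 for windows, tiles and 1-kb bins is not
dictated by anything; it is fixed for reproducibility.

# Dynamics classification

Three rule sets, each a partition of its input domain:

- **Trajectory** between an early and a late stage:
  $r = (L_e - L_l)/L_e$; *decreased* when $r > 0.15$, *increased* when
  $r < -0.15$, *maintained* when $|r| \le 0.15$ (boundaries inclusive
  for maintained). Undefined at $L_e = 0$, reported as NA.
- **Bands**: *high* $\ge$ 5%, *medium* $\ge$ 2% and < 5%, *low*
  $\ge$ 1% and < 2%, *below_low* otherwise; lower bounds inclusive.
  The same three-band split (0.05 / 0.02 / 0.01) is the documented
  default wherever a maintenance / partial-loss / loss grouping is
  needed, because no explicit cutoffs accompany that grouping.
- **Fate** across a transition: *de novo methylation* when the gain
  exceeds 0.25, *demethylation* when the loss exceeds 0.25,
  *maintenance* otherwise. The 0.25 default reuses the 5mC DMR effect
  cutoff — the partition's own threshold is never stated, and borrowing
  the DMR cutoff keeps the two definitions consistent; it is fully
  configurable.
- A locus is flagged *low initial methylation* when its
  growing-oocyte-stage 5mC level is strictly below 0.15.

# Enrichment statistics

**Site enrichment** in an element class is a density-of-densities
ratio: the fraction of detected (coverage $\ge 2$) CpGs that are
high-confidence, per megabase of element, divided by the same quantity
genome-wide. The underlying normalisation phrase ("number of sites (in
megabases)") is ambiguous; this ratio is self-normalising (a
genome-wide element scores exactly 1), depends only on the union
geometry of the element class, and the raw per-Mb densities are also
reported so any other convention can be reconstructed.

**DMR enrichment** discretises the genome into 1-kb blocks (bp-level
factorials are needless extremes; the unit is configurable) and
computes the one-sided hypergeometric tail $P(X \ge \text{overlap})$
for the DMR blocks falling in the element, i.e. Fisher's exact test on
lengths. The tail is evaluated in log space (`phyper(log.p = TRUE)`),
so the $-\log_{10} p$ enrichment score is accurate far beyond double
underflow and capped at 300.

**Target genes**: a hit (motif match, region) targets a gene when it
overlaps the 15-kb window upstream of the TSS — $[t-15\,\mathrm{kb},
t]$ on the plus strand, $[t, t+15\,\mathrm{kb}]$ on the minus strand.
Overlap semantics are half-open BED on disk, 1-based closed in memory,
strand-agnostic except for this window.

# The synthetic data generator

`simulateDataset` draws, for every site, stage, assay and replicate,
coverage $N$ from a negative binomial (mean 30, dispersion 0.2 by
default; dispersion 0 gives constant depth, used by the benchmark
functions where a fixed-depth condition is analysed) and unconverted
counts from $\mathrm{Binomial}(N, p)$ with $p$ composed from the truth
and the error model exactly as in the measurement model above. Identical
seeds give bit-identical output.

What it emulates, and the defaults:

- a two-chromosome 10-Mb genome with uniformly placed CpG dyads at
  density 0.01/bp (the human genome-wide average of roughly one dyad
  per 100 bp) and CH sites at 0.002/bp;
- the gamete-to-blastocyst stage series with replicate counts
  (2, 4, 3, 3, 4, 5, 3) matching the study design being emulated;
- global 5hmCpG stage profiles anchored to the reported values
  (maternal 5.75% in oocytes, 5.17% in zygotes; paternal 5.71% in
  zygotes, 6.09% at the two-cell stage) with an interpolated decline to
  the blastocyst; CH 5hmC uniform in [0.12%, 0.20%];
- per-site 5mC heterogeneity as a Beta distribution around the stage
  target (precision 10), maternal and paternal truth tracks
  independent, gametes carrying a single parental genome and embryos
  weighting both at 1/2;
- planted regions — by default 50 hyper-hmDMRs of 7,600 bp at a 13.69%
  5hmC level, the reported median hmDMR geometry — inserted with a
  guaranteed minimum gap (20 kb) so that the 10-kb merge step cannot
  fuse distinct truths; inside a region $h$ is set to the planted level
  and $u$ absorbs the change;
- both spike-ins: lambda (fully 5mC CpG + unmodified CH) and a fully
  hydroxymethylated control;
- optional allele tagging: 30% of reads assignable to a parental
  allele, the remainder unassigned, mirroring SNP-phasing sparsity
  without implementing phasing.

What it does **not** emulate: read-level artefacts (the
three-consecutive-non-conversion read filter operates upstream of
counts), sequencing-error substitution models beyond conversion error,
CpG clustering into islands (placement is uniform), copy-number or
mappability structure, and coverage consequences of per-stage embryo
pool sizes beyond the mean-depth knob. Passing tests on this generator
therefore demonstrates the statistical correctness of the pipeline under
the stated model, not robustness to alignment artefacts or genome
composition effects in real data.

# Numerical choices and problem sizes

- Binomial and hypergeometric tails come from `pbinom`/`phyper`; both
  are validated against term-by-term pmf summation (all count
  configurations up to $N = 30$ for the binomial at five error rates;
  every margin configuration up to 50 blocks plus seeded random tables
  up to 200 blocks for the hypergeometric) at 1e-12 / 1e-9 absolute
  tolerance on $p$ and $-\log_{10} p$ respectively.
- The t statistic is computed in closed form and vectorised across
  tiles; it equals `stats::t.test` on the same differences
  (cross-checked in the tests).
- Validation problem sizes were chosen to keep the full suite under a
  few minutes: 100,000-site null genomes (10 seeds) for the type-I
  check, 10,000 sites for estimator bias, 10-Mb genomes with 50 planted
  regions over 20 seeds for hmDMR recovery, and the default
  configuration (run twice) for the determinism check.
- Region placement in the generator uses fixed-size slots so
  min-gap guarantees hold deterministically under any seed.

# Known limitations

- The DMR caller assumes two conditions; multi-group designs must be
  decomposed into pairs.
- Tile boundaries quantise called regions to the 100-bp/300-bp grid, so
  region edges carry up to ~1 kb of uncertainty.
- The binomial site test treats the calibrated error rate as known; its
  spike-in sampling uncertainty is not propagated (with tens of
  thousands of spike-in reads it is negligible at the default alpha).
- `conflictTest` compares two independent Wilson intervals and is
  conservative relative to an exact two-proportion test.
- CH analysis is restricted to global level summaries; no CH site
  calling is attempted.
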