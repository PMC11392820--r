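Package: hydroxymap
Title: Spike-In Calibrated Mapping of 5-Hydroxymethylcytosine from
    Paired ACE-seq and WGBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Count-level analysis of DNA hydroxymethylation (5hmC) from
    APOBEC-coupled epigenetic sequencing (ACE-seq) paired with whole-genome
    bisulfite sequencing (WGBS). Provides readers and writers for
    MethylDackel-style per-cytosine count tables, spike-in calibration of
    deamination error and glucosylation protection rates, binomial calling
    of high-confidence 5hmCpG sites and high-5hmC-fraction tiles, joint
    constrained maximum-likelihood estimation of per-site unmodified, 5mC
    and 5hmC fractions, a sliding-window caller for differentially
    (hydroxy)methylated regions with FDR control, rule-based classifiers of
    methylation fate and 5hmC trajectories across developmental stages,
    genomic-element enrichment statistics, and a synthetic data generator
    with planted regions and known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
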