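Package: popdiff
Title: Population Differentiation Selection Scans and Cross-Coalescence
    Divergence Times
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-site pairwise Hudson F_ST between pooled ancestry groups,
    the d statistic for locus-specific differentiation, empirical-percentile
    outlier calling, greedy LD clumping into tag variants, merged selection
    windows, and locus-local annotation-shift permutation enrichment with
    Bonferroni family-wise error control. Also converts MSMC-style scaled
    coalescence-rate curves into relative cross-coalescence rate (RCCR)
    curves and threshold-crossing divergence times in years. Ships seeded
    synthetic-data generators (Balding-Nichols genotypes with frequency
    spike-ins; pairwise coalescence times under a clean two-deme split) so
    every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Coverage, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'dscan.R'
    'enrichment.R'
    'fst.R'
    'genotype-data.R'
    'ldclump.R'
    'pipeline.R'
    'rccr.R'
    'synthetic-coalescent.R'
    'synthetic-genotypes.R'
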