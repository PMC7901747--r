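Package: strainassoc
Title: Case/Control Allelic Association Screening with Crowd-Sourced
    Strain Phenotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess whether crowd-sourced phenotype databases can
    support genome-wide association screening in clonally named crop
    strains. Collates per-source strain-by-trait tables, averages chemical
    measurements across sources, encodes quantitative traits into
    reciprocal percentile case/control catalogs, hard-filters and LD-prunes
    a multi-sample SNP set, runs the 1-df allelic chi-square battery, and
    calls consensus hits by four complementary rules including a balanced
    Fisher-Yates bootstrap. A synthetic-data module simulates genotypes
    with local linkage disequilibrium, multi-source noisy phenotypes and
    planted causal variants so the whole pipeline is testable end to end,
    and an annotation module interprets hits by gene proximity,
    chromosomal distribution and GO-term over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
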