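Package: mesasim
Title: Microfluidic Droplet Target Enrichment: Simulation and Coverage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates droplet-based targeted sequence enrichment (MESA):
    Poisson co-encapsulation of high-molecular-weight genomic fragments into
    TaqMan digital-PCR microdroplets, fluorescence-threshold dielectrophoretic
    sorting with merged droplets and false sorts, amplicon removal, and
    whole-genome-amplification copy dispersion. Provides the coverage-based
    enrichment statistics used to evaluate such experiments (sliding-window
    means, mean+3SD background thresholds, differential specificity scans,
    probe-centered fold enrichment versus window size, FWHM fragment-size
    estimation, coverage-uniformity CDFs), closed-form digital-PCR enrichment
    mathematics including the purity-recovery dilution tradeoff, and a minimal
    pileup SNP caller with depth/quality filtering and truth concordance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
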