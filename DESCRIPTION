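Package: gwasim
Title: Simulation-Based Power Evaluation of Mixed-Model GWAS in Structured
    Yeast Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates structured haploid or diploid genotype panels with
    configurable allele-frequency spectra, singleton load, clade structure and
    clonal relatedness; simulates additive Mendelian and complex quantitative
    traits at a target heritability; performs linear mixed model association
    with a genomic relationship matrix, restricted maximum likelihood variance
    components estimated by a single spectral decomposition, and Wald tests;
    derives permutation-based family-wise significance thresholds; and
    evaluates detection performance (true/false positive rates, genomic
    inflation factor, heritability recovery) across population designs.
    Includes presets emulating six Saccharomyces cerevisiae population panels
    and reads/writes VCF and PLINK-style text genotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
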