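Package: radscan
Title: Minor-Allele-Count Filtering and FST Genome Scans for RAD-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a RAD-sequencing genome-scan
    analysis chain for two-population comparisons: quality-aware consensus
    genotyping of read stacks with a binomial heterozygote test, per-site
    population differentiation via Weir and Cockerham's theta and a
    haplotype-diversity FST estimator, minor-allele-count marker filtering,
    threshold sweeps, LOESS sliding-window differentiation profiles, and a
    sister-RAD-site correlation diagnostic.  A synthetic-data module
    generates two-population genotype and read-stack data with rare-allele
    skewed site-frequency spectra, drift baseline differentiation, and
    localized hitchhiking peaks, and is used to demonstrate that retaining
    low minor-allele-frequency SNPs biases baseline FST downward and
    flattens differentiation profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
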