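Package: polyscan
Title: Genetic Mapping in Autopolyploids from Low-Coverage Sequencing
    Using Allele Dosage Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Association mapping for autopolyploid populations genotyped by
    low-coverage sequencing (GBS/RAD-seq). Instead of hard allele-dosage
    calls, per-marker dosage probability matrices are computed from reference
    and total read depths under a binomial model, and marker-phenotype
    association is tested with generalized-linear-model likelihood-ratio
    tests under two genotype encodings (expected continuous dosage, or the
    full dosage-probability matrix). Genome-wide significance thresholds are
    calibrated by phenotype permutation with generalized-extreme-value tail
    modelling. A built-in simulator of polysomic S1/F1 segregation at
    arbitrary even ploidy, beta-binomial read counts with allelic bias and
    overdispersion, and single-locus phenotypes at controlled heritability
    supports power and accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
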