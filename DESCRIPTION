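Package: vgrscan
Title: Breed-Differentiation Scans and Variable Genomic Region Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects variable genomic regions (VGR) that differentiate two
    populations genotyped on a SNP array. Reads PLINK text PED/MAP genotypes,
    applies marker quality control (missingness, minor allele frequency,
    exact Hardy-Weinberg test), scores every SNP by the Weir-Cockerham Fst
    estimator and by Fisher's exact allelic test, runs an EMMAX-style
    mixed-model association with an identity-by-state kinship matrix and the
    population label as the phenotype, then calls regions by a rank-based
    peak-extension rule and reports only regions supported by both scan
    types, annotated against user-supplied candidate-gene intervals. A
    Balding-Nichols simulator with planted divergent regions makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
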