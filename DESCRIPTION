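Package: poolimpute
Title: Parent-Progeny Genotype Imputation from Pooled Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the marker genotypes of individual doubled-haploid (DH)
    lines from non-barcoded pooled DNA samples genotyped by sequencing. A
    hidden Markov model over parental inheritance patterns combines parent
    genotypes, pedigree, a genetic linkage map and pooled allele read counts
    (Beta-Binomial emission model) to produce posterior genotype
    probabilities and fractional allele dosages per pooled individual.
    Includes a genotyping-by-sequencing pool simulator (synthetic founder
    panels, Haldane meiosis, Dirichlet DNA contributions, Gamma-Poisson read
    depths), accuracy and calibration diagnostics, genomic prediction
    helpers, and selection-economics calculations for comparing pooled
    low-coverage genotyping with individual high-quality genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    parallel
Config/testthat/edition: 3
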