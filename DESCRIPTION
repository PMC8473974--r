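Package: snppanel
Title: SNP Array Panel Design and Allopolyploid Genotype Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing fixed SNP genotyping arrays from population
    re-sequencing variant calls and for calling genotypes from two-channel
    (X/Y) intensity data in an allotetraploid crop. Implements the candidate
    SNP filter cascade (biallelic, minor allele frequency, mapping quality,
    carrier count, clean and genome-unique 50-bp flanks), 100-kb genome
    binning with greedy r-squared linkage-disequilibrium grouping,
    density-balanced probe selection with QTL boosting, theta/R polar
    transformation, per-marker Gaussian-mixture cluster-model fitting with
    three-genotype and five-dosage (intergenomic) call maps, cluster-file
    construction and replicate concordance, bulked-segregant window scans,
    variety comparison, and transgene dilution-series detection. A synthetic
    population, cross, and intensity simulator with block LD structure makes
    the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
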