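Package: exocall
Title: Genotype-Calling Quality Control for Exome Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for quality control of exome genotyping array data.
    Simulates normalized two-channel array intensities (theta/R) with
    planted clustering pathologies, fits per-variant three-cluster
    genotype models and calls genotypes against them, computes
    GenomeStudio-style per-variant cluster statistics, flags variants
    under the CHARGE-consortium and adjusted rare-variant criteria,
    repairs flagged variants by deterministic reclustering, runs a
    PLINK-style sample and variant QC cascade (Hardy-Weinberg exact
    test, identity-by-descent relatedness, X-chromosome sex check,
    call-rate and minor-allele-count filters), and scores genotype
    concordance against sequencing-derived truth genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
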